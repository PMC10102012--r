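# End-to-end desk benchmark: the package's own scaled-down version of the
# label-efficiency and style-transfer-benefit experiments, run entirely on
# synthetic data.

#' Run the desk-scale end-to-end benchmark
#'
#' Builds a texture-confounded synthetic dataset, trains the AdaIN coder,
#' pre-synthesizes stylized variants, and then, for each replicate seed,
#' (i) contrastively pretrains an encoder with style-transfer augmentation
#' (NST probability 0.70) and one without it, and (ii) fits a
#' `label_fraction`-label classifier from each checkpoint and from random
#' initialization, using the frozen-encoder linear-probe mode of
#' [finetune()] (the exact, optimizer-noise-free fit), averaged over
#' `n_label_draws` stratified label subsamples. All arms are evaluated by
#' AUC on one fixed held-out test manifest.
#'
#' Everything is derived from `seed`; the replicate axis is
#' `seeds = seed-derived stream 1..n_seeds`.
#'
#' @param seed Master seed.
#' @param n_seeds Number of replicate seeds (>= 3 for the headline
#'   comparisons).
#' @param n_images Total synthetic images (training pool + held-out test).
#' @param test_fraction Fraction held out for evaluation (stratified).
#' @param label_fraction Label fraction for the classifier arms.
#' @param n_label_draws Stratified label subsamples averaged per arm.
#' @param pretrain_epochs Contrastive epochs per pretraining run.
#' @param out_dir Working directory for images and caches.
#' @param verbose Print progress.
#' @return `data.frame` (seed, arm, label_fraction, auc) with arms `nst`,
#'   `plain`, `random`, plus attribute `config`.
#' @export
desk_benchmark <- function(seed = 1, n_seeds = 3, n_images = 480,
                           test_fraction = 0.375, label_fraction = 0.1,
                           n_label_draws = 5, pretrain_epochs = 40,
                           out_dir = file.path(tempdir(), "retinaCL-benchmark"),
                           verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  params <- synth_params(image_size = 32)

  say("generating %d synthetic fundus images ...", n_images)
  man <- generate_dataset(n_images, c(0.5, 0.2, 0.15, 0.1, 0.05), params,
                          file.path(out_dir, "data"),
                          seed = derive_seed(seed, "data"))
  test_man <- subsample_label_fraction(man, test_fraction,
                                       derive_seed(seed, "test-split"))
  train_man <- subset_manifest(man, !(man$image_id %in% test_man$image_id))

  say("training AdaIN coder ...")
  bank <- generate_style_bank(24, 32, seed = derive_seed(seed, "styles"))
  coder_imgs <- c(lapply(train_man$path[seq_len(min(64, nrow(train_man)))],
                         read_image),
                  bank, bank, bank[seq_len(16)])
  coder <- train_coder(coder_imgs,
                       desk_coder_config(content_size = 32L, style_size = 32L,
                                         epochs = 45L),
                       seed = derive_seed(seed, "coder"))

  say("pre-synthesizing stylized variants ...")
  cache <- precompute_stylized(train_man, bank, variants_per_image = 2L,
                               alpha = 1.0, coder = coder,
                               out_dir = file.path(out_dir, "stylized"),
                               seed = derive_seed(seed, "stylize"))
  cache <- preload_cache(cache)

  pre_cfg <- function(nst) {
    desk_pretrain_config(
      epochs = pretrain_epochs,
      augmentation = augmentation_policy(output_size = 32L,
                                         nst_probability = nst))
  }
  ft_cfg <- desk_finetune_config(linear_probe = TRUE)
  test_images <- stats::setNames(lapply(test_man$path, read_image),
                                 test_man$image_id)

  # classifier AUC for one initialization at one label fraction: fit the
  # probe on a stratified label subsample (a sliver held out to satisfy the
  # train/validation contract) and score the fixed test manifest
  arm_auc <- function(init, fraction, draw_seed) {
    sub <- subsample_label_fraction(train_man, fraction, draw_seed)
    val <- subsample_label_fraction(sub, 0.15, derive_seed(draw_seed, "val"))
    trn <- subset_manifest(sub, !(sub$image_id %in% val$image_id))
    fit <- finetune(trn, val, init, ft_cfg, seed = draw_seed)
    sc <- predict_referable(fit$model, test_man, test_images)
    roc_auc(sc, test_man$referable)$auc
  }

  rows <- list()
  for (k in seq_len(n_seeds)) {
    rep_seed <- derive_seed(seed, paste0("rep-", k))
    say("replicate %d / %d: contrastive pretraining (with NST) ...", k, n_seeds)
    ck_nst <- pretrain(train_man, cache, pre_cfg(0.70), seed = rep_seed)
    say("replicate %d / %d: contrastive pretraining (no NST) ...", k, n_seeds)
    ck_plain <- pretrain(train_man, NULL, pre_cfg(0), seed = rep_seed)

    arms <- list(
      nst = list(transfer_weights(ck_nst, seed = rep_seed)),
      plain = list(transfer_weights(ck_plain, seed = rep_seed)),
      # random features vary a lot between draws; average two inits
      random = list(
        classifier_model("tiny", seed = derive_seed(rep_seed, "rnd-a")),
        classifier_model("tiny", seed = derive_seed(rep_seed, "rnd-b"))
      )
    )
    for (arm in names(arms)) {
      for (fraction in c(label_fraction, 1.0)) {
        n_draws <- if (fraction < 1) n_label_draws else 1L
        aucs <- c()
        for (init in arms[[arm]]) {
          aucs <- c(aucs, vapply(seq_len(n_draws), function(d) {
            arm_auc(init, fraction,
                    derive_seed(rep_seed, sprintf("draw-%g-%d", fraction, d)))
          }, numeric(1)))
        }
        say("replicate %d: %s arm, %d%% labels: AUC %.3f", k, arm,
            round(100 * fraction), mean(aucs))
        rows[[length(rows) + 1L]] <- data.frame(
          seed = k, arm = arm, label_fraction = fraction, auc = mean(aucs),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(n_images = n_images,
                              test_fraction = test_fraction,
                              label_fraction = label_fraction,
                              n_label_draws = n_label_draws,
                              pretrain_epochs = pretrain_epochs,
                              n_seeds = n_seeds, seed = seed)
  out
}
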