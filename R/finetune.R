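# Supervised fine-tuning for referable vs non-referable DR: one-to-one
# encoder transfer, cross-entropy training with Adam, hyperparameter grid
# search, and the label-fraction experiment.

#' Fine-tuning configuration
#'
#' Full-scale defaults follow the published protocol (batch size 256,
#' cross-entropy, Adam, logarithmic learning-rate grid 1e-6..1e-2 and
#' weight-decay grid 1e-5..1e-3, on-the-fly rotation <= 30 degrees,
#' horizontal flip and color distortion); [desk_finetune_config()] is the
#' CPU preset.
#'
#' @param batch_size Minibatch size.
#' @param learning_rate,weight_decay Adam settings for a single run.
#' @param lr_grid,wd_grid Grids for [hyperparameter_search()].
#' @param epochs Training epochs.
#' @param augmentation An [augmentation_policy()] applied on the fly (no NST,
#'   no vertical flip, no crop by default, matching the fine-tuning recipe).
#' @param linear_probe If `TRUE`, the encoder is frozen and the
#'   classification head is fitted exactly, by ridge-regularized logistic
#'   regression on the encoder features (no stochastic optimizer, no
#'   augmentation), so the result measures representation quality free of
#'   optimizer noise; default is end-to-end stochastic training.
#' @param probe_lambda Ridge penalty of the linear probe (on standardized
#'   features).
#' @param label_fraction Fraction of labeled data, recorded for provenance.
#' @return Object of class `finetune_config`.
#' @export
finetune_config <- function(batch_size = 256L,
                            learning_rate = 1e-3, weight_decay = 1e-4,
                            lr_grid = 10^seq(-6, -2),
                            wd_grid = 10^seq(-5, -3),
                            epochs = 10L,
                            augmentation = augmentation_policy(
                              nst_probability = 0, rotation_max_deg = 30,
                              jitter_strength = 0.5, blur_probability = 0,
                              crop_scale_range = c(1, 1), vflip_prob = 0,
                              output_size = 224L),
                            linear_probe = FALSE,
                            probe_lambda = 1.0,
                            label_fraction = 1.0) {
  if (!length(lr_grid) || !length(wd_grid)) stop("grids must be non-empty", call. = FALSE)
  if (label_fraction <= 0 || label_fraction > 1) {
    stop("label_fraction must lie in (0, 1]", call. = FALSE)
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 lr_grid = lr_grid, wd_grid = wd_grid,
                 epochs = as.integer(epochs), augmentation = augmentation,
                 linear_probe = isTRUE(linear_probe),
                 probe_lambda = probe_lambda,
                 label_fraction = label_fraction),
            class = "finetune_config")
}

#' Desk-profile fine-tuning configuration (small encoder, 32 px)
#' @param ... Overrides passed to [finetune_config()].
#' @export
desk_finetune_config <- function(...) {
  args <- utils::modifyList(
    list(batch_size = 16L, epochs = 8L, learning_rate = 2e-3,
         augmentation = augmentation_policy(
           nst_probability = 0, rotation_max_deg = 30, jitter_strength = 0.5,
           blur_probability = 0, crop_scale_range = c(1, 1), vflip_prob = 0,
           output_size = 32L)),
    list(...))
  do.call(finetune_config, args)
}

#' Build a classifier model (encoder + classification head)
#'
#' @param encoder_name Encoder architecture.
#' @param seed Integer seed for initialization.
#' @param provenance One of `"random"`, `"fundus-cl"`, `"external-init"`.
#' @return Object of class `classifier_model`.
#' @export
classifier_model <- function(encoder_name = "tiny", seed = 1,
                             provenance = "random") {
  encoder <- make_encoder(encoder_name, derive_seed(seed, "clf-enc"))
  head <- nn_init(list(nn_dense("clf", encoder$h_dim, 1L)),
                  derive_seed(seed, "clf-head"))
  structure(list(encoder = encoder, head = head,
                 encoder_name = encoder_name, provenance = provenance),
            class = "classifier_model")
}

#' Transfer pretrained encoder weights one-to-one into a classifier
#'
#' Every encoder layer is copied bit-exactly from the checkpoint (the layer
#' name sets must match exactly); the projection head is discarded — the h
#' representation feeding the classifier is the one before the projection
#' head — and the classification head is freshly initialized from the seed.
#'
#' @param checkpoint A `cl_checkpoint`.
#' @param model A [classifier_model()] with the same encoder architecture,
#'   or `NULL` to build one.
#' @param seed Seed for the fresh classification head.
#' @return A `classifier_model` with provenance `"fundus-cl"`.
#' @export
transfer_weights <- function(checkpoint, model = NULL, seed = 1) {
  if (!inherits(checkpoint, "cl_checkpoint")) {
    stop("checkpoint must be a cl_checkpoint", call. = FALSE)
  }
  if (is.null(model)) {
    model <- classifier_model(checkpoint$encoder_name, seed = seed)
  }
  if (!identical(model$encoder_name, checkpoint$encoder_name)) {
    stop("encoder mismatch: checkpoint is '", checkpoint$encoder_name,
         "', model is '", model$encoder_name, "'", call. = FALSE)
  }
  have <- names(net_params(model$encoder$net))
  want <- names(checkpoint$encoder)
  if (!setequal(have, want)) {
    stop("encoder layer names differ; missing: ",
         paste(setdiff(have, want), collapse = ", "), "; unexpected: ",
         paste(setdiff(want, have), collapse = ", "), call. = FALSE)
  }
  model$encoder$net <- net_set_params(model$encoder$net, checkpoint$encoder)
  model$head <- nn_init(list(nn_dense("clf", model$encoder$h_dim, 1L)),
                        derive_seed(seed, "clf-head"))
  model$provenance <- "fundus-cl"
  model
}

sigmoid <- function(x) 1 / (1 + exp(-x))

model_forward_scores <- function(model, x) {
  h <- net_forward(model$encoder$net, x)$out
  as.vector(sigmoid(net_forward(model$head, h)$out))
}

#' Predict referable-DR scores for a manifest
#'
#' @param model A trained `classifier_model`.
#' @param manifest A `fundus_manifest`.
#' @param images Optional named list of preloaded images (by image_id).
#' @return Numeric vector of scores in \[0, 1\], aligned with the manifest.
#' @export
predict_referable <- function(model, manifest, images = NULL) {
  if (nrow(manifest) == 0) return(numeric(0))
  imgs <- lapply(seq_len(nrow(manifest)), function(r) {
    id <- manifest$image_id[r]
    if (!is.null(images) && !is.null(images[[id]])) return(images[[id]])
    read_image(manifest$path[r])
  })
  scores <- numeric(nrow(manifest))
  for (start in seq(1L, length(imgs), by = 64L)) {
    ids <- start:min(start + 63L, length(imgs))
    scores[ids] <- model_forward_scores(model, prep_batch(imgs[ids]))
  }
  scores
}

#' Supervised fine-tuning
#'
#' Trains the classifier with on-the-fly augmentation and binary
#' cross-entropy under Adam; after each epoch the model is scored on the
#' validation manifest and the epoch with the best validation AUC is
#' returned (earlier epoch wins ties).
#'
#' @param train_manifest,val_manifest Disjoint `fundus_manifest`s.
#' @param init A `classifier_model` initialization.
#' @param config A [finetune_config()].
#' @param seed Integer seed.
#' @return List: `model` (best epoch), `history` (epoch, train_loss,
#'   val_auc), `best_epoch`.
#' @export
finetune <- function(train_manifest, val_manifest, init,
                     config = desk_finetune_config(), seed = 1) {
  if (nrow(train_manifest) == 0 || nrow(val_manifest) == 0) {
    stop("manifests must be non-empty", call. = FALSE)
  }
  overlap <- intersect(train_manifest$image_id, val_manifest$image_id)
  if (length(overlap)) {
    stop("train and validation manifests overlap: ",
         paste(utils::head(overlap, 3), collapse = ", "), call. = FALSE)
  }
  model <- init
  train_images <- stats::setNames(
    lapply(train_manifest$path, read_image), train_manifest$image_id)
  val_images <- stats::setNames(
    lapply(val_manifest$path, read_image), val_manifest$image_id)
  y <- as.numeric(train_manifest$referable)

  if (config$linear_probe) {
    model <- fit_linear_probe(model, train_manifest, train_images, y,
                              lambda = config$probe_lambda)
    val_scores <- predict_referable(model, val_manifest, val_images)
    v_auc <- roc_auc(val_scores, val_manifest$referable)$auc
    history <- data.frame(epoch = 1L, train_loss = NA_real_, val_auc = v_auc)
    return(list(model = model, history = history, best_epoch = 1L))
  }

  par <- c(net_params(model$encoder$net), net_params(model$head))
  n_enc <- length(net_params(model$encoder$net))
  state <- adam_init(par)
  n <- nrow(train_manifest)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_auc = numeric())
  best <- list(auc = -Inf, par = par, epoch = 0L)

  if (config$epochs == 0L) {
    return(list(model = model, history = history, best_epoch = 0L))
  }

  for (ep in seq_len(config$epochs)) {
    ep_stats <- with_seed(derive_seed(seed, paste0("ft-epoch-", ep)), {
      order_ep <- sample(n)
      tot_loss <- 0; n_b <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        ids <- order_ep[start:min(start + config$batch_size - 1L, n)]
        views <- lapply(ids, function(i) {
          regular_augment(train_images[[train_manifest$image_id[i]]],
                          config$augmentation)
        })
        x <- prep_batch(views)
        model$encoder$net <- net_set_params(model$encoder$net, par[seq_len(n_enc)])
        model$head <- net_set_params(model$head, par[-seq_len(n_enc)])
        ef <- net_forward(model$encoder$net, x)
        hf <- net_forward(model$head, ef$out)
        pr <- sigmoid(as.vector(hf$out))
        yi <- y[ids]
        eps <- 1e-12
        loss <- -mean(yi * log(pr + eps) + (1 - yi) * log(1 - pr + eps))
        if (!is.finite(loss)) stop("non-finite training loss", call. = FALSE)
        dlogit <- matrix((pr - yi) / length(ids), nrow = 1L)
        bh <- net_backward(model$head, hf$caches, dlogit)
        be <- net_backward(model$encoder$net, ef$caches, bh$dx)
        grads <- c(be$grads, bh$grads)
        upd <- adam_step(par, grads, state, lr = config$learning_rate,
                         weight_decay = config$weight_decay)
        par <- upd$params; state <- upd$state
        tot_loss <- tot_loss + loss; n_b <- n_b + 1L
      }
      tot_loss / n_b
    })
    model$encoder$net <- net_set_params(model$encoder$net, par[seq_len(n_enc)])
    model$head <- net_set_params(model$head, par[-seq_len(n_enc)])
    val_scores <- predict_referable(model, val_manifest, val_images)
    v_auc <- roc_auc(val_scores, val_manifest$referable)$auc
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_stats,
                                         val_auc = v_auc))
    if (v_auc > best$auc) best <- list(auc = v_auc, par = par, epoch = ep)
  }

  model$encoder$net <- net_set_params(model$encoder$net,
                                      best$par[seq_len(n_enc)])
  model$head <- net_set_params(model$head, best$par[-seq_len(n_enc)])
  list(model = model, history = history, best_epoch = best$epoch)
}

#' Grid search over learning rate and weight decay by cross-validation
#'
#' Trains each `(lr, wd)` grid point on every fold and averages validation
#' AUC; the argmax is returned with ties broken by smaller learning rate,
#' then smaller weight decay.
#'
#' @param folds Folds from [kfold_split()].
#' @param init_fn Function `(seed) -> classifier_model` producing a fresh
#'   initialization per run.
#' @param config A [finetune_config()] (its `lr_grid`/`wd_grid` are used).
#' @param seed Integer seed.
#' @return List: `best` (lr, wd), `table` (lr, wd, fold, val_auc).
#' @export
hyperparameter_search <- function(folds, init_fn, config = desk_finetune_config(),
                                  seed = 1) {
  if (!length(config$lr_grid) || !length(config$wd_grid)) {
    stop("empty hyperparameter grid", call. = FALSE)
  }
  rows <- list()
  for (lr in sort(config$lr_grid)) {
    for (wd in sort(config$wd_grid)) {
      cfg <- config
      cfg$learning_rate <- lr; cfg$weight_decay <- wd
      for (f in seq_along(folds)) {
        fit <- finetune(folds[[f]]$train, folds[[f]]$validation,
                        init_fn(derive_seed(seed, sprintf("hp-%g-%g-%d", lr, wd, f))),
                        cfg, seed = derive_seed(seed, sprintf("hpft-%g-%g-%d", lr, wd, f)))
        rows[[length(rows) + 1L]] <- data.frame(
          lr = lr, wd = wd, fold = f,
          # an untrained run carries no information: score it as chance
          val_auc = if (nrow(fit$history)) max(fit$history$val_auc) else 0.5)
      }
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(val_auc ~ lr + wd, tab, mean)
  agg <- agg[order(-agg$val_auc, agg$lr, agg$wd), ]
  list(best = list(lr = agg$lr[1], wd = agg$wd[1]), table = tab,
       summary = agg)
}

#' Label-fraction experiment
#'
#' For every fraction x seed x initialization (contrastively pretrained vs
#' random), subsamples the labeled training manifest (stratified, nested per
#' seed), fine-tunes, and evaluates on the fixed held-out manifest.
#'
#' @param train_manifest Labeled training pool.
#' @param test_manifest Fixed held-out evaluation manifest.
#' @param fractions Label fractions in (0, 1\].
#' @param seeds Integer vector of replicate seeds.
#' @param checkpoint A `cl_checkpoint` for the pretrained arm.
#' @param config A [finetune_config()].
#' @param val_fraction Fraction of each subsample held out (stratified) for
#'   epoch selection within [finetune()].
#' @return Long-format data.frame: fraction, seed, init, auc.
#' @export
label_fraction_experiment <- function(train_manifest, test_manifest,
                                      fractions = seq(0.1, 1.0, by = 0.1),
                                      seeds = 1:3, checkpoint,
                                      config = desk_finetune_config(),
                                      val_fraction = 0.25) {
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  if (!length(seeds)) stop("need at least one seed", call. = FALSE)
  rows <- list()
  for (fr in fractions) {
    for (sd in seeds) {
      sub <- subsample_label_fraction(train_manifest, fr, sd)
      val <- subsample_label_fraction(sub, val_fraction, derive_seed(sd, "val"))
      trn <- subset_manifest(sub, !(sub$image_id %in% val$image_id))
      for (init_kind in c("fundus-cl", "random")) {
        init <- if (init_kind == "fundus-cl") {
          transfer_weights(checkpoint, seed = derive_seed(sd, paste0("lf-", fr)))
        } else {
          classifier_model(config_encoder_name(checkpoint),
                           seed = derive_seed(sd, paste0("lfr-", fr)))
        }
        fit <- finetune(trn, val, init, config,
                        seed = derive_seed(sd, sprintf("lf-ft-%g-%s", fr, init_kind)))
        scores <- predict_referable(fit$model, test_manifest)
        rows[[length(rows) + 1L]] <- data.frame(
          fraction = fr, seed = sd, init = init_kind,
          auc = roc_auc(scores, test_manifest$referable)$auc)
      }
    }
  }
  do.call(rbind, rows)
}

config_encoder_name <- function(checkpoint) checkpoint$encoder_name

# Frozen-encoder linear probe: ridge-regularized logistic regression on the
# (unaugmented) encoder features, fitted exactly by iteratively reweighted
# least squares; the solution is folded into the classification head so the
# usual predict path applies.
fit_linear_probe <- function(model, manifest, images, y, lambda = 1.0,
                             n_iter = 30L) {
  feats <- matrix(0, nrow(manifest), model$encoder$h_dim)
  for (start in seq(1L, nrow(manifest), by = 64L)) {
    ids <- start:min(start + 63L, nrow(manifest))
    x <- prep_batch(images[manifest$image_id[ids]])
    feats[ids, ] <- t(net_forward(model$encoder$net, x)$out)
  }
  mu <- colMeans(feats)
  sdv <- apply(feats, 2, stats::sd)
  sdv[sdv < 1e-8] <- 1
  xs <- sweep(sweep(feats, 2, mu), 2, sdv, "/")
  X <- cbind(1, xs)
  p_dim <- ncol(X)
  pen <- diag(c(0, rep(lambda, p_dim - 1L)))   # intercept unpenalized
  beta <- numeric(p_dim)
  for (it in seq_len(n_iter)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-6)
    z <- eta + (y - p) / w
    xtw <- t(X * w)
    beta_new <- solve(xtw %*% X + pen, xtw %*% z)
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta <- as.vector(beta)
  w_raw <- beta[-1] / sdv
  b_raw <- beta[1] - sum(beta[-1] * mu / sdv)
  model$head <- net_set_params(model$head, list(
    clf.W = matrix(w_raw, 1L), clf.b = b_raw))
  model
}
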