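# Shared lazily-built fixtures. Everything is generated in code under a
# session temp dir; heavier objects (the trained AdaIN coder, the small
# on-disk dataset) are built once per test run and memoised.

fixture_env <- new.env(parent = emptyenv())

desk_params <- function() synth_params(image_size = 32)

# Small on-disk dataset (40 images, 32 px) shared across tests.
fixture_dataset <- function() {
  if (is.null(fixture_env$manifest)) {
    dir <- file.path(tempdir(), "retinaCL-fixture-ds")
    fixture_env$manifest <- generate_dataset(
      40, c(0.4, 0.15, 0.2, 0.15, 0.1), desk_params(), dir, seed = 424)
  }
  fixture_env$manifest
}

fixture_style_bank <- function() {
  if (is.null(fixture_env$styles)) {
    fixture_env$styles <- generate_style_bank(8, 32, seed = 77)
  }
  fixture_env$styles
}

# Trained desk coder (the slowest fixture; ~30 s, built once).
fixture_coder <- function() {
  if (is.null(fixture_env$coder)) {
    man <- fixture_dataset()
    imgs <- c(lapply(man$path, read_image),
              fixture_style_bank(),
              generate_style_bank(32, 32, seed = 78))
    fixture_env$coder <- train_coder(
      imgs, desk_coder_config(content_size = 32L, style_size = 32L,
                              epochs = 45L),
      seed = 11)
  }
  fixture_env$coder
}

fixture_stylized_cache <- function() {
  if (is.null(fixture_env$cache)) {
    dir <- file.path(tempdir(), "retinaCL-fixture-sty")
    fixture_env$cache <- precompute_stylized(
      fixture_dataset(), fixture_style_bank(), variants_per_image = 2L,
      alpha = 1.0, coder = fixture_coder(), out_dir = dir, seed = 31)
  }
  fixture_env$cache
}

# A one-epoch contrastive checkpoint shared by the transfer tests.
make_small_checkpoint <- function(seed = 9) {
  if (is.null(fixture_env$small_ck)) {
    cfg <- desk_pretrain_config(batch_size = 8L, epochs = 1L,
                                augmentation = identity_policy())
    fixture_env$small_ck <- pretrain(fixture_dataset(), NULL, cfg, seed = seed)
  }
  fixture_env$small_ck
}

# An in-memory manifest with no backing files, for split/subsample tests.
synthetic_manifest <- function(n_nonref = 70, n_ref = 30) {
  grades <- c(sample(0:1, n_nonref, replace = TRUE, prob = c(0.7, 0.3)),
              sample(2:4, n_ref, replace = TRUE, prob = c(0.5, 0.3, 0.2)))
  as_manifest(data.frame(
    image_id = sprintf("rec%03d", seq_along(grades)),
    path = sprintf("rec%03d.png", seq_along(grades)),
    dr_grade = grades, referable = grades >= 2,
    split = NA_character_, stringsAsFactors = FALSE))
}

# Cheap augmentation policy: no geometric/color ops, used where only the
# NST-substitution draw matters.
identity_policy <- function(nst_probability = 0, output_size = 32L) {
  augmentation_policy(nst_probability = nst_probability,
                      rotation_max_deg = 0, jitter_strength = 0,
                      blur_probability = 0, crop_scale_range = c(1, 1),
                      hflip_prob = 0, vflip_prob = 0,
                      output_size = output_size)
}

quiet_adain <- function(expr) {
  withCallingHandlers(expr,
    retinaCL_zero_sd = function(w) invokeRestart("muffleWarning"))
}
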