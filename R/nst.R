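# Adaptive instance normalization (AdaIN) style transfer.
#
# A content image and a style image are both encoded into a convolutional
# feature space; the AdaIN layer re-scales each content feature channel so
# its spatial mean and standard deviation match the style channel's, and a
# decoder renders the result back to pixels. The AdaIN algebra is exact and
# decoder-independent; the coder supplying the feature space is a small
# convolutional autoencoder trained by reconstruction on synthetic fundus
# and style images.

#' Per-channel spatial mean and standard deviation of a feature map
#'
#' @param fm Feature map: (H, W, C) array (a trailing singleton batch axis is
#'   tolerated). Standard deviation uses the population convention
#'   (denominator n, not n - 1).
#' @return Object of class `channel_stats`: list with `mean` and `sd`,
#'   one entry per channel.
#' @export
channel_stats <- function(fm) {
  d <- dim(fm)
  if (length(d) == 4L && d[4] == 1L) {
    dim(fm) <- d[1:3]
    d <- d[1:3]
  }
  if (length(d) != 3L) stop("feature map must be (H, W, C)", call. = FALSE)
  n_sp <- d[1] * d[2]
  if (n_sp < 1L) stop("feature map has empty spatial extent", call. = FALSE)
  m <- fm
  dim(m) <- c(n_sp, d[3])
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(m^2) - mu^2)
  sdv[is.na(sdv) | sdv < 0] <- 0
  structure(list(mean = mu, sd = sdv), class = "channel_stats")
}

#' Adaptive instance normalization
#'
#' Re-scales each content channel to the style channel's spatial mean and
#' standard deviation, then blends with the original content features:
#' `out = alpha * t + (1 - alpha) * content` where
#' `t = sd(style) * (content - mean(content)) / sd(content) + mean(style)`.
#'
#' @param content,style Feature maps (H, W, C); spatial sizes may differ but
#'   channel counts must match.
#' @param alpha Stylization coefficient in \[0, 1\]; 1 is full style.
#' @param eps Substitute for a zero content standard deviation (a constant
#'   channel); a warning is raised when it is used.
#' @return Feature map with the dimensions of `content`.
#' @export
adain <- function(content, style, alpha = 1.0, eps = 1e-5) {
  dc <- dim(content); ds <- dim(style)
  if (length(dc) != 3L || length(ds) != 3L) {
    stop("content and style must be (H, W, C) feature maps", call. = FALSE)
  }
  if (dc[3] != ds[3]) {
    stop("channel count mismatch: content has ", dc[3], ", style has ", ds[3],
         call. = FALSE)
  }
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  cs <- channel_stats(content)
  ss <- channel_stats(style)
  sd_c <- cs$sd
  if (any(sd_c == 0)) {
    warning(warningCondition(
      paste0("constant content channel(s): substituting sd = ", eps),
      class = "retinaCL_zero_sd"))
    sd_c[sd_c == 0] <- eps
  }
  t_map <- content
  for (ch in seq_len(dc[3])) {
    t_map[, , ch] <- ss$sd[ch] * (content[, , ch] - cs$mean[ch]) / sd_c[ch] +
      ss$mean[ch]
  }
  alpha * t_map + (1 - alpha) * content
}

#' Configuration for the AdaIN coder and stylization sizes
#'
#' `content_size`/`style_size` are the working resolutions: content images
#' are resized to `content_size` and style images to the smaller
#' `style_size` before encoding (the asymmetry keeps the global geometry of
#' the content while sampling coarser style statistics). Full-scale defaults
#' are 512/128; [desk_coder_config()] gives the 64/32 desk profile used
#' throughout the tests.
#'
#' @param content_size,style_size Working resolutions in pixels (even).
#' @param feature_channels Channels of the AdaIN feature space.
#' @param hidden_channels Channels of the intermediate convolution blocks.
#' @param epochs,batch_size,lr Reconstruction-training settings (Adam).
#' @param holdout_fraction Fraction of images held out to measure the final
#'   reconstruction error.
#' @param recon_ceiling Training fails if the held-out mean squared
#'   reconstruction error does not fall below this ceiling.
#' @return List of class `coder_config`.
#' @export
coder_config <- function(content_size = 512L, style_size = 128L,
                         feature_channels = 24L, hidden_channels = 12L,
                         epochs = 30L, batch_size = 16L, lr = 1e-2,
                         holdout_fraction = 0.125, recon_ceiling = 3.5e-2) {
  structure(list(content_size = as.integer(content_size),
                 style_size = as.integer(style_size),
                 feature_channels = as.integer(feature_channels),
                 hidden_channels = as.integer(hidden_channels),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, holdout_fraction = holdout_fraction,
                 recon_ceiling = recon_ceiling),
            class = "coder_config")
}

#' Desk-profile coder configuration (64 px content, 32 px style)
#' @param ... Overrides passed to [coder_config()].
#' @export
desk_coder_config <- function(...) {
  args <- utils::modifyList(list(content_size = 64L, style_size = 32L),
                            list(...))
  do.call(coder_config, args)
}

#' Train the AdaIN coder by reconstruction
#'
#' Fits a small convolutional autoencoder (encoder: two 3x3 convolution
#' blocks at full resolution; decoder: the mirror) by mean-squared
#' reconstruction error on the supplied images. The encoder output is the
#' feature space in which [adain()] operates; keeping full spatial
#' resolution preserves small lesions through the decode, which matters
#' because stylization must change texture while keeping semantic content.
#'
#' @param images List of (H, W, 3) arrays, all the same even size; at least
#'   64 images. Mix fundus and style images so both domains reconstruct.
#' @param config A [coder_config()].
#' @param seed Integer seed (initialization, shuffling, holdout split).
#' @return Object of class `coder_spec`: encoder/decoder nets, config, loss
#'   trace and held-out reconstruction error.
#' @export
train_coder <- function(images, config = desk_coder_config(), seed = 1) {
  if (length(images) < 64L) {
    stop("need at least 64 training images, got ", length(images), call. = FALSE)
  }
  fc <- config$feature_channels; hc <- config$hidden_channels
  encoder <- nn_init(list(
    nn_conv("enc1", 3L, hc), nn_relu("encrelu1"),
    nn_conv("enc2", hc, fc), nn_relu("encrelu2")
  ), derive_seed(seed, "coder-enc"))
  decoder <- nn_init(list(
    nn_conv("dec1", fc, hc), nn_relu("decrelu1"),
    nn_conv("dec2", hc, 3L)
  ), derive_seed(seed, "coder-dec"))

  n <- length(images)
  perm <- with_seed(derive_seed(seed, "coder-split"), sample(n))
  n_hold <- max(1L, round(config$holdout_fraction * n))
  hold_idx <- perm[seq_len(n_hold)]
  train_idx <- perm[-seq_len(n_hold)]

  enc_par <- net_params(encoder); dec_par <- net_params(decoder)
  par <- c(enc_par, dec_par)
  state <- adam_init(par)
  n_enc <- length(enc_par)
  trace <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    order_ep <- with_seed(derive_seed(seed, paste0("coder-ep-", ep)),
                          sample(train_idx))
    ep_loss <- 0; n_b <- 0L
    for (start in seq(1L, length(order_ep), by = config$batch_size)) {
      ids <- order_ep[start:min(start + config$batch_size - 1L, length(order_ep))]
      x <- stack_images(images[ids])
      encoder <- net_set_params(encoder, par[seq_len(n_enc)])
      decoder <- net_set_params(decoder, par[-seq_len(n_enc)])
      ef <- net_forward(encoder, x)
      df <- net_forward(decoder, ef$out)
      resid <- df$out - x
      loss <- mean(resid^2)
      dout <- 2 * resid / length(resid)
      bd <- net_backward(decoder, df$caches, dout)
      be <- net_backward(encoder, ef$caches, bd$dx)
      upd <- adam_step(par, c(be$grads, bd$grads), state, lr = config$lr)
      par <- upd$params; state <- upd$state
      ep_loss <- ep_loss + loss; n_b <- n_b + 1L
    }
    trace <- c(trace, ep_loss / n_b)
  }
  encoder <- net_set_params(encoder, par[seq_len(n_enc)])
  decoder <- net_set_params(decoder, par[-seq_len(n_enc)])

  hold_err <- {
    x <- stack_images(images[hold_idx])
    xhat <- net_forward(decoder, net_forward(encoder, x)$out)$out
    mean((xhat - x)^2)
  }
  if (hold_err >= config$recon_ceiling) {
    stop(sprintf(paste0("coder failed to converge: held-out reconstruction ",
                        "error %.4g >= ceiling %.4g (loss trace: %s)"),
                 hold_err, config$recon_ceiling,
                 paste(signif(trace, 3), collapse = ", ")), call. = FALSE)
  }
  structure(list(encoder = encoder, decoder = decoder, config = config,
                 loss_trace = trace, holdout_error = hold_err,
                 seed = as.integer(seed)),
            class = "coder_spec")
}

encode_image <- function(coder, img) {
  fm <- net_forward(coder$encoder, array(img, dim = c(dim(img), 1L)))$out
  dim(fm) <- dim(fm)[1:3]
  fm
}

decode_features <- function(coder, fm) {
  out <- net_forward(coder$decoder, array(fm, dim = c(dim(fm), 1L)))$out
  dim(out) <- dim(out)[1:3]
  clip01(out)
}

#' Stylize a content image with AdaIN
#'
#' Content is resized to the coder's working content size and the style image
#' to the (smaller) style size; both are encoded, the AdaIN layer aligns the
#' content feature statistics to the style's with blending coefficient
#' `alpha`, the decoder renders the result, and the output is resized back
#' to the content's original size.
#'
#' @param content_image,style_image RGB arrays in \[0, 1\].
#' @param alpha Stylization coefficient in \[0, 1\] (1 = full style).
#' @param coder A trained [train_coder()] object.
#' @param return_features If `TRUE`, also return the pre-decode feature map
#'   and the style feature map (used by tests to assert the AdaIN algebra at
#'   the feature level, where it is exact regardless of decoder quality).
#' @return 8-bit-grid RGB array, or a list when `return_features = TRUE`.
#' @export
stylize <- function(content_image, style_image, alpha = 1.0, coder,
                    return_features = FALSE) {
  if (!inherits(coder, "coder_spec")) {
    stop("coder must be a trained coder_spec (see train_coder)", call. = FALSE)
  }
  stopifnot_rgb(content_image, "content_image")
  stopifnot_rgb(style_image, "style_image")
  orig <- dim(content_image)[1]
  cwork <- resize_image(content_image, coder$config$content_size)
  swork <- resize_image(style_image, coder$config$style_size)
  fc <- encode_image(coder, cwork)
  fs <- encode_image(coder, swork)
  t_map <- adain(fc, fs, alpha = alpha)
  out <- decode_features(coder, t_map)
  out <- resize_image(out, orig)
  if (return_features) {
    list(image = quantize8(out), features = t_map, style_features = fs,
         content_features = fc)
  } else {
    quantize8(out)
  }
}

#' Pre-synthesize stylized variants for a manifest
#'
#' For each record, draws `variants_per_image` styles from the bank (without
#' replacement within an image, with replacement across images), writes the
#' stylized images, and returns an index. Stylized variants are synthesized
#' in advance precisely because on-the-fly style transfer is the expensive
#' step; the pretraining loop then samples from this cache.
#'
#' @param manifest A `fundus_manifest`.
#' @param style_bank Named list of style images (see [generate_style_bank()]).
#' @param variants_per_image Number of stylized variants per record (>= 1).
#' @param alpha Stylization coefficient.
#' @param coder A trained [train_coder()] object.
#' @param out_dir Output directory.
#' @param seed Integer seed for the style draws.
#' @return Object of class `stylized_cache`: list with `index` (data.frame:
#'   image_id, variant_path, style_id, alpha) and `dir`.
#' @export
precompute_stylized <- function(manifest, style_bank, variants_per_image = 2L,
                                alpha = 1.0, coder, out_dir, seed = 1) {
  if (length(style_bank) == 0) stop("style bank is empty", call. = FALSE)
  if (variants_per_image < 1L) stop("variants_per_image must be >= 1", call. = FALSE)
  if (is.null(names(style_bank))) {
    names(style_bank) <- sprintf("style%03d", seq_along(style_bank))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (r in seq_len(nrow(manifest))) {
    id <- manifest$image_id[r]
    img <- read_image(manifest$path[r])
    k <- min(variants_per_image, length(style_bank))
    picks <- with_seed(derive_seed(seed, paste0("styles-", id)),
                       sample(names(style_bank), k, replace = FALSE))
    if (variants_per_image > k) {
      picks <- rep_len(picks, variants_per_image)
    }
    for (v in seq_along(picks)) {
      # dead (constant) feature channels are routine with ReLU features;
      # the eps-substitution warning would fire for most images here
      out <- withCallingHandlers(
        stylize(img, style_bank[[picks[v]]], alpha = alpha, coder = coder),
        retinaCL_zero_sd = function(w) invokeRestart("muffleWarning"))
      vpath <- file.path(out_dir, sprintf("%s_v%d.png", id, v))
      write_image(out, vpath)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, variant_path = vpath, style_id = picks[v],
        alpha = alpha, stringsAsFactors = FALSE)
    }
  }
  index <- do.call(rbind, rows)
  utils::write.csv(index, file.path(out_dir, "stylized_index.csv"),
                   row.names = FALSE)
  structure(list(index = index, dir = out_dir), class = "stylized_cache")
}

#' Load a stylized cache from its index CSV
#' @param dir Directory written by [precompute_stylized()].
#' @export
load_stylized_cache <- function(dir) {
  path <- file.path(dir, "stylized_index.csv")
  if (!file.exists(path)) stop("no stylized_index.csv in ", dir, call. = FALSE)
  structure(list(index = utils::read.csv(path, stringsAsFactors = FALSE),
                 dir = dir),
            class = "stylized_cache")
}

# In-memory image store for one cache (speeds up the pretraining loop).
preload_cache <- function(cache) {
  env <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(cache$index))) {
    assign(cache$index$variant_path[r], read_image(cache$index$variant_path[r]),
           envir = env)
  }
  cache$store <- env
  cache
}

cache_variant_paths <- function(cache, image_id) {
  cache$index$variant_path[cache$index$image_id == image_id]
}

cache_read <- function(cache, path) {
  if (!is.null(cache$store) && !is.null(cache$store[[path]])) {
    return(cache$store[[path]])
  }
  read_image(path)
}
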