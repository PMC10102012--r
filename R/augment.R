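# Stochastic view augmentation for contrastive pretraining and fine-tuning.

#' Augmentation policy
#'
#' Defaults follow the contrastive-pretraining recipe: random crop with
#' resize, random horizontal/vertical flips, rotation up to 30 degrees,
#' color jitter at strength 0.5, Gaussian blur, with style transfer
#' substituted for the source image with probability `nst_probability`
#' (default 0.70) before the regular chain.
#'
#' @param nst_probability Probability that a view starts from a pre-stylized
#'   variant instead of the original image.
#' @param rotation_max_deg Maximum absolute rotation, degrees.
#' @param jitter_strength Color-jitter strength; brightness/contrast/
#'   saturation factors are drawn within `0.8 * strength` of 1 and the
#'   per-channel shift within `0.2 * strength`.
#' @param blur_sigma_range Range of the Gaussian blur sigma, pixels.
#' @param blur_probability Probability of applying the blur.
#' @param crop_scale_range Range of the linear crop size as a fraction of
#'   the image side.
#' @param hflip_prob,vflip_prob Flip probabilities.
#' @param output_size Side of the square output view, pixels (224 at full
#'   scale; 32 in the desk profile).
#' @return Object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(nst_probability = 0.70,
                                rotation_max_deg = 30,
                                jitter_strength = 0.5,
                                blur_sigma_range = c(0.1, 1.0),
                                blur_probability = 0.5,
                                crop_scale_range = c(0.7, 1.0),
                                hflip_prob = 0.5,
                                vflip_prob = 0.5,
                                output_size = 224L) {
  probs <- c(nst_probability, blur_probability, hflip_prob, vflip_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (output_size <= 0) stop("output_size must be positive", call. = FALSE)
  if (rotation_max_deg < 0) stop("rotation_max_deg must be >= 0", call. = FALSE)
  structure(list(nst_probability = nst_probability,
                 rotation_max_deg = rotation_max_deg,
                 jitter_strength = jitter_strength,
                 blur_sigma_range = blur_sigma_range,
                 blur_probability = blur_probability,
                 crop_scale_range = crop_scale_range,
                 hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 output_size = as.integer(output_size)),
            class = "augmentation_policy")
}

#' Apply the regular (non-NST) augmentation chain to one image
#'
#' Order: random crop -> horizontal/vertical flip draws -> rotation uniform
#' in +/- `rotation_max_deg` -> color jitter -> Gaussian blur draw -> resize
#' to `output_size`. All draws come from the current RNG stream (or a local
#' one when `seed` is given), so a fixed stream reproduces the output
#' exactly. The draws actually taken are attached as attribute `"draws"`.
#'
#' @param image RGB array in \[0, 1\].
#' @param policy An [augmentation_policy()].
#' @param seed Optional integer; when given the function uses a local seeded
#'   stream and leaves the caller's RNG untouched.
#' @return Augmented RGB array of side `output_size`.
#' @export
regular_augment <- function(image, policy = augmentation_policy(), seed = NULL) {
  stopifnot_rgb(image)
  if (!is.null(seed)) {
    return(with_seed(seed, regular_augment(image, policy, seed = NULL)))
  }
  s <- dim(image)[1]
  draws <- list()

  # crop with resize
  scale <- stats::runif(1, policy$crop_scale_range[1], policy$crop_scale_range[2])
  side <- max(8L, round(scale * s))
  ox <- if (side < s) sample.int(s - side + 1L, 1L) else 1L
  oy <- if (side < s) sample.int(s - side + 1L, 1L) else 1L
  out <- image[ox:(ox + side - 1L), oy:(oy + side - 1L), , drop = FALSE]
  draws$crop <- c(scale = scale, ox = ox, oy = oy)

  # flips
  if (stats::runif(1) < policy$hflip_prob) {
    out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
    draws$hflip <- TRUE
  }
  if (stats::runif(1) < policy$vflip_prob) {
    out <- out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
    draws$vflip <- TRUE
  }

  # rotation
  if (policy$rotation_max_deg > 0) {
    ang <- stats::runif(1, -policy$rotation_max_deg, policy$rotation_max_deg)
    out <- rotate_image(out, ang)
    draws$rotation_deg <- ang
  }

  # color jitter (strength-scaled brightness, contrast, saturation, shift)
  st <- policy$jitter_strength
  if (st > 0) {
    f <- stats::runif(4, -1, 1)
    bright <- 1 + 0.8 * st * f[1]
    contr <- 1 + 0.8 * st * f[2]
    satur <- 1 + 0.8 * st * f[3]
    shift <- 0.2 * st * stats::runif(3, -1, 1)
    out <- out * bright
    mu <- mean(out)
    out <- (out - mu) * contr + mu
    g <- luminance(out)
    for (ch in 1:3) out[, , ch] <- g + (out[, , ch] - g) * satur + shift[ch]
    out <- clip01(out)
    draws$jitter <- c(bright = bright, contrast = contr, saturation = satur)
  }

  # blur
  if (stats::runif(1) < policy$blur_probability) {
    sg <- stats::runif(1, policy$blur_sigma_range[1], policy$blur_sigma_range[2])
    out <- blur_image(out, sg)
    draws$blur_sigma <- sg
  }

  out <- resize_image(out, policy$output_size)
  attr(out, "draws") <- draws
  out
}

#' Build a contrastive view pair for one record
#'
#' Each view independently starts from a pre-stylized variant of the source
#' (with probability `nst_probability`, uniform over the cached variants) or
#' from the original image, then passes through [regular_augment()]. The two
#' views use independent draws from the current RNG stream.
#'
#' @param record One-row manifest slice (needs `image_id`, `path`).
#' @param policy An [augmentation_policy()].
#' @param cache A `stylized_cache` (required when `nst_probability > 0`).
#' @param seed Optional integer for a local RNG stream.
#' @return Object of class `view_pair`: list(view_i, view_j, image_id,
#'   used_nst).
#' @export
make_view_pair <- function(record, policy = augmentation_policy(), cache = NULL,
                           seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed(seed, make_view_pair(record, policy, cache, seed = NULL)))
  }
  id <- record$image_id
  original <- NULL
  used <- logical(2)
  views <- vector("list", 2)
  for (v in 1:2) {
    use_nst <- policy$nst_probability > 0 &&
      stats::runif(1) < policy$nst_probability
    if (use_nst) {
      if (is.null(cache)) {
        stop("nst_probability > 0 but no stylized cache supplied", call. = FALSE)
      }
      paths <- cache_variant_paths(cache, id)
      if (length(paths) == 0) {
        stop("no stylized variants cached for image_id ", id, call. = FALSE)
      }
      pick <- paths[sample.int(length(paths), 1L)]
      src <- cache_read(cache, pick)
    } else {
      if (is.null(original)) original <- read_image(record$path)
      src <- original
    }
    used[v] <- use_nst
    views[[v]] <- regular_augment(src, policy)
  }
  structure(list(view_i = views[[1]], view_j = views[[2]],
                 image_id = id, used_nst = used),
            class = "view_pair")
}
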