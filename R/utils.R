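# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded generators never
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic sub-stream seed from a base seed and a string tag.
# Keeps results < 2^31 so set.seed() always accepts them.
derive_seed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(as.character(tag))) h <- (h * 31 + k) %% 2147480009
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147480009)
}

clip01 <- function(x) {
  # index assignment keeps dim attributes (pmin/pmax may drop them)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# Quantize to the 8-bit grid in [0,1], matching what a PNG round trip gives.
quantize8 <- function(img) round(clip01(img) * 255) / 255

is_rgb_image <- function(img) {
  is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L && is.numeric(img)
}

stopifnot_rgb <- function(img, arg = "image") {
  if (!is_rgb_image(img)) {
    stop(sprintf("`%s` must be a numeric H x W x 3 RGB array", arg), call. = FALSE)
  }
}

luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
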