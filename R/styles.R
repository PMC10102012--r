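# Procedural style textures. These stand in for an external directory of
# artistic style images: what matters for adaptive instance normalization is
# that each style supplies non-degenerate, varied per-channel feature
# statistics, which every family below guarantees by construction.

STYLE_FAMILIES <- c("noise-field", "stripes", "color-patches", "swirl")

#' Parameters for the procedural style-texture generator
#'
#' @param image_size Pixels per side; at least 32.
#' @param family One of `"noise-field"`, `"stripes"`, `"color-patches"`,
#'   `"swirl"`.
#' @param palette_seed Integer offsetting the color palette stream, so the
#'   same structural seed can be re-colored.
#' @return An object of class `style_params`.
#' @export
style_params <- function(image_size = 64, family = "noise-field", palette_seed = 0L) {
  if (image_size < 32) stop("image_size must be >= 32", call. = FALSE)
  if (!family %in% STYLE_FAMILIES) {
    stop("unknown style family: ", family, " (expected one of ",
         paste(STYLE_FAMILIES, collapse = ", "), ")", call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size), family = family,
                 palette_seed = as.integer(palette_seed)),
            class = "style_params")
}

#' Generate one style texture image
#'
#' Deterministic under `(params, seed)`; every family produces per-channel
#' pixel standard deviation > 0.
#'
#' @param params A [style_params()] object.
#' @param seed Integer seed.
#' @return H x W x 3 array on the 8-bit grid.
#' @export
generate_style <- function(params = style_params(), seed) {
  if (!inherits(params, "style_params")) stop("params must be style_params", call. = FALSE)
  s <- params$image_size
  xs <- matrix(seq_len(s), s, s) / s
  ys <- matrix(seq_len(s), s, s, byrow = TRUE) / s
  pal <- with_seed(derive_seed(seed + params$palette_seed, "palette"),
                  matrix(stats::runif(6), 2, 3))
  img <- with_seed(derive_seed(seed, paste0("style-", params$family)), {
    switch(params$family,
      "noise-field" = {
        raw <- array(stats::runif(s * s * 3), dim = c(s, s, 3))
        b <- blur_image(raw, sigma = s / 24)
        # re-stretch after blur so the texture keeps contrast
        for (ch in 1:3) {
          v <- b[, , ch]
          b[, , ch] <- (v - min(v)) / max(max(v) - min(v), 1e-8)
        }
        b
      },
      "stripes" = {
        theta <- stats::runif(1, 0, pi)
        freq <- stats::runif(1, 3, 9)
        phase <- stats::runif(1, 0, 2 * pi)
        w <- 0.5 + 0.5 * sin(2 * pi * freq * (cos(theta) * xs + sin(theta) * ys) + phase)
        out <- array(0, dim = c(s, s, 3))
        for (ch in 1:3) out[, , ch] <- pal[1, ch] * w + pal[2, ch] * (1 - w)
        out
      },
      "color-patches" = {
        k <- 7L
        out <- array(0, dim = c(s, s, 3))
        for (ch in 1:3) out[, , ch] <- stats::runif(1)
        for (p in seq_len(k)) {
          x0 <- sample.int(s, 1); y0 <- sample.int(s, 1)
          wd <- sample(seq(s %/% 6, s %/% 2), 1); ht <- sample(seq(s %/% 6, s %/% 2), 1)
          col <- stats::runif(3)
          ii <- x0:min(s, x0 + wd); jj <- y0:min(s, y0 + ht)
          for (ch in 1:3) out[ii, jj, ch] <- col[ch]
        }
        blur_image(out, sigma = 0.8)
      },
      "swirl" = {
        a <- stats::runif(1, 2, 5)
        b <- stats::runif(1, 4, 10)
        phases <- stats::runif(3, 0, 2 * pi)
        r <- sqrt((xs - 0.5)^2 + (ys - 0.5)^2)
        th <- atan2(ys - 0.5, xs - 0.5)
        out <- array(0, dim = c(s, s, 3))
        for (ch in 1:3) out[, , ch] <- 0.5 + 0.5 * sin(a * th + b * 2 * pi * r + phases[ch])
        out
      }
    )
  })
  quantize8(img)
}

#' Generate a bank of style textures cycling over all families
#'
#' @param n Number of styles.
#' @param image_size Pixels per side.
#' @param seed Integer seed.
#' @return List of `n` style images with names `style001`, ...
#' @export
generate_style_bank <- function(n, image_size = 64, seed = 1) {
  fams <- rep_len(STYLE_FAMILIES, n)
  out <- lapply(seq_len(n), function(i) {
    generate_style(style_params(image_size, fams[i]), derive_seed(seed, paste0("bank-", i)))
  })
  names(out) <- sprintf("style%03d", seq_len(n))
  out
}
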