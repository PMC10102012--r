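# Heuristic image-quality scoring implementing the stated exclusion
# criteria: uneven illumination, color distortion, low contrast, motion
# blur, missing fovea/optic-disc landmarks. Each score is a transparent,
# normalized statistic in [0, 1]; an image is excluded when its maximal
# score reaches the threshold for that criterion, and the highest-scoring
# criterion is recorded as the primary one.

QUALITY_CRITERIA <- c("uneven_illumination", "color_distortion", "low_contrast",
                      "motion_blur", "missing_landmarks")

#' Default exclusion thresholds and normalizers for quality scoring
#'
#' Normalizers map each raw statistic onto \[0, 1\] so that clean synthetic
#' fundus images score well below threshold while degraded ones saturate;
#' they were calibrated once against the default synthetic generator and are
#' plain config, not claims about any external quality algorithm.
#'
#' @param thresholds Named numeric vector of per-criterion exclusion
#'   thresholds in \[0, 1\].
#' @param illumination_norm Brightness range treated as maximal unevenness.
#' @param contrast_norm Luminance interquartile range treated as full contrast.
#' @param blur_norm Laplacian-response variance treated as fully sharp.
#' @param color_norm Total deviation of channel proportions from reference
#'   fundus chromaticity treated as maximal.
#' @param color_reference Reference RGB channel proportions of a healthy
#'   fundus (red-dominant); sums to 1.
#' @param landmark_norm Disc-template contrast treated as a certain detection.
#' @return List of class `quality_config`.
#' @export
quality_config <- function(thresholds = c(uneven_illumination = 0.85,
                                          color_distortion = 0.85,
                                          low_contrast = 0.85,
                                          motion_blur = 0.85,
                                          missing_landmarks = 0.85),
                           illumination_norm = 0.55,
                           contrast_norm = 0.18,
                           blur_norm = 2e-3,
                           color_norm = 0.45,
                           color_reference = c(0.56, 0.31, 0.13),
                           landmark_norm = 0.18) {
  stopifnot(all(QUALITY_CRITERIA %in% names(thresholds)))
  structure(list(thresholds = thresholds,
                 illumination_norm = illumination_norm,
                 contrast_norm = contrast_norm,
                 blur_norm = blur_norm,
                 color_norm = color_norm,
                 color_reference = color_reference / sum(color_reference),
                 landmark_norm = landmark_norm),
            class = "quality_config")
}

#' Score an image against the exclusion criteria
#'
#' @param image H x W x 3 RGB array in \[0, 1\].
#' @param config A [quality_config()].
#' @return Object of class `quality_report`: list with `scores` (named,
#'   in \[0,1\]), `primary_criterion`, `excluded`.
#' @export
assess_quality <- function(image, config = quality_config()) {
  stopifnot_rgb(image)
  s <- dim(image)[1]
  lum <- luminance(image)
  mask <- lum > 0.04
  if (!any(mask)) mask <- matrix(TRUE, s, dim(image)[2])

  # (a) uneven illumination: range of a coarse low-pass brightness field
  lp <- blur_image(array(rep(lum, 3), dim = c(dim(lum), 3)), sigma = s / 6)[, , 1]
  rng <- diff(range(lp[mask]))
  uneven <- clip01(rng / config$illumination_norm)

  # (b) low contrast: 1 - normalized interquartile range of luminance
  iqr <- stats::IQR(lum[mask])
  low_contrast <- clip01(1 - iqr / config$contrast_norm)

  # (c) motion blur: 1 - normalized variance of a Laplacian response
  lap <- lum[2:(s - 1), -c(1, ncol(lum))] * 4 -
    lum[1:(s - 2), -c(1, ncol(lum))] - lum[3:s, -c(1, ncol(lum))] -
    lum[2:(s - 1), 1:(ncol(lum) - 2)] - lum[2:(s - 1), 3:ncol(lum)]
  motion_blur <- clip01(1 - stats::var(as.vector(lap)) / config$blur_norm)

  # (d) color distortion: deviation of channel proportions from reference
  # fundus chromaticity (a healthy fundus is strongly red-dominant, so raw
  # channel imbalance is the norm, not a distortion)
  ch_means <- vapply(1:3, function(ch) mean(image[, , ch][mask]), numeric(1))
  props <- ch_means / (sum(ch_means) + 1e-8)
  color_distortion <- clip01(sum(abs(props - config$color_reference)) / config$color_norm)

  # (e) missing landmarks: bright-disc template score inside the aperture
  rad <- max(2L, round(0.075 * s))
  centers <- expand.grid(
    x = seq(rad + 1, s - rad, by = max(1L, rad %/% 2)),
    y = seq(rad + 1, s - rad, by = max(1L, rad %/% 2))
  )
  base_lum <- mean(lum[mask])
  best <- -Inf
  for (r in seq_len(nrow(centers))) {
    cxx <- centers$x[r]; cyy <- centers$y[r]
    win <- lum[(cxx - rad):(cxx + rad), (cyy - rad):(cyy + rad)]
    best <- max(best, mean(win) - base_lum)
  }
  missing_landmarks <- clip01(1 - best / config$landmark_norm)

  scores <- c(uneven_illumination = uneven,
              color_distortion = color_distortion,
              low_contrast = low_contrast,
              motion_blur = motion_blur,
              missing_landmarks = missing_landmarks)
  primary <- names(scores)[which.max(scores)]
  excluded <- any(scores >= config$thresholds[names(scores)])
  structure(list(scores = scores, primary_criterion = primary,
                 excluded = excluded),
            class = "quality_report")
}

#' Drop excluded records from a manifest
#'
#' @param manifest A `fundus_manifest`.
#' @param reports List of [assess_quality()] reports, one per record, in
#'   manifest order.
#' @return The surviving manifest with attribute `exclusion_log`, a
#'   data.frame of (criterion, count): each removed image is counted once,
#'   under its primary criterion, even when several criteria fired.
#' @export
apply_exclusion <- function(manifest, reports) {
  if (length(reports) != nrow(manifest)) {
    stop("need exactly one quality report per manifest record", call. = FALSE)
  }
  excluded <- vapply(reports, function(r) isTRUE(r$excluded), logical(1))
  primary <- vapply(reports, function(r) r$primary_criterion, character(1))
  log <- data.frame(criterion = QUALITY_CRITERIA,
                    count = vapply(QUALITY_CRITERIA, function(cr) {
                      sum(excluded & primary == cr)
                    }, numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- subset_manifest(manifest, !excluded)
  attr(out, "exclusion_log") <- log
  out
}
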