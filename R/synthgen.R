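# Seeded synthetic fundus-image generator.
#
# The generator is built so that *shape* carries the class signal and
# *texture/color* is a class-independent nuisance: referable grades (>= 2)
# receive hemorrhage blobs and exudate patches, mild disease receives a
# couple of microaneurysm dots, while every image — whatever its grade —
# gets an independent smooth color/texture field, an illumination gradient
# and a background tint drawn from RNG streams that never see the grade.
# This is exactly the regime style-transfer augmentation targets: a
# texture-biased encoder can latch onto the nuisance field, a shape-biased
# one has to find the lesions and vasculature.

#' Parameters for the synthetic fundus generator
#'
#' @param image_size Pixels per (square) side; at least 32.
#' @param vessel_count Number of major vessel branches leaving the optic disc.
#' @param lesion_count_by_grade Named list mapping grades `"0"`..`"4"` to
#'   `c(min, max)` lesion counts. Grade 0 must be `c(0, 0)` and ranges must be
#'   non-decreasing with grade.
#' @param illumination_amplitude Peak-to-peak amplitude of the smooth
#'   illumination gradient, as a fraction of dynamic range in \[0, 1\].
#' @param nuisance_texture Whether to overlay the class-independent smooth
#'   color/texture field.
#' @param texture_scale Correlation length of the nuisance field, in pixels.
#' @param texture_amplitude Amplitude of the nuisance field (fraction of
#'   dynamic range). The default makes texture the dominant low-level cue —
#'   stronger than any single lesion — so the images actually sit in the
#'   texture-confounded regime the generator is meant to emulate.
#' @param background_tint_jitter Per-channel background tint jitter amplitude
#'   (fraction of dynamic range in \[0, 1\]).
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(image_size = 64,
                         vessel_count = 6,
                         lesion_count_by_grade = list(
                           "0" = c(0, 0),
                           "1" = c(1, 2),
                           "2" = c(3, 6),
                           "3" = c(6, 10),
                           "4" = c(10, 16)
                         ),
                         illumination_amplitude = 0.25,
                         nuisance_texture = TRUE,
                         texture_scale = 8,
                         texture_amplitude = 0.25,
                         background_tint_jitter = 0.15) {
  if (image_size < 32) stop("image_size must be >= 32", call. = FALSE)
  if (!setequal(names(lesion_count_by_grade), as.character(0:4))) {
    stop("lesion_count_by_grade must have entries for grades 0..4", call. = FALSE)
  }
  rng <- lapply(as.character(0:4), function(g) lesion_count_by_grade[[g]])
  if (!all(rng[[1]] == c(0, 0))) {
    stop("grade-0 lesion count range must be (0, 0)", call. = FALSE)
  }
  mins <- vapply(rng, `[`, numeric(1), 1L)
  maxs <- vapply(rng, `[`, numeric(1), 2L)
  if (any(mins > maxs)) stop("lesion count min > max", call. = FALSE)
  if (is.unsorted(mins) || is.unsorted(maxs)) {
    stop("lesion count ranges must be non-decreasing in grade", call. = FALSE)
  }
  if (illumination_amplitude < 0 || illumination_amplitude > 1) {
    stop("illumination_amplitude must lie in [0, 1]", call. = FALSE)
  }
  if (background_tint_jitter < 0 || background_tint_jitter > 1) {
    stop("background_tint_jitter must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    image_size = as.integer(image_size),
    vessel_count = as.integer(vessel_count),
    lesion_count_by_grade = stats::setNames(rng, as.character(0:4)),
    illumination_amplitude = illumination_amplitude,
    nuisance_texture = isTRUE(nuisance_texture),
    texture_scale = texture_scale,
    texture_amplitude = texture_amplitude,
    background_tint_jitter = background_tint_jitter
  ), class = "synth_params")
}

# Stamp a soft (Gaussian-profile) disc onto `field`, returning the field.
stamp_disc <- function(field, cx, cy, radius, height = 1) {
  s <- nrow(field)
  r <- max(radius, 0.6)
  i0 <- max(1L, floor(cx - 3 * r)); i1 <- min(s, ceiling(cx + 3 * r))
  j0 <- max(1L, floor(cy - 3 * r)); j1 <- min(s, ceiling(cy + 3 * r))
  if (i0 > i1 || j0 > j1) return(field)
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer((ii - cx)^2, (jj - cy)^2, `+`)
  field[ii, jj] <- field[ii, jj] + height * exp(-d2 / (2 * (r / 1.6)^2))
  field
}

# Smooth, zero-mean random field with the given correlation length.
smooth_field <- function(size, scale) {
  coarse <- max(2L, ceiling(size / max(scale, 2)))
  base <- array(stats::runif(coarse * coarse * 3, -1, 1), dim = c(coarse, coarse, 3))
  up <- EBImage::resize(base, w = size, h = size)
  up <- as.numeric_array(up)
  up <- blur_image((up + 1) / 2, sigma = max(1, scale / 3)) * 2 - 1
  up - mean(up)
}

#' Generate one synthetic fundus image
#'
#' Renders a circular retinal field on a dark background with an optic disc,
#' fovea, branching vessel tree, grade-dependent lesions, and
#' grade-independent nuisance (tint, illumination gradient, texture field).
#' Identical `(params, grade, seed)` give bit-identical 8-bit pixels. A
#' ground-truth log of every drawn object is returned alongside the pixels so
#' tests can reason about content without reading pixels.
#'
#' @param params A [synth_params()] object.
#' @param grade Integer DR grade in 0..4.
#' @param seed Integer seed.
#' @return An object of class `image_record`: list with `image` (H x W x 3
#'   array on the 8-bit grid), `dr_grade`, `referable`, `objects`
#'   (data.frame log: type, x, y, radius, polarity), `seed`.
#' @export
generate_fundus <- function(params = synth_params(), grade, seed) {
  if (!inherits(params, "synth_params")) stop("params must be synth_params", call. = FALSE)
  if (length(grade) != 1L || is.na(grade) || grade %% 1 != 0 || grade < 0 || grade > 4) {
    stop("grade must be a single integer in 0..4", call. = FALSE)
  }
  grade <- as.integer(grade)
  s <- params$image_size
  cx <- (s + 1) / 2
  xs <- matrix(seq_len(s), s, s)          # row coordinate
  ys <- matrix(seq_len(s), s, s, byrow = TRUE)
  aperture_r <- 0.47 * s
  dist_c <- sqrt((xs - cx)^2 + (ys - cx)^2)
  mask <- dist_c <= aperture_r

  objects <- list()

  ## --- nuisance streams: keyed by seed only, never by grade -------------
  tint <- with_seed(derive_seed(seed, "tint"), {
    stats::runif(3, -1, 1) * params$background_tint_jitter
  })
  illum <- with_seed(derive_seed(seed, "illum"), {
    theta <- stats::runif(1, 0, 2 * pi)
    proj <- cos(theta) * (xs - cx) + sin(theta) * (ys - cx)
    proj <- (proj - min(proj)) / (max(proj) - min(proj))
    1 - params$illumination_amplitude * proj
  })
  texture <- if (params$nuisance_texture) {
    with_seed(derive_seed(seed, "texture"), smooth_field(s, params$texture_scale))
  } else {
    array(0, dim = c(s, s, 3))
  }

  ## --- anatomy: keyed by seed only (shape carries no label either, only
  ## lesions do) ----------------------------------------------------------
  anatomy <- with_seed(derive_seed(seed, "anatomy"), {
    side <- sample(c(-1, 1), 1)                    # nasal side left or right
    disc_d <- stats::runif(1, 0.5, 0.62) * aperture_r
    disc_x <- cx + stats::runif(1, -0.15, 0.15) * aperture_r
    disc_y <- cx + side * disc_d
    disc_r <- 0.16 * aperture_r
    fov_x <- cx + stats::runif(1, -0.05, 0.05) * s
    fov_y <- cx - (disc_y - cx) * 0.8
    fov_r <- 0.2 * aperture_r

    vessel <- matrix(0, s, s)
    n_steps <- max(16L, as.integer(s * 0.9))
    for (v in seq_len(params$vessel_count)) {
      ang <- atan2(cx - disc_x, cx - disc_y) +
        stats::runif(1, -1.3, 1.3)
      px <- disc_x; py <- disc_y
      w0 <- stats::runif(1, 0.9, 1.6) * s / 64
      for (t in seq_len(n_steps)) {
        ang <- ang + stats::rnorm(1, 0, 0.18)
        px <- px + sin(ang); py <- py + cos(ang)
        if (sqrt((px - cx)^2 + (py - cx)^2) > aperture_r * 0.96) break
        vessel <- stamp_disc(vessel, px, py, w0 * (1 - 0.5 * t / n_steps), 1)
      }
    }
    list(disc_x = disc_x, disc_y = disc_y, disc_r = disc_r,
         fov_x = fov_x, fov_y = fov_y, fov_r = fov_r,
         vessel = pmin(vessel, 1))
  })

  ## --- lesions: the only grade-coupled stream ---------------------------
  lesions <- with_seed(derive_seed(seed, paste0("lesions-", grade)), {
    rng <- params$lesion_count_by_grade[[as.character(grade)]]
    n_les <- if (rng[2] > rng[1]) sample(rng[1]:rng[2], 1L) else rng[1]
    out <- list()
    if (n_les > 0) {
      for (i in seq_len(n_les)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * 0.8 * aperture_r
        lx <- cx + cos(ang) * rad
        ly <- cx + sin(ang) * rad
        type <- if (grade <= 1) {
          "microaneurysm"
        } else {
          sample(c("microaneurysm", "hemorrhage", "exudate"), 1L,
                 prob = c(0.3, 0.4, 0.3))
        }
        lr <- switch(type,
          microaneurysm = stats::runif(1, 0.8, 1.3) * s / 48,
          hemorrhage = stats::runif(1, 1.8, 3.2) * s / 48,
          exudate = stats::runif(1, 1.6, 2.8) * s / 48
        )
        out[[i]] <- data.frame(
          type = type, x = lx, y = ly, radius = lr,
          polarity = if (type == "exudate") "bright" else "dark",
          stringsAsFactors = FALSE
        )
      }
    }
    out
  })

  ## --- compose ----------------------------------------------------------
  base_col <- clip01(c(0.72, 0.40, 0.16) + tint)
  img <- array(0, dim = c(s, s, 3))
  for (ch in 1:3) img[, , ch] <- base_col[ch] * illum

  # retinal depth shading toward the rim
  rim <- clip01(1 - 0.55 * (dist_c / aperture_r)^4)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * rim

  # optic disc (bright) and fovea (dark)
  disc <- stamp_disc(matrix(0, s, s), anatomy$disc_x, anatomy$disc_y,
                     anatomy$disc_r, 1)
  fov <- stamp_disc(matrix(0, s, s), anatomy$fov_x, anatomy$fov_y,
                    anatomy$fov_r, 1)
  disc_col <- c(0.98, 0.88, 0.55)
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - pmin(disc, 1)) + disc_col[ch] * pmin(disc, 1)
    img[, , ch] <- img[, , ch] * (1 - 0.45 * pmin(fov, 1))
  }

  # vessels (dark red)
  ves_col <- c(0.34, 0.08, 0.06)
  a <- 0.85 * anatomy$vessel
  for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - a) + ves_col[ch] * a

  # lesions
  for (les in lesions) {
    m <- pmin(stamp_disc(matrix(0, s, s), les$x, les$y, les$radius, 1), 1)
    lcol <- if (les$polarity == "bright") c(0.98, 0.95, 0.45) else c(0.28, 0.04, 0.04)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.9 * m) + lcol[ch] * 0.9 * m
    objects[[length(objects) + 1L]] <- les
  }

  # nuisance texture, additive inside the aperture
  if (params$nuisance_texture) img <- img + params$texture_amplitude * texture

  # aperture: dark background outside
  for (ch in 1:3) img[, , ch] <- ifelse(mask, img[, , ch], 0.015)

  obj_df <- if (length(objects)) {
    do.call(rbind, objects)
  } else {
    data.frame(type = character(), x = numeric(), y = numeric(),
               radius = numeric(), polarity = character(),
               stringsAsFactors = FALSE)
  }

  structure(list(
    image = quantize8(img),
    image_id = NA_character_,
    dr_grade = grade,
    referable = grade >= 2L,
    objects = obj_df,
    seed = as.integer(seed)
  ), class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record> grade %d (%s), %d x %d, %d lesion(s)\n",
              x$dr_grade, if (x$referable) "referable" else "non-referable",
              dim(x$image)[1], dim(x$image)[2], nrow(x$objects)))
  invisible(x)
}

#' Generate a labeled synthetic dataset on disk
#'
#' Draws grades from a seeded multinomial, renders each image with its own
#' derived seed, writes PNGs plus one ground-truth JSON sidecar per image,
#' and writes a manifest CSV.
#'
#' @param n Number of images (>= 0).
#' @param grade_distribution Probabilities for grades 0..4; must sum to 1
#'   within 1e-9.
#' @param params A [synth_params()] object.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return The manifest (see [load_manifest()]) with attribute
#'   `grade_counts`, the multinomial draw actually used.
#' @export
generate_dataset <- function(n, grade_distribution = c(0.5, 0.2, 0.15, 0.1, 0.05),
                             params = synth_params(), out_dir, seed) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (length(grade_distribution) != 5L ||
      abs(sum(grade_distribution) - 1) > 1e-9 || any(grade_distribution < 0)) {
    stop("grade_distribution must be 5 probabilities summing to 1", call. = FALSE)
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create out_dir: ", out_dir, call. = FALSE)
  }
  counts <- if (n > 0) {
    as.integer(with_seed(derive_seed(seed, "grades"),
                         stats::rmultinom(1, n, grade_distribution)))
  } else {
    integer(5)
  }
  grades <- rep(0:4, times = counts)
  if (n > 0) {
    grades <- with_seed(derive_seed(seed, "order"), sample(grades))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("img%05d", i)
    rec <- generate_fundus(params, grades[i], derive_seed(seed, paste0("img-", i)))
    img_path <- file.path(out_dir, paste0(id, ".png"))
    write_image(rec$image, img_path)
    jsonlite::write_json(
      list(image_id = id, dr_grade = rec$dr_grade, seed = rec$seed,
           objects = rec$objects),
      file.path(out_dir, paste0(id, ".json")),
      auto_unbox = TRUE, digits = NA
    )
    rows[[i]] <- data.frame(
      image_id = id, path = img_path, dr_grade = grades[i],
      referable = grades[i] >= 2L, split = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  df <- if (n > 0) do.call(rbind, rows) else {
    data.frame(image_id = character(), path = character(),
               dr_grade = integer(), referable = logical(),
               split = character(), stringsAsFactors = FALSE)
  }
  man <- as_manifest(df, provenance = sprintf("synthetic (seed %s)", seed))
  attr(man, "grade_counts") <- stats::setNames(counts, as.character(0:4))
  jsonlite::write_json(
    list(seed = as.integer(seed), n = as.integer(n),
         grade_counts = stats::setNames(as.list(counts), as.character(0:4))),
    file.path(out_dir, "runlog.json"), auto_unbox = TRUE
  )
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  man
}

#' Read the ground-truth sidecar log for one generated image
#' @param manifest A manifest from [generate_dataset()].
#' @param image_id Image id.
#' @return List with `dr_grade`, `seed` and the `objects` data.frame.
#' @export
read_object_log <- function(manifest, image_id) {
  row <- manifest[manifest$image_id == image_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown image_id: ", image_id, call. = FALSE)
  path <- sub("\\.png$", ".json", row$path)
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(out$objects) == 0) {
    out$objects <- data.frame(type = character(), x = numeric(), y = numeric(),
                              radius = numeric(), polarity = character())
  }
  out
}
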