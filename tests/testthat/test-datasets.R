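test_that("grade maps to referable at the moderate-NPDR boundary", {
  expect_true(grade_to_referable(2))
  expect_false(grade_to_referable(0))
  expect_false(grade_to_referable(1))
  expect_equal(grade_to_referable(0:4), c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_error(grade_to_referable(5), "0..4")
  expect_error(grade_to_referable(-1), "0..4")
})

test_that("manifest round trip preserves fields and enforces invariants", {
  df <- data.frame(image_id = c("a", "b", "c"),
                   path = c("a.png", "b.png", "c.png"),
                   dr_grade = c(0L, 2L, 4L),
                   referable = c(FALSE, TRUE, TRUE),
                   split = NA_character_, stringsAsFactors = FALSE)
  man <- as_manifest(df)
  path <- tempfile(fileext = ".csv")
  write_manifest(man, path)
  back <- load_manifest(path, check_paths = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(man), ignore_attr = TRUE)

  bad_grade <- df; bad_grade$dr_grade[2] <- 5L
  expect_error(as_manifest(bad_grade), "row\\(s\\): 2")

  contradiction <- df; contradiction$referable[3] <- FALSE
  expect_error(as_manifest(contradiction), "contradicts.*3")

  dup <- rbind(df, df[1, ])
  expect_error(as_manifest(dup), "duplicate")

  missing_col <- df[, -3]
  expect_error(as_manifest(missing_col), "missing column")

  expect_error(load_manifest(path, check_paths = TRUE), "missing image file")
})

test_that("k-fold splits are stratified partitions, deterministic in seed", {
  man <- synthetic_manifest(70, 30)
  folds <- kfold_split(man, k = 5, seed = 3)
  expect_length(folds, 5)
  for (f in folds) {
    expect_equal(nrow(f$validation), 20)
    expect_equal(sum(f$validation$referable), 6)
    expect_equal(sum(!f$validation$referable), 14)
    expect_equal(nrow(f$train) + nrow(f$validation), 100)
    expect_length(intersect(f$train$image_id, f$validation$image_id), 0)
  }
  all_val <- sort(unlist(lapply(folds, function(f) f$validation$image_id)))
  expect_equal(all_val, sort(man$image_id))

  folds2 <- kfold_split(man, k = 5, seed = 3)
  expect_identical(lapply(folds, function(f) f$validation$image_id),
                   lapply(folds2, function(f) f$validation$image_id))

  tiny <- synthetic_manifest(10, 3)
  expect_error(kfold_split(tiny, k = 5, seed = 1), "fewer than k")
})

test_that("label-fraction subsampling is stratified, rounded, and nested", {
  man <- synthetic_manifest(70, 30)
  expect_equal(nrow(subsample_label_fraction(man, 1.0, seed = 1)), 100)

  s10 <- subsample_label_fraction(man, 0.1, seed = 1)
  expect_equal(nrow(s10), 10)
  expect_equal(sum(s10$referable), 3)
  expect_equal(sum(!s10$referable), 7)

  s20 <- subsample_label_fraction(man, 0.2, seed = 1)
  expect_true(all(s10$image_id %in% s20$image_id))
  # nestedness holds across the whole fraction ladder for a fixed seed
  prev <- s10$image_id
  for (fr in seq(0.2, 1, by = 0.1)) {
    cur <- subsample_label_fraction(man, fr, seed = 1)$image_id
    expect_true(all(prev %in% cur), info = paste("fraction", fr))
    prev <- cur
  }
  # a different seed gives a different (but equally sized) subsample
  other <- subsample_label_fraction(man, 0.1, seed = 2)
  expect_equal(nrow(other), 10)

  expect_error(subsample_label_fraction(man, 0, seed = 1), "fraction")
  expect_error(subsample_label_fraction(man, 1.2, seed = 1), "fraction")
  expect_error(subsample_label_fraction(synthetic_manifest(70, 4), 0.1, 1),
               "class size")
})

test_that("quality scores react to the defects they name", {
  p <- desk_params()
  clean <- generate_fundus(p, 0, seed = 1)$image
  q <- assess_quality(clean)
  expect_false(q$excluded)
  expect_true(all(q$scores >= 0 & q$scores <= 1))
  expect_equal(q$primary_criterion, names(which.max(q$scores)))

  # Laplacian-variance monotonicity: smoothing raises the blur score
  q_blur <- assess_quality(retinaCL:::blur_image(clean, 3))
  expect_gt(q_blur$scores["motion_blur"], q$scores["motion_blur"])

  # uniform gray disc: zero interquartile range => maximal low-contrast
  gray <- array(0.5, dim = c(32, 32, 3))
  expect_equal(unname(assess_quality(gray)$scores["low_contrast"]), 1)

  # swapping R and B channels is a gross color cast
  q_swap <- assess_quality(clean[, , c(3, 2, 1)])
  expect_gt(q_swap$scores["color_distortion"], q$scores["color_distortion"])
  expect_true(q_swap$excluded)

  expect_error(assess_quality(matrix(0.5, 8, 8)), "RGB")
})

test_that("exclusion drops flagged records and logs one count per image", {
  man <- synthetic_manifest(8, 2)
  mk_report <- function(excluded, primary) {
    scores <- stats::setNames(rep(0.1, 5), retinaCL:::QUALITY_CRITERIA)
    scores[primary] <- if (excluded) 0.95 else 0.4
    structure(list(scores = scores, primary_criterion = primary,
                   excluded = excluded), class = "quality_report")
  }
  reports <- c(
    lapply(1:3, function(i) mk_report(TRUE, "motion_blur")),
    lapply(4:10, function(i) mk_report(FALSE, "low_contrast"))
  )
  out <- apply_exclusion(man, reports)
  expect_equal(nrow(out), 7)
  log <- attr(out, "exclusion_log")
  expect_equal(sum(log$count), 3)
  expect_equal(log$count[log$criterion == "motion_blur"], 3)

  # identity when nothing is excluded
  ok <- lapply(1:10, function(i) mk_report(FALSE, "low_contrast"))
  expect_equal(nrow(apply_exclusion(man, ok)), 10)

  # an image over threshold on two criteria counts once, under its primary
  multi <- mk_report(TRUE, "color_distortion")
  multi$scores["motion_blur"] <- 0.9
  out2 <- apply_exclusion(man, c(list(multi), reports[-1]))
  log2 <- attr(out2, "exclusion_log")
  expect_equal(sum(log2$count), 3)
  expect_equal(log2$count[log2$criterion == "color_distortion"], 1)

  expect_error(apply_exclusion(man, reports[1:5]), "one quality report per")
})
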