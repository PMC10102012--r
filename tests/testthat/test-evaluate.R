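# Exhaustive-oracle checks for the ROC machinery, plus cross-checks against
# pROC (an independent implementation, never the one under test).

auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

youden_scan_oracle <- function(scores, labels) {
  best <- NULL
  for (t in sort(unique(scores), decreasing = TRUE)) {
    sens <- mean(scores[labels] >= t)
    spec <- mean(scores[!labels] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j ||
        (j == best$j &&
           (sens > best$sensitivity ||
              (sens == best$sensitivity && t < best$threshold)))) {
      best <- list(threshold = t, j = j, sensitivity = sens,
                   specificity = spec)
    }
  }
  best
}

test_that("AUC equals Mann-Whitney pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.6, 0.1, 0.3, 0.7),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc, 8 / 9)
  expect_equal(roc_auc(rep(0.4, 8), rep(c(TRUE, FALSE), 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), "both classes")
  expect_error(roc_auc(c(1, Inf), c(TRUE, FALSE)), "finite")

  set.seed(12)
  for (r in 1:200) {
    m <- sample(2:20, 1); n <- sample(2:20, 1)
    scores <- round(c(rnorm(m, 0.5), rnorm(n)), sample(c(1, 2, 8), 1))
    labels <- rep(c(TRUE, FALSE), c(m, n))
    expect_equal(roc_auc(scores, labels)$auc, auc_pair_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("the Youden point matches an exhaustive threshold scan", {
  rc <- roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(youden(rc)$j, 1)

  # tie case: J = 2/3 at two thresholds; higher sensitivity wins
  rc2 <- roc_auc(c(0.9, 0.8, 0.6, 0.1, 0.3, 0.7),
                 c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  y2 <- youden(rc2)
  expect_equal(y2$j, 2 / 3, tolerance = 1e-12)
  expect_equal(y2$sensitivity, 1)
  expect_equal(y2$specificity, 2 / 3, tolerance = 1e-12)

  set.seed(77)
  for (r in 1:100) {
    m <- sample(3:15, 1); n <- sample(3:15, 1)
    scores <- round(c(rnorm(m, 0.8), rnorm(n)), sample(1:2, 1))
    labels <- rep(c(TRUE, FALSE), c(m, n))
    got <- youden(roc_auc(scores, labels))
    want <- youden_scan_oracle(scores, labels)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("DeLong intervals match an independent implementation and widen with small n", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- c(rnorm(200, 1), rnorm(200))
  labels <- rep(c(TRUE, FALSE), each = 200)
  ci <- auc_ci_delong(scores, labels)
  ref <- as.numeric(pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE),
                                 method = "delong"))
  expect_equal(c(ci$lower, ci$auc, ci$upper), ref, tolerance = 1e-10)

  small <- c(1:20, 21:40)
  idx <- c(sample(which(labels), 20), sample(which(!labels), 20))
  ci_small <- auc_ci_delong(scores[idx], labels[idx])
  expect_gt(ci_small$upper - ci_small$lower, ci$upper - ci$lower)

  expect_warning(auc_ci_delong(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
                 "degenerate")
})

test_that("DeLong CI covers a bootstrap interval's center on overlapping scores", {
  set.seed(41)
  scores <- c(rnorm(200, 0.8), rnorm(200))
  labels <- rep(c(TRUE, FALSE), each = 200)
  dl <- auc_ci_delong(scores, labels)
  bs <- auc_ci_bootstrap(scores, labels, n_boot = 2000, seed = 7)
  mid <- (bs$lower + bs$upper) / 2
  expect_lt(abs(mid - (dl$lower + dl$upper) / 2), 0.02)
})

test_that("the paired DeLong test behaves as a test should", {
  skip_if_not_installed("pROC")
  set.seed(9)
  labels <- rep(c(TRUE, FALSE), each = 150)
  a <- ifelse(labels, rnorm(300, 1.2), rnorm(300))[seq_along(labels)]
  a <- c(rnorm(150, 1.2), rnorm(150))
  b <- 0.4 * a + rnorm(300, 0, 1.2)

  same <- delong_test(a, a, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  ab <- delong_test(a, b, labels)
  ba <- delong_test(b, a, labels)
  expect_equal(ba$z, -ab$z)
  expect_equal(ba$p, ab$p)

  ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE),
                        pROC::roc(labels, b, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(ab$z, as.numeric(ref$statistic), tolerance = 1e-10)
  expect_equal(ab$p, ref$p.value, tolerance = 1e-10)

  # strongly separated generators: the difference is detected
  set.seed(10)
  lab2 <- rep(c(TRUE, FALSE), each = 300)
  strong <- c(rnorm(300, 1.81), rnorm(300))   # true AUC ~ 0.9
  weak <- c(rnorm(300, 0.36), rnorm(300))     # true AUC ~ 0.6
  expect_lt(delong_test(strong, weak, lab2)$p, 0.01)

  expect_error(delong_test(a[-1], b, labels), "paired")
})

test_that("DeLong CI coverage sits near nominal on binormal scores", {
  # true AUC of the binormal model with unit variances: pnorm(mu / sqrt(2))
  mu <- 1.0
  true_auc <- stats::pnorm(mu / sqrt(2))
  set.seed(2024)
  hits <- 0L
  n_sim <- 300L
  for (r in seq_len(n_sim)) {
    sc <- c(rnorm(60, mu), rnorm(60))
    lb <- rep(c(TRUE, FALSE), each = 60)
    ci <- auc_ci_delong(sc, lb)
    if (ci$lower <= true_auc && true_auc <= ci$upper) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.92)
  expect_lte(hits / n_sim, 0.98)
})

test_that("report writing renders curves, JSON and the pairwise table", {
  set.seed(3)
  labels <- rep(c(TRUE, FALSE), each = 60)
  sc <- list(good = c(rnorm(60, 1.5), rnorm(60)),
             fair = c(rnorm(60, 0.7), rnorm(60)),
             poor = c(rnorm(60, 0.1), rnorm(60)))
  out <- file.path(tempdir(), "rocrep")
  res <- make_report(sc, labels, out, seed = 4)
  expect_length(res$reports, 3)
  expect_equal(nrow(res$pairwise), 3)   # C(3, 2)
  expect_true(all(file.exists(file.path(out, c(
    "good_report.json", "fair_curve.csv", "pairwise_delong.csv",
    "roc_curves.png")))))
  back <- jsonlite::read_json(file.path(out, "good_report.json"))
  expect_equal(back$auc, res$reports$good$auc)

  one <- make_report(sc["good"], labels, file.path(tempdir(), "rocrep1"))
  expect_equal(nrow(one$pairwise), 0)

  rp <- roc_report(sc$fair, labels, ci_method = "bootstrap", n_boot = 200)
  expect_lte(rp$ci["lower"], rp$auc)
  expect_gte(rp$ci["upper"], rp$auc)
  expect_equal(rp$youden_j, rp$sensitivity + rp$specificity - 1,
               tolerance = 1e-12)
})
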