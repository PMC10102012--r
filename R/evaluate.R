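# ROC analysis: Mann-Whitney AUC, DeLong confidence intervals and paired
# tests, Youden operating points, and report rendering.

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  labels <- as.logical(labels)
  if (all(labels) || !any(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  labels
}

#' ROC curve and AUC
#'
#' Thresholds are the distinct scores; a record is called positive when its
#' score is >= the threshold. The AUC equals the Mann-Whitney statistic:
#' the fraction of positive-negative pairs ranked correctly, ties counting
#' one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) class labels.
#' @return Object of class `roc_curve`: data.frame `curve` (threshold,
#'   sensitivity, specificity) plus `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  r <- rank(scores)                       # midranks handle ties as 1/2
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1))
  structure(list(curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

# DeLong structural components: V10 (per positive) and V01 (per negative).
delong_components <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi),
       auc = mean(psi), m = length(x), n = length(y))
}

#' DeLong confidence interval for one AUC
#'
#' Normal-approximation interval using the DeLong structural-components
#' variance, clipped to \[0, 1\]. With zero variance (perfect separation)
#' the interval collapses to the point estimate with a warning.
#'
#' @param scores,labels As in [roc_auc()]; each class needs >= 2 members.
#' @param level Confidence level.
#' @return List: `auc`, `lower`, `upper`, `se`.
#' @export
auc_ci_delong <- function(scores, labels, level = 0.95) {
  labels <- check_scores_labels(scores, labels)
  if (sum(labels) < 2L || sum(!labels) < 2L) {
    stop("need >= 2 members per class for a DeLong interval", call. = FALSE)
  }
  dc <- delong_components(scores, labels)
  v <- stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n
  if (v <= 0) {
    warning("degenerate DeLong variance: interval collapses to the AUC point")
    return(list(auc = dc$auc, lower = dc$auc, upper = dc$auc, se = 0))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(v)
  list(auc = dc$auc, lower = max(0, dc$auc - z * se),
       upper = min(1, dc$auc + z * se), se = se)
}

#' Youden operating point
#'
#' Maximizes J = sensitivity + specificity - 1 over the curve's thresholds.
#' Ties are broken by higher sensitivity, then by lower threshold.
#'
#' @param curve A `roc_curve` from [roc_auc()].
#' @return List: `threshold`, `j`, `sensitivity`, `specificity`.
#' @export
youden <- function(curve) {
  cv <- curve$curve
  if (!nrow(cv)) stop("empty ROC curve", call. = FALSE)
  j <- cv$sensitivity + cv$specificity - 1
  ord <- order(-j, -cv$sensitivity, cv$threshold)
  b <- ord[1]
  list(threshold = cv$threshold[b], j = j[b],
       sensitivity = cv$sensitivity[b], specificity = cv$specificity[b])
}

#' Paired DeLong test for two correlated AUCs
#'
#' Both score vectors must be computed on the same records (same labels);
#' the covariance of the two AUC estimators is estimated from the paired
#' structural components.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Common labels.
#' @return Object of class `delong_result`: `auc_a`, `auc_b`, `diff`,
#'   `var_diff`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("scores_a and scores_b must be paired (equal length)", call. = FALSE)
  }
  labels <- check_scores_labels(scores_a, labels)
  check_scores_labels(scores_b, labels)
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(da$v10, db$v10))
  s01 <- stats::cov(cbind(da$v01, db$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / da$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / da$n
  d <- da$auc - db$auc
  if (var_diff <= 0) {
    z <- if (abs(d) < .Machine$double.eps^0.5) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(auc_a = da$auc, auc_b = db$auc, diff = d,
                 var_diff = max(var_diff, 0), z = z, p = p),
            class = "delong_result")
}

#' Bootstrap confidence interval for an AUC (alternative to DeLong)
#'
#' Stratified nonparametric bootstrap (resampling within class).
#'
#' @param scores,labels As in [roc_auc()].
#' @param level Confidence level.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return List: `auc`, `lower`, `upper`.
#' @export
auc_ci_bootstrap <- function(scores, labels, level = 0.95, n_boot = 2000L,
                             seed = 1) {
  labels <- check_scores_labels(scores, labels)
  ip <- which(labels); ineg <- which(!labels)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
      roc_auc(scores[idx], labels[idx])$auc
    }, numeric(1))
  })
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(auc = roc_auc(scores, labels)$auc, lower = qs[1], upper = qs[2])
}

#' Full ROC report for one model
#'
#' AUC with a 95 percent CI (DeLong by default, bootstrap optional), the
#' Youden operating point, and stratified-bootstrap CIs for sensitivity and
#' specificity at that operating point.
#'
#' @param scores,labels As in [roc_auc()].
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param n_boot Bootstrap replicates for the operating-point CIs.
#' @param seed Integer seed for the bootstraps.
#' @return Object of class `roc_report`.
#' @export
roc_report <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                       n_boot = 2000L, seed = 1) {
  ci_method <- match.arg(ci_method)
  labels <- check_scores_labels(scores, labels)
  rc <- roc_auc(scores, labels)
  ci <- if (ci_method == "delong") {
    auc_ci_delong(scores, labels)
  } else {
    auc_ci_bootstrap(scores, labels, n_boot = n_boot, seed = seed)
  }
  yd <- youden(rc)
  ip <- which(labels); ineg <- which(!labels)
  op <- with_seed(derive_seed(seed, "op-boot"), {
    reps <- vapply(seq_len(n_boot), function(b) {
      sp <- scores[sample(ip, replace = TRUE)]
      sn <- scores[sample(ineg, replace = TRUE)]
      c(mean(sp >= yd$threshold), mean(sn < yd$threshold))
    }, numeric(2))
    list(sens_ci = stats::quantile(reps[1, ], c(0.025, 0.975), names = FALSE),
         spec_ci = stats::quantile(reps[2, ], c(0.025, 0.975), names = FALSE))
  })
  structure(list(curve = rc$curve, auc = rc$auc,
                 ci = c(lower = ci$lower, upper = ci$upper),
                 ci_method = ci_method,
                 youden_threshold = yd$threshold, youden_j = yd$j,
                 sensitivity = yd$sensitivity, specificity = yd$specificity,
                 sensitivity_ci = op$sens_ci, specificity_ci = op$spec_ci,
                 n_pos = rc$n_pos, n_neg = rc$n_neg),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("ROC report: AUC %.3f (95%% CI %.3f-%.3f, %s)\n",
              x$auc, x$ci["lower"], x$ci["upper"], x$ci_method))
  cat(sprintf("  Youden threshold %.3f (J = %.3f): sens %.3f (%.3f-%.3f), spec %.3f (%.3f-%.3f)\n",
              x$youden_threshold, x$youden_j,
              x$sensitivity, x$sensitivity_ci[1], x$sensitivity_ci[2],
              x$specificity, x$specificity_ci[1], x$specificity_ci[2]))
  cat(sprintf("  n: %d positive / %d negative\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' Write ROC reports, curves, pairwise DeLong table and a plot
#'
#' @param scores_by_model Named list of score vectors, all on the same
#'   records.
#' @param labels Common labels.
#' @param out_dir Output directory.
#' @param seed Integer seed for the bootstraps.
#' @return Invisibly, a list with the reports and the pairwise table.
#' @export
make_report <- function(scores_by_model, labels, out_dir, seed = 1) {
  if (!length(scores_by_model)) stop("need at least one model", call. = FALSE)
  if (is.null(names(scores_by_model))) {
    names(scores_by_model) <- paste0("model", seq_along(scores_by_model))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  reports <- lapply(scores_by_model, roc_report, labels = labels, seed = seed)
  for (nm in names(reports)) {
    rp <- reports[[nm]]
    jsonlite::write_json(
      list(model = nm, auc = rp$auc,
           ci = as.list(rp$ci), ci_method = rp$ci_method,
           youden_threshold = rp$youden_threshold, youden_j = rp$youden_j,
           sensitivity = rp$sensitivity, specificity = rp$specificity,
           n_pos = rp$n_pos, n_neg = rp$n_neg),
      file.path(out_dir, paste0(nm, "_report.json")),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(rp$curve, file.path(out_dir, paste0(nm, "_curve.csv")),
                     row.names = FALSE)
  }
  pairs <- if (length(scores_by_model) >= 2) {
    utils::combn(names(scores_by_model), 2, simplify = FALSE)
  } else {
    list()
  }
  pw <- do.call(rbind, lapply(pairs, function(p) {
    dt <- delong_test(scores_by_model[[p[1]]], scores_by_model[[p[2]]], labels)
    data.frame(model_a = p[1], model_b = p[2], auc_a = dt$auc_a,
               auc_b = dt$auc_b, z = dt$z, p = dt$p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pw)) {
    pw <- data.frame(model_a = character(), model_b = character(),
                     auc_a = numeric(), auc_b = numeric(),
                     z = numeric(), p = numeric())
  }
  utils::write.csv(pw, file.path(out_dir, "pairwise_delong.csv"),
                   row.names = FALSE)
  grDevices::png(file.path(out_dir, "roc_curves.png"), width = 640,
                 height = 640)
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "gray",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = "ROC curves")
  cols <- grDevices::hcl.colors(max(3L, length(reports)), "Dark 3")
  for (i in seq_along(reports)) {
    cv <- reports[[i]]$curve
    graphics::lines(c(1, 1 - cv$specificity, 0), c(1, cv$sensitivity, 0),
                    col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.3f)", names(reports),
                                    vapply(reports, `[[`, numeric(1), "auc")),
                   col = cols[seq_along(reports)], lwd = 2, bty = "n")
  grDevices::dev.off()
  invisible(list(reports = reports, pairwise = pw))
}
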