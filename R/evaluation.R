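# ROC analysis: empirical curves, Mann-Whitney AUC, DeLong variance
# for the AUC confidence interval, and sensitivity (detection rate) at
# a fixed false-positive rate with a stratified bootstrap CI.

check_two_classes <- function(labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop_pe("labels must be binary 0/1")
  if (sum(labels) == 0 || sum(labels) == length(labels))
    stop_pe("both classes must be present")
  labels
}

#' Empirical ROC curve
#'
#' Points of the empirical ROC from the sorted unique score thresholds,
#' ties grouped into a single step; the curve starts at (0, 0) with
#' threshold `Inf` and ends at (1, 1).
#'
#' @param scores numeric risk scores (higher = more case-like).
#' @param labels binary outcome (1 = case).
#' @return data.frame with `fpr`, `tpr`, `threshold`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  n1 <- sum(y); n0 <- length(y) - n1
  last <- !duplicated(s, fromLast = TRUE)   # group tied scores
  tpr <- cumsum(y)[last] / n1
  fpr <- cumsum(1 - y)[last] / n0
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr), threshold = c(Inf, s[last]))
}

#' Area under the ROC curve
#'
#' Equals the Mann-Whitney U statistic divided by
#' `n_cases * n_controls`, ties counted one half (computed via
#' midranks).
#'
#' @inheritParams roc_curve
#' @return the AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels); n0 <- length(labels) - n1
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components via midranks: V10 per case, V01 per
# control.
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  rx <- rank(x); ry <- rank(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rx) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric structural-component variance with a normal
#' approximation, clipped to `[0, 1]`. Perfect separation has zero
#' DeLong variance; the returned zero-width interval carries a
#' `"degenerate"` attribute.
#'
#' @inheritParams roc_curve
#' @param conf confidence level (default 0.95).
#' @return numeric `c(lo, hi)` with attributes `auc`, `se` and
#'   `degenerate`.
#' @export
auc_ci_delong <- function(scores, labels, conf = 0.95) {
  labels <- check_two_classes(labels)
  if (sum(labels) < 2 || sum(1 - labels) < 2)
    stop_pe("DeLong CI needs >= 2 cases and >= 2 controls")
  dc <- delong_components(scores, labels)
  v <- var(dc$v10) / length(dc$v10) + var(dc$v01) / length(dc$v01)
  se <- sqrt(v)
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- pmin(pmax(dc$auc + c(-1, 1) * z * se, 0), 1)
  names(ci) <- c("lo", "hi")
  attr(ci, "auc") <- dc$auc
  attr(ci, "se") <- se
  attr(ci, "degenerate") <- se == 0
  ci
}

#' Sensitivity at a fixed false-positive rate
#'
#' Detection rate at the most liberal threshold whose empirical FPR
#' does not exceed the target (step-function convention, no
#' interpolation), with a seeded case/control-stratified percentile
#' bootstrap CI.
#'
#' @inheritParams roc_curve
#' @param fpr_target maximum false-positive rate (default 0.10).
#' @param n_boot bootstrap resamples for the CI (default 2000; 0 skips
#'   the CI).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @return list with `sensitivity`, `threshold`, `fpr`, and `ci`
#'   (`c(lo, hi)`, `NA` when `n_boot = 0`).
#' @export
sensitivity_at_fpr <- function(scores, labels, fpr_target = 0.10,
                               n_boot = 2000, seed = 1, conf = 0.95) {
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels), fpr_target >= 0)
  x <- scores[labels == 1]; y <- scores[labels == 0]
  est <- sens_fpr_point(x, y, fpr_target)
  ci <- c(lo = NA_real_, hi = NA_real_)
  if (n_boot > 0) {
    bs <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        xb <- x[sample.int(length(x), replace = TRUE)]
        yb <- y[sample.int(length(y), replace = TRUE)]
        sens_fpr_point(xb, yb, fpr_target)$sensitivity
      }, numeric(1))
    })
    qs <- quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    ci <- c(lo = qs[1], hi = qs[2])
  }
  c(est, list(ci = ci))
}

sens_fpr_point <- function(case_scores, ctrl_scores, fpr_target) {
  thr <- sort(unique(c(case_scores, ctrl_scores)))
  sc <- sort(ctrl_scores)
  m <- length(sc)
  # controls >= thr, exact under ties
  n_ge <- m - findInterval(thr, sc, left.open = TRUE)
  ok <- which(n_ge / m <= fpr_target)
  if (length(ok) == 0) {
    # even the strictest finite threshold is too liberal: call nobody
    return(list(sensitivity = 0, threshold = Inf, fpr = 0))
  }
  t_star <- thr[ok[1]]                     # most liberal admissible
  list(sensitivity = mean(case_scores >= t_star),
       threshold = t_star,
       fpr = n_ge[ok[1]] / m)
}

#' Evaluate fitted risk models over outcomes and landmarks
#'
#' One evaluation row per outcome x landmark: AUC with DeLong 95% CI,
#' sensitivity at the fixed FPR with bootstrap CI, and case/control
#' counts. Cells without a fitted model (e.g. too few cases in the risk
#' set) are recorded as absent (`NA` metrics), never silently skipped.
#'
#' @param models nested list `models[[outcome]][[as.character(week)]]`
#'   of `pe_risk_model`s (missing entries allowed).
#' @param datasets list `datasets[[as.character(week)]]` of
#'   `pe_landmark_dataset`s to score (training data for apparent
#'   performance, or holdout data assembled with the training
#'   template).
#' @param outcomes outcome label names.
#' @param landmarks completed weeks.
#' @param fpr_target fixed false-positive rate (default 0.10).
#' @param n_boot bootstrap resamples for the sensitivity CI.
#' @param seed master seed for the bootstraps.
#' @param keep_roc also return the ROC point lists.
#' @return a data.frame (class `pe_eval`) with columns `outcome`,
#'   `landmark_week`, `n_cases`, `n_controls`, `auc`, `auc_lo`,
#'   `auc_hi`, `sens_fpr10`, `sens_lo`, `sens_hi`; ROC point lists in
#'   the `"roc"` attribute when requested.
#' @export
evaluate_all <- function(models, datasets,
                         outcomes = c("any_pe", "preterm_pe", "term_pe"),
                         landmarks = c(24, 28, 32, 34, 36),
                         fpr_target = 0.10, n_boot = 2000, seed = 1,
                         keep_roc = FALSE) {
  rows <- list()
  rocs <- list()
  for (oc in outcomes) {
    for (w in landmarks) {
      key <- as.character(w)
      model <- models[[oc]][[key]]
      ds <- datasets[[key]]
      row <- data.frame(outcome = oc, landmark_week = w,
                        n_cases = NA_integer_, n_controls = NA_integer_,
                        auc = NA_real_, auc_lo = NA_real_, auc_hi = NA_real_,
                        sens_fpr10 = NA_real_, sens_lo = NA_real_,
                        sens_hi = NA_real_, stringsAsFactors = FALSE)
      if (!is.null(model) && !is.null(ds)) {
        p <- predict_risk(model, ds)
        y <- as.numeric(ds$labels[[oc]])
        if (sum(y) > 0 && sum(y) < length(y)) {
          ci <- auc_ci_delong(p, y)
          sn <- sensitivity_at_fpr(p, y, fpr_target, n_boot = n_boot,
                                   seed = derive_seed(seed,
                                                      paste("sens", oc, w)))
          row$n_cases <- sum(y); row$n_controls <- sum(1 - y)
          row$auc <- attr(ci, "auc"); row$auc_lo <- ci[["lo"]]
          row$auc_hi <- ci[["hi"]]
          row$sens_fpr10 <- sn$sensitivity
          row$sens_lo <- sn$ci[["lo"]]; row$sens_hi <- sn$ci[["hi"]]
          if (keep_roc) rocs[[paste0(oc, "_w", w)]] <- roc_curve(p, y)
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pe_eval", "data.frame")
  if (keep_roc) attr(out, "roc") <- rocs
  out
}

#' @export
print.pe_eval <- function(x, digits = 3, ...) {
  cat("Landmark prediction performance (AUC [95% CI], sensitivity at fixed FPR):\n")
  df <- as.data.frame(x)
  df$auc <- sprintf("%.*f (%.*f-%.*f)", digits, df$auc, digits, df$auc_lo,
                    digits, df$auc_hi)
  df$sens <- ifelse(is.na(df$sens_fpr10), "NA",
                    sprintf("%.1f%% (%.1f-%.1f)", 100 * df$sens_fpr10,
                            100 * df$sens_lo, 100 * df$sens_hi))
  print(df[, c("outcome", "landmark_week", "n_cases", "n_controls",
               "auc", "sens")], row.names = FALSE)
  invisible(x)
}
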