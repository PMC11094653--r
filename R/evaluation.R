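#' Conditional rates from a 2x2 confusion matrix
#'
#' The positive class is the sleep-deprived (SD) condition; `tn` counts
#' well-rested (WR) samples predicted WR, `tp` SD predicted SD. Four raw
#' conditional rates are reported with explicit numerator/denominator
#' definitions (terminology for these rates varies across reports, so the
#' definitions are the contract): `rate_true_wr = tn/(tn+fp)`,
#' `rate_true_sd = tp/(tp+fn)`, `rate_pred_wr = tn/(tn+fn)`,
#' `rate_pred_sd = tp/(tp+fp)`. Rates with zero denominator are `NA`.
#' All arithmetic is exact; rounding happens only at report serialization.
#'
#' @param tn,fp,fn,tp nonnegative integer counts.
#' @return list of `accuracy` and the four conditional rates (proportions).
#' @export
confusion_rates <- function(tn, fp, fn, tp) {
  counts <- c(tn, fp, fn, tp)
  if (any(counts < 0) || sum(counts) == 0) stop("invalid confusion counts")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    accuracy = (tn + tp) / sum(counts),
    rate_true_wr = rate(tn, tn + fp),
    rate_true_sd = rate(tp, tp + fn),
    rate_pred_wr = rate(tn, tn + fn),
    rate_pred_sd = rate(tp, tp + fp)
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form: lower `qbeta(a/2, x, n-x+1)`, upper
#' `qbeta(1-a/2, x+1, n-x)`; at `x = n` the lower bound reduces to
#' `(a/2)^(1/n)` and the upper bound is 1.
#'
#' @param successes,n counts with `0 <= successes <= n`, `n > 0`.
#' @param conf confidence level (default 0.95).
#' @return numeric `c(lower, upper)` as proportions.
#' @export
exact_binomial_ci <- function(successes, n, conf = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (successes < 0 || successes > n) stop("successes must be in [0, n]")
  a <- 1 - conf
  lower <- if (successes == 0) 0 else stats::qbeta(a / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else stats::qbeta(1 - a / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' Empirical ROC curve with AUC and DeLong-type confidence interval
#'
#' Sweeps all score thresholds, computes the empirical true/false positive
#' rates, the trapezoid AUC (equal to the Mann-Whitney concordance
#' probability, ties counted half), and an asymptotic 95% CI from the DeLong
#' placement-value variance.
#'
#' @param scores numeric classifier scores, larger = more SD-like.
#' @param labels binary labels (positive class = 1/"SD"/TRUE).
#' @param conf confidence level for the CI.
#' @return a `roc_curve` list: `thresholds`, `tpr`, `fpr`, `auc_pct`,
#'   `ci95` (percent), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  s1 <- scores[pos]
  s0 <- scores[!pos]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(s1 >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s0 >= t), numeric(1))
  # placement values (DeLong)
  psi <- function(x, y) (sum(x > y) + 0.5 * sum(x == y)) / length(y)
  v10 <- vapply(s1, psi, numeric(1), y = s0)
  v01 <- vapply(s0, function(y) (sum(s1 < y) + 0.5 * sum(s1 == y)) / length(s1),
                numeric(1))
  auc <- mean(v10)
  var_auc <- stats::var(v10) / length(s1) + stats::var(v01) / length(s0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(var_auc), 0), 1)
  structure(
    list(thresholds = thr, tpr = tpr, fpr = fpr,
         auc_pct = 100 * auc, ci95 = 100 * ci,
         n_pos = length(s1), n_neg = length(s0)),
    class = "roc_curve"
  )
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) return(labels %in% c("SD", "1", "TRUE", "pos"))
  labels == max(labels)
}

#' Sensitivity at a specificity-targeted operating point
#'
#' Picks the operating threshold that maximizes sensitivity subject to
#' specificity >= `sp_target` — the adjustment needed when false positives
#' must be capped (e.g., forensic use of a sleep-deprivation test).
#'
#' @param curve a `roc_curve` from [roc_auc()].
#' @param sp_target required specificity, as a proportion.
#' @return list: `threshold`, `sensitivity`, `specificity`, `attainable`.
#' @export
sp_targeted_sensitivity <- function(curve, sp_target = 0.85) {
  stopifnot(inherits(curve, "roc_curve"))
  sp <- 1 - curve$fpr
  ok <- sp >= sp_target
  if (!any(ok)) {
    return(list(threshold = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_, attainable = FALSE))
  }
  i <- which(ok)[which.max(curve$tpr[ok])]
  list(threshold = curve$thresholds[i], sensitivity = curve$tpr[i],
       specificity = sp[i], attainable = TRUE)
}

#' Empirical quantiles of absolute prediction error
#'
#' For a time-since-wake regressor: the error (hours) within which the given
#' fraction of samples is predicted (linear-interpolated quantiles).
#'
#' @param pred_h,actual_h equal-length numeric vectors (hours).
#' @param q quantile levels (default 0.5, 0.75, 0.9).
#' @return named numeric vector of error quantiles.
#' @export
percentile_abs_error <- function(pred_h, actual_h, q = c(0.5, 0.75, 0.9)) {
  if (length(pred_h) != length(actual_h)) stop("length mismatch")
  stats::quantile(abs(pred_h - actual_h), q, names = TRUE, type = 7)
}

#' Test-set coefficient of determination
#'
#' `R^2 = 1 - SSE/SST` about the test-set mean; negative values are
#' legitimate (a predictor worse than the test mean).
#'
#' @param pred,actual equal-length numeric vectors.
#' @return scalar R-squared (proportion, may be negative).
#' @export
r_squared <- function(pred, actual) {
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) stop("constant actual values; R^2 undefined")
  1 - sum((actual - pred)^2) / sst
}

#' Root-mean-square error
#' @param pred,actual equal-length numeric vectors.
#' @return scalar RMSE in the units of the inputs.
#' @export
rmse <- function(pred, actual) sqrt(mean((actual - pred)^2))
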