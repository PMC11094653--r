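# Multi-response OLS on a fixed design matrix: returns coefficients, residual
# variance and the joint F-test against the intercept-only model for each
# response column. Used to fit thousands of features in one pass.
mlm_fit <- function(X, Y) {
  qrx <- qr(X)
  coef <- qr.coef(qrx, Y)
  res <- Y - X %*% coef
  n <- nrow(X)
  k <- ncol(X)
  df <- n - k
  sse1 <- colSums(res^2)
  sse0 <- colSums(scale(Y, center = TRUE, scale = FALSE)^2)
  xtx_inv <- chol2inv(qr.R(qrx))
  list(coef = coef, df = df, sse1 = sse1, sse0 = sse0,
       var_unit = diag(xtx_inv), sigma2 = sse1 / df)
}

#' Fit a linear (homeostatic) trend to one feature series
#'
#' Ordinary least squares of intensity on time since wake, with the exact
#' t-test p-value for a zero slope. A monotone drift with accumulated wake is
#' the signature of sleep-homeostat control.
#'
#' @param values numeric response.
#' @param times_h sampling times (hours); at least 3 distinct values.
#' @return list: `slope`, `intercept`, `p_value`, `direction` (sign of slope).
#' @export
fit_linear <- function(values, times_h) {
  if (length(values) != length(times_h)) stop("values/times length mismatch")
  if (length(unique(times_h)) < 3) stop("need >= 3 distinct times")
  X <- cbind(1, times_h)
  f <- mlm_fit(X, matrix(values, ncol = 1))
  slope <- unname(f$coef[2, 1])
  se <- unname(sqrt(f$sigma2[1] * f$var_unit[2]))
  p <- linear_p_from_stats(slope, se, f$df)
  list(slope = slope, intercept = unname(f$coef[1, 1]), p_value = p,
       direction = sign(slope))
}

# Degenerate-safe two-sided t-test p for a slope: an exactly flat noiseless
# series is non-significant (p = 1); a noiseless nonzero slope is p = 0.
linear_p_from_stats <- function(slope, se, df) {
  tol <- 1e-12
  p <- ifelse(se > tol,
              2 * stats::pt(-abs(slope / se), df),
              ifelse(abs(slope) > tol, 0, 1))
  as.numeric(p)
}

#' Fit a fixed-period cosinor (circadian) model to one feature series
#'
#' OLS on `cos(2*pi*t/period)` and `sin(2*pi*t/period)` plus an intercept
#' (the mesor). Amplitude is the vector norm of the two coefficients,
#' acrophase the peak time, and the p-value comes from the joint F-test of
#' both rhythm coefficients being zero.
#'
#' @param values numeric response.
#' @param times_h sampling times (hours); at least 4 distinct values spanning
#'   more than half a period.
#' @param period_h rhythm period, default 24.
#' @param linear_covariate also include a linear time term, so the rhythm
#'   amplitude is estimated net of any homeostatic drift. Off by default
#'   (plain cosinor); recommended when sampling does not span whole periods,
#'   where an unmodeled trend leaks into the cos/sin coefficients.
#' @return list: `mesor`, `amplitude`, `acrophase_h`, `p_value`, `period_h`.
#' @export
fit_cosinor <- function(values, times_h, period_h = 24,
                        linear_covariate = FALSE) {
  if (length(values) != length(times_h)) stop("values/times length mismatch")
  if (length(unique(times_h)) < 4) stop("need >= 4 distinct times")
  if (diff(range(times_h)) <= period_h / 2) {
    stop("times must span more than half a period")
  }
  w <- 2 * pi / period_h
  X0 <- if (linear_covariate) cbind(1, times_h) else matrix(1, length(values), 1)
  X <- cbind(X0, cos(w * times_h), sin(w * times_h))
  f <- mlm_fit(X, matrix(values, ncol = 1))
  k <- ncol(X0)
  bc <- unname(f$coef[k + 1, 1])
  bs <- unname(f$coef[k + 2, 1])
  amp <- sqrt(bc^2 + bs^2)
  acro <- (atan2(bs, bc) / w) %% period_h
  # F-test of the two rhythm coefficients against the rhythm-free null
  f0 <- mlm_fit(X0, matrix(values, ncol = 1))
  p <- cosinor_p_from_sse(unname(f0$sse1[1]), unname(f$sse1[1]), f$df, amp)
  list(mesor = unname(f$coef[1, 1]), amplitude = amp, acrophase_h = acro,
       p_value = unname(p), period_h = period_h)
}

cosinor_p_from_sse <- function(sse0, sse1, df, amp) {
  tol <- 1e-12
  if (sse1 > tol * max(sse0, 1)) {
    F <- ((sse0 - sse1) / 2) / (sse1 / df)
    stats::pf(F, 2, df, lower.tail = FALSE)
  } else if (amp > tol) 0 else 1
}

# Vectorized per-feature fits over one set of samples; returns a data.frame
# with slope/p_lin and amplitude/acrophase/p_cos for every feature.
fit_all_features <- function(Y, times_h, period_h = 24) {
  Xl <- cbind(1, times_h)
  fl <- mlm_fit(Xl, Y)
  slope <- fl$coef[2, ]
  se <- sqrt(fl$sigma2 * fl$var_unit[2])
  p_lin <- linear_p_from_stats(slope, se, fl$df)
  w <- 2 * pi / period_h
  Xc <- cbind(1, cos(w * times_h), sin(w * times_h))
  fc <- mlm_fit(Xc, Y)
  amp <- sqrt(fc$coef[2, ]^2 + fc$coef[3, ]^2)
  acro <- (atan2(fc$coef[3, ], fc$coef[2, ]) / w) %% period_h
  p_cos <- vapply(seq_len(ncol(Y)), function(j) {
    cosinor_p_from_sse(fc$sse0[j], fc$sse1[j], fc$df, amp[j])
  }, numeric(1))
  data.frame(feature_id = colnames(Y), slope = slope, p_lin = p_lin,
             amplitude = amp, acrophase_h = acro, p_cos = p_cos,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Characterize every feature's linear and circadian trends
#'
#' Fits the linear and 24-h cosinor models to each feature, either per
#' participant (`level = "individual"`) or pooled over all samples
#' (`level = "group"`). Benjamini-Hochberg FDR is applied across features
#' separately for the linear and cosinor families; group-level category
#' flags follow `cycling <=> q_cos < alpha` and `increasing`/`decreasing`
#' `<=> q_lin < alpha` with the slope sign.
#'
#' @param view a `data_view` from [prepare_views()] (or a `feature_table`).
#' @param level `"group"` or `"individual"`.
#' @param period_h cosinor period, default 24.
#' @param alpha significance level for category flags (on q-values).
#' @return a `trend_catalog`: list with `level`, `entries` (tidy data.frame)
#'   and, for group level, `categories` per feature.
#' @export
characterize <- function(view, level = c("group", "individual"),
                         period_h = 24, alpha = 0.05) {
  level <- match.arg(level)
  tab <- if (inherits(view, "data_view")) view$table else view
  stopifnot(inherits(tab, "feature_table"))
  Y <- tab$intensities
  tsw <- tab$sample_meta$tsw_hours
  if (level == "group") {
    entries <- fit_all_features(Y, tsw, period_h)
    entries$participant_id <- "group"
  } else {
    parts <- unique(as.character(tab$sample_meta$participant_id))
    entries <- do.call(rbind, lapply(parts, function(p) {
      idx <- tab$sample_meta$participant_id == p
      e <- fit_all_features(Y[idx, , drop = FALSE], tsw[idx], period_h)
      e$participant_id <- p
      e
    }))
  }
  # FDR within each (participant, model-family) across features
  entries$q_lin <- stats::ave(entries$p_lin, entries$participant_id,
                              FUN = function(p) stats::p.adjust(p, "BH"))
  entries$q_cos <- stats::ave(entries$p_cos, entries$participant_id,
                              FUN = function(p) stats::p.adjust(p, "BH"))
  categories <- NULL
  if (level == "group") {
    categories <- data.frame(
      feature_id = entries$feature_id,
      cycling = entries$q_cos < alpha,
      increasing = entries$q_lin < alpha & entries$slope > 0,
      decreasing = entries$q_lin < alpha & entries$slope < 0,
      stringsAsFactors = FALSE
    )
  }
  structure(list(level = level, entries = entries, categories = categories,
                 alpha = alpha),
            class = "trend_catalog")
}

# Five mutually exclusive category bins for between-experiment comparison.
category_bins <- function(categories) {
  lin <- categories$increasing | categories$decreasing
  bin <- ifelse(categories$cycling & lin, "cycling+linear",
         ifelse(categories$cycling, "cycling-only",
         ifelse(categories$increasing, "linear-only increasing",
         ifelse(categories$decreasing, "linear-only decreasing", "neither"))))
  factor(bin, levels = c("linear-only increasing", "linear-only decreasing",
                         "cycling-only", "cycling+linear", "neither"))
}

#' Compare trend-category composition between two experiments
#'
#' Pearson chi-square on the contingency table of group-level feature
#' category counts (rows: experiments; columns: category bins — linear-only
#' increasing/decreasing, cycling-only, cycling+linear, neither). Bins empty
#' in both experiments are dropped from the table.
#'
#' @param catalog_a,catalog_b group-level `trend_catalog`s over the same
#'   feature universe.
#' @return list: `statistic`, `df`, `p_value`, `table`.
#' @export
compare_experiments <- function(catalog_a, catalog_b) {
  stopifnot(inherits(catalog_a, "trend_catalog"),
            inherits(catalog_b, "trend_catalog"))
  if (is.null(catalog_a$categories) || is.null(catalog_b$categories)) {
    stop("both catalogs must be group-level (with categories)")
  }
  if (!identical(sort(catalog_a$categories$feature_id),
                 sort(catalog_b$categories$feature_id))) {
    stop("catalogs must categorize the same feature universe")
  }
  ta <- table(category_bins(catalog_a$categories))
  tb <- table(category_bins(catalog_b$categories))
  m <- rbind(a = ta, b = tb)
  m <- m[, colSums(m) > 0, drop = FALSE]
  exp_counts <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(exp_counts < 1)) {
    warning("expected cell count < 1; chi-square approximation is poor")
  }
  chi <- sum((m - exp_counts)^2 / exp_counts)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  p <- if (df < 1) 1 else stats::pchisq(chi, df, lower.tail = FALSE)
  list(statistic = chi, df = df, p_value = p, table = m)
}
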