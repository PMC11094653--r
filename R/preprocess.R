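#' Remove features with too many censored (zero) values
#'
#' A feature is dropped iff its zero count / sample count exceeds
#' `max_zero_fraction` (strict inequality, mirroring a ">20% zeros removed"
#' cleanup rule). Retained feature order is preserved.
#'
#' @param table a [feature_table()].
#' @param max_zero_fraction maximum tolerated zero fraction, in `[0, 1)`.
#' @return list with `table` (filtered) and `dropped` (character feature ids).
#' @export
filter_zero_features <- function(table, max_zero_fraction = 0.20) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$intensities) == 0 || ncol(table$intensities) == 0) {
    stop("empty feature table")
  }
  if (max_zero_fraction < 0 || max_zero_fraction >= 1) {
    stop("max_zero_fraction must be in [0, 1)")
  }
  zf <- colMeans(table$intensities == 0)
  keep <- zf <= max_zero_fraction
  list(
    table = ft_subset(table, features = which(keep)),
    dropped = table$feature_meta$feature_id[!keep]
  )
}

#' Impute left-censored zeros below each feature's observed minimum
#'
#' Zeros are treated as values below the detection limit, never true zeros.
#' The default draws from a per-feature normal truncated to
#' `(0, min observed nonzero)`, with mean and sd recovered from the observed
#' (upper-tail) values by quantile matching against the censoring fraction;
#' `"half_min"` deterministically substitutes half the observed minimum.
#' Nonzero entries are untouched; results are reproducible given `seed`.
#'
#' @param table a [feature_table()].
#' @param method `"truncated_normal_qr"` (default) or `"half_min"`.
#' @param seed integer seed for the stochastic method.
#' @return a [feature_table()] with strictly positive intensities.
#' @export
impute_left_censored <- function(table, method = c("truncated_normal_qr", "half_min"),
                                 seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  Y <- table$intensities
  if (!any(Y == 0)) return(table)
  set.seed(seed)
  global_min <- min(Y[Y > 0])
  for (j in seq_len(ncol(Y))) {
    zi <- which(Y[, j] == 0)
    if (!length(zi)) next
    obs <- Y[Y[, j] > 0, j]
    if (!length(obs)) {
      warning("feature ", colnames(Y)[j],
              " is entirely censored; imputing from the global minimum")
      Y[zi, j] <- global_min / 2
      next
    }
    min_obs <- min(obs)
    if (method == "half_min") {
      Y[zi, j] <- min_obs / 2
      next
    }
    # Quantile matching: the observed values are the upper (1 - p0) tail of
    # the latent distribution. Two latent quantiles pin down (mu, sigma).
    p0 <- length(zi) / nrow(Y)
    u <- c(0.25, 0.75)
    latent_p <- p0 + (1 - p0) * u
    qq <- stats::quantile(obs, u, names = FALSE)
    zz <- stats::qnorm(latent_p)
    sigma <- (qq[2] - qq[1]) / (zz[2] - zz[1])
    if (!is.finite(sigma) || sigma <= 0) sigma <- stats::sd(obs)
    if (!is.finite(sigma) || sigma <= 0) sigma <- min_obs / 4
    mu <- qq[1] - sigma * zz[1]
    lo <- stats::pnorm(0, mu, sigma)
    hi <- stats::pnorm(min_obs, mu, sigma)
    if (hi <= lo) {
      Y[zi, j] <- min_obs / 2
      next
    }
    draws <- stats::qnorm(stats::runif(length(zi), lo, hi), mu, sigma)
    # numerical guard: keep draws strictly inside (0, min_obs)
    eps <- min_obs * 1e-9
    Y[zi, j] <- pmin(pmax(draws, eps), min_obs - eps)
  }
  feature_table(Y, table$sample_meta, table$feature_meta)
}

#' Median-normalize intensities within each sample
#'
#' Accounts for sample-to-sample variation across the LC-MS run: each
#' sample's intensities are rescaled multiplicatively so that every sample's
#' median across features equals the reference median (the median of
#' per-sample medians).
#'
#' @param table a [feature_table()] with no zeros (impute first).
#' @return a [feature_table()].
#' @export
median_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  med <- apply(table$intensities, 1, stats::median)
  if (any(med <= 0)) {
    stop("sample(s) with non-positive median: ",
         paste(table$sample_meta$sample_id[med <= 0], collapse = ", "))
  }
  ref <- stats::median(med)
  Y <- table$intensities * (ref / med)
  feature_table(Y, table$sample_meta, table$feature_meta)
}

#' Autoscale each feature within each participant
#'
#' For every participant and feature, subtracts the participant's mean over
#' their samples and divides by the sample sd (denominator n-1), removing
#' between-participant baseline variation so that only each individual's
#' temporal shape remains.
#'
#' @param table a [feature_table()].
#' @return a list-of-class `feature_table` whose `intensities` hold z-scores
#'   (negative values allowed; stored as a plain matrix in `$values`).
#' @details Zero-variance (constant) feature/participant series are set to 0
#'   with a warning; a participant with fewer than 2 samples is an error.
#' @export
zscore_within_participant <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  Y <- table$intensities
  part <- as.character(table$sample_meta$participant_id)
  Z <- Y
  n_const <- 0L
  for (p in unique(part)) {
    idx <- which(part == p)
    if (length(idx) < 2) {
      stop("participant ", p, " has a single sample; cannot z-score")
    }
    m <- colMeans(Y[idx, , drop = FALSE])
    s <- apply(Y[idx, , drop = FALSE], 2, stats::sd)
    const <- s == 0 | !is.finite(s)
    s[const] <- 1
    n_const <- n_const + sum(const)
    Z[idx, ] <- sweep(sweep(Y[idx, , drop = FALSE], 2, m), 2, s, `/`)
    Z[idx, const] <- 0
  }
  if (n_const > 0) {
    warning(n_const, " constant feature/participant series set to 0")
  }
  out <- table
  out$intensities <- Z
  out
}

#' Prepare the between- and within-participant data views
#'
#' The between view is filter (zero fraction) -> left-censored imputation ->
#' within-sample median normalization on raw relative peak areas; the within
#' view additionally z-scores each feature within each participant. All
#' downstream stages consume one of these views.
#'
#' @param table a raw [feature_table()].
#' @param max_zero_fraction see [filter_zero_features()].
#' @param imputation,imputation_seed see [impute_left_censored()].
#' @param views subset of `c("between", "within")`.
#' @return named list of `data_view` objects, each with `$view_kind`,
#'   `$table` and `$provenance`.
#' @export
prepare_views <- function(table, max_zero_fraction = 0.20,
                          imputation = "truncated_normal_qr",
                          imputation_seed = 1L,
                          views = c("between", "within")) {
  views <- match.arg(views, several.ok = TRUE)
  filt <- filter_zero_features(table, max_zero_fraction)
  if (ncol(filt$table$intensities) == 0) {
    stop("no features survive the zero-fraction filter")
  }
  imputed <- impute_left_censored(filt$table, imputation, imputation_seed)
  between <- median_normalize(imputed)
  prov <- c(sprintf("filter_zero_features(max_zero_fraction=%g) dropped %d",
                    max_zero_fraction, length(filt$dropped)),
            sprintf("impute_left_censored(%s, seed=%d)", imputation, imputation_seed),
            "median_normalize(reference = median of per-sample medians)")
  out <- list()
  if ("between" %in% views) {
    out$between <- structure(
      list(view_kind = "between", table = between, provenance = prov,
           dropped_features = filt$dropped),
      class = "data_view")
  }
  if ("within" %in% views) {
    within <- zscore_within_participant(between)
    out$within <- structure(
      list(view_kind = "within", table = within,
           provenance = c(prov, "zscore_within_participant(ddof=1)"),
           dropped_features = filt$dropped),
      class = "data_view")
  }
  out
}

#' @method print data_view
#' @export
print.data_view <- function(x, ...) {
  cat("data_view [", x$view_kind, "]:", nrow(x$table$intensities), "samples x",
      ncol(x$table$intensities), "features\n")
  for (s in x$provenance) cat("  -", s, "\n")
  invisible(x)
}
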