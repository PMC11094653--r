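#' Feature table: samples x features intensity matrix with metadata
#'
#' The universal data currency of the pipeline: a nonnegative matrix of
#' relative peak areas (one row per collected sample, one column per LC-MS
#' mass feature), joined 1:1 to per-sample metadata and per-feature metadata.
#' A zero intensity encodes a left-censored (below detection limit) value,
#' never a true zero.
#'
#' @param intensities numeric matrix, samples x features, nonnegative.
#' @param sample_meta data.frame with one row per intensity row; must contain
#'   `sample_id`, `participant_id`, `experiment_id`, `tsw_hours` (time since
#'   wake, hours), `day_index`, `protocol_kind`.
#' @param feature_meta data.frame with one row per intensity column; must
#'   contain `feature_id`. For synthetic tables it also records the generative
#'   truth (`true_class`, `slope`, `amplitude`, `acrophase_h`).
#' @param nonnegative enforce nonnegativity (TRUE for raw/normalized peak
#'   areas; z-scored views legitimately hold negative values).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(intensities, sample_meta, feature_meta = NULL,
                          nonnegative = TRUE) {
  intensities <- as.matrix(intensities)
  if (!is.numeric(intensities)) {
    stop("intensities must be a numeric matrix")
  }
  if (anyNA(intensities)) {
    stop("intensities must be non-missing (0 encodes censored)")
  }
  if (nonnegative && any(intensities < 0)) {
    stop("intensities must be nonnegative (0 encodes censored)")
  }
  sample_meta <- as.data.frame(sample_meta)
  req <- c("sample_id", "participant_id", "experiment_id", "tsw_hours")
  missing_cols <- setdiff(req, names(sample_meta))
  if (length(missing_cols)) {
    stop("sample_meta lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(sample_meta) != nrow(intensities)) {
    stop("sample_meta rows must correspond 1:1 with intensity rows")
  }
  if (any(!nzchar(as.character(sample_meta$participant_id))) ||
      any(!nzchar(as.character(sample_meta$experiment_id)))) {
    stop("participant/experiment IDs must be non-empty")
  }
  if (is.null(feature_meta)) {
    feature_meta <- data.frame(
      feature_id = colnames(intensities) %||% paste0("F", seq_len(ncol(intensities))),
      stringsAsFactors = FALSE
    )
  }
  feature_meta <- as.data.frame(feature_meta)
  if (nrow(feature_meta) != ncol(intensities)) {
    stop("feature_meta rows must correspond 1:1 with intensity columns")
  }
  colnames(intensities) <- as.character(feature_meta$feature_id)
  rownames(intensities) <- as.character(sample_meta$sample_id)
  structure(
    list(intensities = intensities, sample_meta = sample_meta,
         feature_meta = feature_meta),
    class = "feature_table"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @method print feature_table
#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$intensities), "samples x",
      ncol(x$intensities), "features\n")
  cat("  participants:", length(unique(x$sample_meta$participant_id)),
      " experiments:", paste(unique(x$sample_meta$experiment_id), collapse = ", "),
      "\n")
  zf <- mean(x$intensities == 0)
  cat(sprintf("  zero (censored) fraction: %.3f\n", zf))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Subset a feature table by samples and/or features
#'
#' @param x a `feature_table`.
#' @param samples logical/integer index over rows, or NULL for all.
#' @param features logical/integer/character index over columns, or NULL.
#' @return a `feature_table`.
#' @export
ft_subset <- function(x, samples = NULL, features = NULL) {
  stopifnot(inherits(x, "feature_table"))
  si <- samples %||% seq_len(nrow(x$intensities))
  if (is.character(features)) {
    features <- match(features, x$feature_meta$feature_id)
    if (anyNA(features)) stop("unknown feature id(s) requested")
  }
  fi <- features %||% seq_len(ncol(x$intensities))
  feature_table(
    x$intensities[si, fi, drop = FALSE],
    x$sample_meta[si, , drop = FALSE],
    x$feature_meta[fi, , drop = FALSE],
    nonnegative = !any(x$intensities < 0)
  )
}

#' Write a feature table to plain-text CSV files
#'
#' Writes `<name>_intensities.csv` (first column `sample_id`, remaining
#' columns one per feature) and `<name>_samples.csv` (the sample metadata);
#' when generative truth is recorded, also `<name>_truth.csv`.
#'
#' @param x a `feature_table`.
#' @param dir output directory (created if needed).
#' @param name file-name stem.
#' @return invisibly, the paths written.
#' @export
write_feature_table <- function(x, dir, name) {
  stopifnot(inherits(x, "feature_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_int <- file.path(dir, paste0(name, "_intensities.csv"))
  p_smp <- file.path(dir, paste0(name, "_samples.csv"))
  int_df <- data.frame(sample_id = x$sample_meta$sample_id, x$intensities,
                       check.names = FALSE)
  utils::write.csv(int_df, p_int, row.names = FALSE)
  utils::write.csv(x$sample_meta, p_smp, row.names = FALSE)
  paths <- c(p_int, p_smp)
  if (all(c("true_class", "slope", "amplitude") %in% names(x$feature_meta))) {
    p_tru <- file.path(dir, paste0(name, "_truth.csv"))
    utils::write.csv(x$feature_meta, p_tru, row.names = FALSE)
    paths <- c(paths, p_tru)
  }
  invisible(paths)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param dir directory containing the CSVs.
#' @param name file-name stem used at write time.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(dir, name) {
  p_int <- file.path(dir, paste0(name, "_intensities.csv"))
  p_smp <- file.path(dir, paste0(name, "_samples.csv"))
  if (!file.exists(p_int) || !file.exists(p_smp)) {
    stop("missing feature-table CSVs for '", name, "' in ", dir)
  }
  int_df <- utils::read.csv(p_int, check.names = FALSE)
  smp <- utils::read.csv(p_smp)
  m <- as.matrix(int_df[, -1, drop = FALSE])
  p_tru <- file.path(dir, paste0(name, "_truth.csv"))
  fm <- if (file.exists(p_tru)) utils::read.csv(p_tru) else NULL
  feature_table(m, smp, fm)
}
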