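#' Configuration for three-stage random-forest variable selection
#'
#' Stage parameters follow the established thresholding / interpretation /
#' prediction procedure: `ntree_*` is the forest size and `nfor_*` the number
#' of replicate forests per stage.
#'
#' @param ntree_thres,nfor_thres stage-1 forest size / replicates (300, 40).
#' @param ntree_interp,nfor_interp stage-2 values (100, 30).
#' @param ntree_pred,nfor_pred stage-3 values (100, 10).
#' @param seed integer seed; every stage derives its RNG stream from it.
#' @param task `"classification"` or `"regression"`.
#' @param mtry forest mtry during selection; default `ceiling(sqrt(p))`.
#' @return a `vsurf_config` list.
#' @export
vsurf_config <- function(ntree_thres = 300, nfor_thres = 40,
                         ntree_interp = 100, nfor_interp = 30,
                         ntree_pred = 100, nfor_pred = 10,
                         seed = 1L,
                         task = c("classification", "regression"),
                         mtry = NULL) {
  task <- match.arg(task)
  counts <- c(ntree_thres, nfor_thres, ntree_interp, nfor_interp,
              ntree_pred, nfor_pred)
  if (any(counts < 1)) stop("all forest counts must be >= 1")
  structure(list(ntree_thres = ntree_thres, nfor_thres = nfor_thres,
                 ntree_interp = ntree_interp, nfor_interp = nfor_interp,
                 ntree_pred = ntree_pred, nfor_pred = nfor_pred,
                 seed = as.integer(seed), task = task, mtry = mtry),
            class = "vsurf_config")
}

check_xy <- function(X, y, task) {
  X <- as.data.frame(X)
  if (task == "classification") {
    y <- as.factor(y)
    if (nlevels(droplevels(y)) < 2) stop("classification needs >= 2 classes")
  } else {
    y <- as.numeric(y)
  }
  list(X = X, y = y)
}

grow_forest <- function(X, y, ntree, mtry = NULL, task, nodesize = NULL,
                        importance = FALSE) {
  p <- ncol(X)
  if (is.null(mtry)) {
    mtry <- if (task == "classification") max(1, floor(sqrt(p))) else
      max(1, floor(p / 3))
  }
  mtry <- min(mtry, p)
  if (is.null(nodesize)) nodesize <- if (task == "classification") 1 else 5
  randomForest::randomForest(x = X, y = y, ntree = ntree, mtry = mtry,
                             nodesize = nodesize, importance = importance)
}

forest_oob_error <- function(rf) {
  if (rf$type == "classification") {
    unname(rf$err.rate[rf$ntree, "OOB"])
  } else {
    unname(rf$mse[rf$ntree])
  }
}

#' Permutation-importance ranking over replicate forests
#'
#' Grows `nfor_thres` forests of `ntree_thres` trees and averages the raw
#' permutation importance (mean decrease in accuracy for classification,
#' mean increase in MSE for regression) of each variable; ties in the mean
#' are broken by first appearance.
#'
#' @param X predictors (data.frame or matrix).
#' @param y response (factor or numeric per task).
#' @param config a [vsurf_config()].
#' @return data.frame ordered by descending mean importance: `variable`,
#'   `importance_mean`, `importance_sd`.
#' @export
rank_importance <- function(X, y, config = vsurf_config()) {
  d <- check_xy(X, y, config$task)
  if (ncol(d$X) < 2) stop("need >= 2 variables to rank")
  set.seed(config$seed)
  imp <- replicate(config$nfor_thres, {
    rf <- grow_forest(d$X, d$y, config$ntree_thres, config$mtry, config$task,
                      importance = TRUE)
    randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  })
  m <- rowMeans(imp)
  s <- apply(imp, 1, stats::sd)
  ord <- order(-m) # stable: ties keep first appearance
  data.frame(variable = colnames(d$X)[ord], importance_mean = m[ord],
             importance_sd = s[ord], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Stage 1: importance thresholding
#'
#' Fits an unlimited-depth piecewise-constant (CART) regression of the
#' importance sd on rank; the threshold is the minimum of the fitted curve,
#' and variables with mean importance >= threshold are retained.
#'
#' @param ranked output of [rank_importance()].
#' @return list: `vars_thresholded` (character, in importance order) and
#'   `threshold_value`.
#' @export
threshold_step <- function(ranked) {
  p <- nrow(ranked)
  if (p == 1) {
    return(list(vars_thresholded = ranked$variable, threshold_value = -Inf))
  }
  dat <- data.frame(rank = seq_len(p), s = ranked$importance_sd)
  tree <- rpart::rpart(s ~ rank, data = dat,
                       control = rpart::rpart.control(minsplit = 2,
                                                      minbucket = 1, cp = 0,
                                                      maxdepth = 30))
  thr <- min(stats::predict(tree))
  keep <- ranked$importance_mean >= thr
  if (!any(keep)) keep <- rep(TRUE, p) # degenerate: retain all
  list(vars_thresholded = ranked$variable[keep], threshold_value = thr)
}

# Mean/sd of OOB error for nested models var[1:k], k = 1..K.
nested_oob_path <- function(X, y, vars, ntree, nfor, task, mtry) {
  t(vapply(seq_along(vars), function(k) {
    errs <- replicate(nfor, {
      rf <- grow_forest(X[, vars[1:k], drop = FALSE], y, ntree, mtry, task)
      forest_oob_error(rf)
    })
    c(mean = mean(errs), sd = stats::sd(errs))
  }, c(mean = 0, sd = 0)))
}

#' Stage 2: interpretation set
#'
#' Grows nested models in importance order over the thresholded variables
#' and selects the smallest model whose mean OOB error is within one sd (at
#' the minimizer) of the global minimum mean OOB error.
#'
#' @param X,y data.
#' @param vars_thresholded stage-1 output, in importance order.
#' @param config a [vsurf_config()].
#' @return list: `vars_interpretation`, `oob_path` (data.frame with size,
#'   mean, sd).
#' @export
interpretation_step <- function(X, y, vars_thresholded, config = vsurf_config()) {
  d <- check_xy(X, y, config$task)
  set.seed(config$seed + 1L)
  path <- nested_oob_path(d$X, d$y, vars_thresholded, config$ntree_interp,
                          config$nfor_interp, config$task, config$mtry)
  i_min <- which.min(path[, "mean"])
  cutoff <- path[i_min, "mean"] + path[i_min, "sd"]
  k <- which(path[, "mean"] <= cutoff)[1]
  list(vars_interpretation = vars_thresholded[seq_len(k)],
       oob_path = data.frame(size = seq_along(vars_thresholded),
                             mean = path[, "mean"], sd = path[, "sd"]))
}

#' Stage 3: prediction set
#'
#' Stepwise inclusion in importance order: a variable enters only if it
#' lowers the mean OOB error (over `nfor_pred` forests) by more than the
#' noise threshold — the mean absolute first difference of OOB errors among
#' the stage-2-rejected nested models (0 if none were rejected). The first
#' variable is judged against the null-model error (majority-class error
#' rate, or the variance of `y`), so an all-noise input can yield an empty
#' prediction set.
#'
#' @param X,y data.
#' @param vars_interpretation stage-2 output.
#' @param oob_path stage-2 nested OOB path (over the thresholded variables).
#' @param config a [vsurf_config()].
#' @return character vector of selected variables (possibly empty).
#' @export
prediction_step <- function(X, y, vars_interpretation, oob_path,
                            config = vsurf_config()) {
  d <- check_xy(X, y, config$task)
  k_interp <- length(vars_interpretation)
  rejected <- oob_path$mean[oob_path$size > k_interp]
  noise_thr <- if (length(rejected) >= 2) mean(abs(diff(rejected))) else 0
  null_err <- if (config$task == "classification") {
    1 - max(table(d$y)) / length(d$y)
  } else {
    mean((d$y - mean(d$y))^2)
  }
  set.seed(config$seed + 2L)
  sel <- character(0)
  prev_err <- null_err
  for (v in vars_interpretation) {
    trial <- c(sel, v)
    errs <- replicate(config$nfor_pred, {
      rf <- grow_forest(d$X[, trial, drop = FALSE], d$y, config$ntree_pred,
                        config$mtry, config$task)
      forest_oob_error(rf)
    })
    err <- mean(errs)
    if (prev_err - err > noise_thr) {
      sel <- trial
      prev_err <- err
    }
  }
  sel
}

#' Run the full three-stage variable selection
#'
#' @param X predictors; @param y response; @param config a [vsurf_config()].
#' @return a `selection_result`: importance table, threshold, the three
#'   nested variable sets, and the stage-2 OOB error path.
#' @export
vsurf_select <- function(X, y, config = vsurf_config()) {
  ranked <- rank_importance(X, y, config)
  st1 <- threshold_step(ranked)
  st2 <- interpretation_step(X, y, st1$vars_thresholded, config)
  st3 <- prediction_step(X, y, st2$vars_interpretation, st2$oob_path, config)
  res <- list(importance = ranked, threshold_value = st1$threshold_value,
              vars_thresholded = st1$vars_thresholded,
              vars_interpretation = st2$vars_interpretation,
              vars_prediction = st3,
              oob_path = st2$oob_path, task = config$task)
  class(res) <- "selection_result"
  stopifnot(all(res$vars_prediction %in% res$vars_interpretation),
            all(res$vars_interpretation %in% res$vars_thresholded))
  res
}

#' Consensus biomarker candidates across selection runs
#'
#' Variables present in the interpretation sets of a strict majority of the
#' supplied selection results (e.g., classification/regression crossed with
#' within/between views), ranked by selection frequency and then mean
#' importance. If no variable reaches a majority, the top `target_size` by
#' frequency are returned with a warning.
#'
#' @param results list of `selection_result`s (>= 2).
#' @param target_size fallback candidate-list size (default 5).
#' @return data.frame: `variable`, `n_selected`, `mean_importance`,
#'   `consensus` flag; consensus rows first.
#' @export
consensus_candidates <- function(results, target_size = 5) {
  if (length(results) < 2) stop("need >= 2 selection results")
  sets <- lapply(results, `[[`, "vars_interpretation")
  vars <- unique(unlist(sets))
  freq <- vapply(vars, function(v) sum(vapply(sets, function(s) v %in% s,
                                              logical(1))), integer(1))
  imp <- vapply(vars, function(v) {
    vals <- vapply(results, function(r) {
      i <- match(v, r$importance$variable)
      if (is.na(i)) NA_real_ else r$importance$importance_mean[i]
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-freq, -imp)
  out <- data.frame(variable = vars[ord], n_selected = freq[ord],
                    mean_importance = imp[ord],
                    consensus = freq[ord] > length(results) / 2,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!any(out$consensus)) {
    warning("no variable selected by a strict majority; returning top ",
            target_size, " by frequency")
    out <- utils::head(out, target_size)
  }
  out
}
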