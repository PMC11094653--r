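#' Time-bin definition of the WR vs SD comparison
#'
#' Samples with time since wake inside `wr_range_h` (closed interval) are
#' labeled well-rested, inside `sd_range_h` sleep-deprived; samples outside
#' both are excluded from that comparison.
#'
#' @param wr_range_h,sd_range_h closed TSW intervals in hours; defaults
#'   `[0, 16]` vs `[24, 38]` (clock-time-matched, >24 h sleep deprivation).
#' @param label row label for scan tables.
#' @return a `condition_def` list.
#' @export
condition_def <- function(wr_range_h = c(0, 16), sd_range_h = c(24, 38),
                          label = NULL) {
  if (wr_range_h[1] > wr_range_h[2] || sd_range_h[1] > sd_range_h[2]) {
    stop("intervals must be ordered")
  }
  if (wr_range_h[2] >= sd_range_h[1] && sd_range_h[2] >= wr_range_h[1]) {
    if (max(wr_range_h[1], sd_range_h[1]) <= min(wr_range_h[2], sd_range_h[2])) {
      stop("WR and SD ranges must not overlap")
    }
  }
  if (is.null(label)) {
    label <- sprintf("%g-%g vs. %g-%g", wr_range_h[1], wr_range_h[2],
                     sd_range_h[1], sd_range_h[2])
  }
  structure(list(wr_range_h = wr_range_h, sd_range_h = sd_range_h,
                 label = label),
            class = "condition_def")
}

#' The six stepwise threshold-narrowing comparisons
#'
#' Starting from WR `[0,16]` vs SD `[24,38]`, 18/20/22-h samples are folded
#' stepwise into either condition, ending at the closest distinction
#' (below vs above 24 h awake).
#'
#' @return list of [condition_def()]s.
#' @export
default_threshold_conditions <- function() {
  list(
    condition_def(c(0, 16), c(18, 38)),
    condition_def(c(0, 16), c(20, 38)),
    condition_def(c(0, 16), c(22, 38)),
    condition_def(c(0, 18), c(24, 38)),
    condition_def(c(0, 20), c(24, 38)),
    condition_def(c(0, 23), c(24, 38))
  )
}

#' Random-forest hyperparameters for biomarker models
#'
#' @param seed forest seed (default 123, governing forest construction only).
#' @param mtry variables tried per split (default 3, capped at p).
#' @param ntree trees per forest (default 500).
#' @param nodesize_classification,nodesize_regression minimum terminal-node
#'   sizes (1 and 5).
#' @return an `rf_config` list.
#' @export
rf_config <- function(seed = 123L, mtry = 3, ntree = 500,
                      nodesize_classification = 1, nodesize_regression = 5) {
  structure(list(seed = as.integer(seed), mtry = mtry, ntree = ntree,
                 nodesize_classification = nodesize_classification,
                 nodesize_regression = nodesize_regression),
            class = "rf_config")
}

#' Label a view's samples WR/SD under a condition definition
#'
#' @param view a `data_view` or `feature_table`.
#' @param cond a [condition_def()].
#' @param features feature ids to keep as predictors (NULL = all).
#' @return list: `X` (data.frame of predictors), `y` (factor WR/SD),
#'   `meta` (sample metadata), `n_excluded`.
#' @export
assign_conditions <- function(view, cond, features = NULL) {
  tab <- if (inherits(view, "data_view")) view$table else view
  stopifnot(inherits(tab, "feature_table"), inherits(cond, "condition_def"))
  tsw <- tab$sample_meta$tsw_hours
  wr <- tsw >= cond$wr_range_h[1] & tsw <= cond$wr_range_h[2]
  sd_ <- tsw >= cond$sd_range_h[1] & tsw <= cond$sd_range_h[2]
  keep <- wr | sd_
  if (!any(wr) || !any(sd_)) stop("empty class under condition ", cond$label)
  sub <- ft_subset(tab, samples = which(keep), features = features)
  y <- factor(ifelse(wr[keep], "WR", "SD"), levels = c("WR", "SD"))
  list(X = as.data.frame(sub$intensities), y = y, meta = sub$sample_meta,
       n_excluded = sum(!keep))
}

#' Extract a view's predictors and TSW target for regression
#'
#' @inheritParams assign_conditions
#' @return list: `X`, `y` (numeric TSW hours), `meta`.
#' @export
tsw_data <- function(view, features = NULL) {
  tab <- if (inherits(view, "data_view")) view$table else view
  sub <- ft_subset(tab, features = features)
  list(X = as.data.frame(sub$intensities), y = sub$sample_meta$tsw_hours,
       meta = sub$sample_meta)
}

classification_report <- function(y, pred, scores = NULL, role = "testing",
                                  meta = NULL) {
  tn <- sum(y == "WR" & pred == "WR"); fp <- sum(y == "WR" & pred == "SD")
  fn <- sum(y == "SD" & pred == "WR"); tp <- sum(y == "SD" & pred == "SD")
  rates <- confusion_rates(tn, fp, fn, tp)
  n <- tn + fp + fn + tp
  ci <- exact_binomial_ci(tn + tp, n)
  roc <- NULL
  if (!is.null(scores) && length(unique(y)) == 2) {
    roc <- tryCatch(roc_auc(scores, y == "SD"), error = function(e) NULL)
  }
  list(role = role, task = "classification",
       confusion = c(tn = tn, fp = fp, fn = fn, tp = tp),
       n = n, accuracy_pct = 100 * rates$accuracy,
       ci95_pct = 100 * ci,
       rates_pct = lapply(rates, function(r) 100 * r),
       auc_pct = if (!is.null(roc)) roc$auc_pct else NA_real_,
       auc_ci95_pct = if (!is.null(roc)) roc$ci95 else c(NA_real_, NA_real_),
       roc = roc)
}

regression_report <- function(y, pred, role = "testing") {
  list(role = role, task = "regression",
       r2_pct = 100 * r_squared(pred, y),
       rmse_h = rmse(pred, y),
       percentile_error_h = percentile_abs_error(pred, y),
       n = length(y))
}

#' Train a WR/SD classification random forest
#'
#' Training accuracy is `1 - OOB error` with an exact binomial CI on the
#' OOB-correct count; variable importance is the permutation mean decrease
#' in accuracy.
#'
#' @param X data.frame/matrix of predictors; @param y factor WR/SD.
#' @param rf an [rf_config()].
#' @return list: `model` (randomForest), `report` (training model report
#'   including `importance`).
#' @export
train_classifier <- function(X, y, rf = rf_config()) {
  X <- as.data.frame(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("two classes required")
  if (rf$mtry > ncol(X)) stop("mtry exceeds number of predictors")
  set.seed(rf$seed)
  model <- randomForest::randomForest(
    x = X, y = y, ntree = rf$ntree, mtry = rf$mtry,
    nodesize = rf$nodesize_classification, importance = TRUE)
  oob_scores <- model$votes[, "SD"]
  rep <- classification_report(y, model$predicted, oob_scores, role = "training")
  rep$importance <- sort(randomForest::importance(model, type = 1)[, 1],
                         decreasing = TRUE)
  list(model = model, report = rep)
}

#' Train a time-since-wake regression random forest
#'
#' OOB `R^2` and RMSE summarize training fit; importance is the percent
#' increase in MSE on permutation.
#'
#' @param X predictors; @param y_tsw numeric hours since wake.
#' @param rf an [rf_config()].
#' @return list: `model`, `report`.
#' @export
train_regressor <- function(X, y_tsw, rf = rf_config()) {
  X <- as.data.frame(X)
  if (rf$mtry > ncol(X)) stop("mtry exceeds number of predictors")
  set.seed(rf$seed)
  model <- randomForest::randomForest(
    x = X, y = as.numeric(y_tsw), ntree = rf$ntree, mtry = rf$mtry,
    nodesize = rf$nodesize_regression, importance = TRUE)
  rep <- regression_report(as.numeric(y_tsw), model$predicted, role = "training")
  rep$importance <- sort(randomForest::importance(model, type = 1)[, 1],
                         decreasing = TRUE)
  list(model = model, report = rep)
}

#' Evaluate a trained model on the hold-out experiment
#'
#' Group-level confusion/accuracy/exact-CI/AUC (classification; ROC scores
#' are the fraction of trees voting SD) or signed test-set R^2, RMSE and
#' percentile errors (regression), plus per-participant sub-reports computed
#' on each test participant's samples only.
#'
#' @param fit output of [train_classifier()] or [train_regressor()].
#' @param test list from [assign_conditions()] or [tsw_data()] on the test
#'   view (same features, identical preprocessing).
#' @return a testing model report with `$per_participant`.
#' @export
evaluate_holdout <- function(fit, test) {
  model <- fit$model
  if (!identical(sort(rownames(model$importance)), sort(colnames(test$X)))) {
    stop("feature mismatch between training model and test data")
  }
  part <- as.character(test$meta$participant_id)
  if (model$type == "classification") {
    pred <- stats::predict(model, test$X)
    scores <- stats::predict(model, test$X, type = "vote")[, "SD"]
    rep <- classification_report(test$y, pred, scores, role = "testing")
    rep$per_participant <- lapply(split(seq_along(part), part), function(idx) {
      sc <- if (length(unique(test$y[idx])) == 2) scores[idx] else NULL
      classification_report(test$y[idx], pred[idx], sc, role = "testing")
    })
  } else {
    pred <- stats::predict(model, test$X)
    rep <- regression_report(test$y, pred, role = "testing")
    rep$per_participant <- lapply(split(seq_along(part), part), function(idx) {
      regression_report(test$y[idx], pred[idx], role = "testing")
    })
  }
  rep
}

#' Train/test the classifier across a list of condition definitions
#'
#' One full train/test cycle per WR/SD time-bin definition; failed
#' definitions are flagged and the scan continues.
#'
#' @param train_view,test_view prepared views of the two experiments.
#' @param features predictor feature ids (the biomarker candidates).
#' @param conds list of [condition_def()]s.
#' @param rf an [rf_config()].
#' @return list with `reports` (per condition) and `summary` data.frame
#'   (label, n train/test, accuracy, CI, AUC, error flag).
#' @export
threshold_scan <- function(train_view, test_view, features,
                           conds = default_threshold_conditions(),
                           rf = rf_config()) {
  rf <- local({x <- rf; x$mtry <- min(x$mtry, length(features)); x})
  reports <- vector("list", length(conds))
  rows <- lapply(seq_along(conds), function(i) {
    cond <- conds[[i]]
    out <- tryCatch({
      tr <- assign_conditions(train_view, cond, features)
      te <- assign_conditions(test_view, cond, features)
      fit <- train_classifier(tr$X, tr$y, rf)
      rep <- evaluate_holdout(fit, te)
      reports[[i]] <<- list(condition = cond, training = fit$report,
                            testing = rep)
      data.frame(label = cond$label, n_train = length(tr$y),
                 n_test = rep$n, accuracy_pct = rep$accuracy_pct,
                 ci_lower_pct = rep$ci95_pct[1], ci_upper_pct = rep$ci95_pct[2],
                 auc_pct = rep$auc_pct, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(label = cond$label, n_train = NA_integer_, n_test = NA_integer_,
                 accuracy_pct = NA_real_, ci_lower_pct = NA_real_,
                 ci_upper_pct = NA_real_, auc_pct = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    out
  })
  list(reports = reports, summary = do.call(rbind, rows))
}

#' Train/test all candidate subsets of size >= k_min
#'
#' Enumerates every combination of the candidate features with at least
#' `k_min` members, trains and tests each (mtry capped at the subset size),
#' and assesses test accuracy against the no-information rate (majority
#' class of the evaluated test subset) with a one-sided exact binomial test,
#' Bonferroni-corrected across combinations.
#'
#' @param train_view,test_view prepared views.
#' @param candidates character vector of candidate feature ids (>= 2).
#' @param cond the WR/SD [condition_def()] to model.
#' @param rf an [rf_config()].
#' @param k_min smallest subset size (default 2).
#' @return data.frame, one row per combination: members, size, test
#'   accuracy, AUC, no-information rate, raw and Bonferroni-adjusted p.
#' @export
combo_scan <- function(train_view, test_view, candidates,
                       cond = condition_def(), rf = rf_config(), k_min = 2) {
  if (length(candidates) < 2) stop("need >= 2 candidates")
  combos <- unlist(lapply(k_min:length(candidates), function(k) {
    utils::combn(candidates, k, simplify = FALSE)
  }), recursive = FALSE)
  n_comb <- length(combos)
  tr_all <- assign_conditions(train_view, cond, candidates)
  te_all <- assign_conditions(test_view, cond, candidates)
  nir <- max(table(te_all$y)) / length(te_all$y)
  rows <- lapply(combos, function(vars) {
    rf_k <- rf
    rf_k$mtry <- min(rf$mtry, length(vars))
    fit <- train_classifier(tr_all$X[, vars, drop = FALSE], tr_all$y, rf_k)
    te <- list(X = te_all$X[, vars, drop = FALSE], y = te_all$y,
               meta = te_all$meta)
    rep <- evaluate_holdout(fit, te)
    correct <- rep$confusion[["tn"]] + rep$confusion[["tp"]]
    p <- stats::binom.test(correct, rep$n, p = nir,
                           alternative = "greater")$p.value
    data.frame(combination = paste(vars, collapse = "+"),
               size = length(vars), accuracy_pct = rep$accuracy_pct,
               auc_pct = rep$auc_pct, no_information_rate_pct = 100 * nir,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * n_comb)
  out
}
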