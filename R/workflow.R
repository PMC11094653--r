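#' Resolved configuration for a full discovery run
#'
#' @param train_experiment_id,test_experiment_id experiment labels; must
#'   differ (hold-out hygiene). Swapping them runs the sanity check on the
#'   identical code path.
#' @param max_zero_fraction,imputation,imputation_seed preprocessing knobs.
#' @param filter named list of [apply_apriori_filter()] arguments.
#' @param vsurf a [vsurf_config()] (task/seed are set per approach).
#' @param rf an [rf_config()].
#' @param conditions list of [condition_def()]s for the threshold scan
#'   (NULL skips the scan).
#' @param approaches which selection approaches feed the consensus; subset of
#'   `"classification_within"`, `"classification_between"`,
#'   `"regression_within"`, `"regression_between"`.
#' @param n_candidates consensus fallback size.
#' @return a `run_config` list.
#' @export
run_config <- function(train_experiment_id, test_experiment_id,
                       max_zero_fraction = 0.20,
                       imputation = "truncated_normal_qr",
                       imputation_seed = 1L,
                       filter = list(),
                       vsurf = vsurf_config(),
                       rf = rf_config(),
                       conditions = NULL,
                       approaches = c("classification_within",
                                      "classification_between",
                                      "regression_within",
                                      "regression_between"),
                       n_candidates = 5) {
  if (identical(train_experiment_id, test_experiment_id)) {
    stop("train and test experiments must differ")
  }
  structure(list(train_experiment_id = train_experiment_id,
                 test_experiment_id = test_experiment_id,
                 max_zero_fraction = max_zero_fraction,
                 imputation = imputation, imputation_seed = imputation_seed,
                 filter = filter, vsurf = vsurf, rf = rf,
                 conditions = conditions, approaches = approaches,
                 n_candidates = n_candidates),
            class = "run_config")
}

object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full biomarker discovery pipeline
#'
#' Executes preprocess -> characterize -> a priori filter -> three-stage
#' variable selection -> consensus candidates -> hold-out models
#' (classification of WR vs SD and regression of TSW, on the within and
#' between views), entirely on the training experiment until the final
#' hold-out evaluation. Returns a manifest with every stage's report,
#' resolved configuration, seeds, stage counts and artifact checksums.
#'
#' @param tables named list of raw `feature_table`s keyed by experiment id.
#' @param config a [run_config()].
#' @return a `run_manifest` list.
#' @export
run_discovery <- function(tables, config) {
  stopifnot(inherits(config, "run_config"))
  for (id in c(config$train_experiment_id, config$test_experiment_id)) {
    if (!id %in% names(tables)) stop("missing input table: ", id)
  }
  train_raw <- tables[[config$train_experiment_id]]
  test_raw <- tables[[config$test_experiment_id]]
  counts <- list(features_raw = ncol(train_raw$intensities))

  train_views <- prepare_views(train_raw, config$max_zero_fraction,
                               config$imputation, config$imputation_seed)
  test_views <- prepare_views(test_raw, config$max_zero_fraction,
                              config$imputation, config$imputation_seed)
  # the hold-out test set only keeps features retained in training
  common <- intersect(train_views$within$table$feature_meta$feature_id,
                      test_views$within$table$feature_meta$feature_id)
  counts$features_clean <- length(common)

  ind_cat <- characterize(train_views$within, "individual")
  grp_cat <- characterize(train_views$within, "group")
  filt <- do.call(apply_apriori_filter,
                  c(list(ind_cat, grp_cat), config$filter))
  filtered_feats <- intersect(filt$feature_id[filt$passed], common)
  counts$features_filtered <- length(filtered_feats)
  if (length(filtered_feats) < 2) {
    stop("stage apriori_filter: fewer than 2 features pass")
  }

  selections <- list()
  for (app in config$approaches) {
    task <- if (grepl("classification", app)) "classification" else "regression"
    view <- if (grepl("within", app)) train_views$within else train_views$between
    vc <- config$vsurf
    vc$task <- task
    if (task == "classification") {
      dd <- assign_conditions(view, condition_def(), filtered_feats)
    } else {
      dd <- tsw_data(view, filtered_feats)
    }
    selections[[app]] <- vsurf_select(dd$X, dd$y, vc)
  }
  cand_tab <- consensus_candidates(selections, config$n_candidates)
  candidates <- cand_tab$variable[cand_tab$consensus]
  if (length(candidates) < 2) candidates <- utils::head(cand_tab$variable, config$n_candidates)
  counts$candidates <- length(candidates)

  rf_run <- config$rf
  rf_run$mtry <- min(rf_run$mtry, length(candidates))
  model_reports <- list()
  for (view_kind in c("within", "between")) {
    trv <- train_views[[view_kind]]
    tev <- test_views[[view_kind]]
    tr_c <- assign_conditions(trv, condition_def(), candidates)
    te_c <- assign_conditions(tev, condition_def(), candidates)
    fit_c <- train_classifier(tr_c$X, tr_c$y, rf_run)
    model_reports[[paste0("classification_", view_kind)]] <-
      list(training = fit_c$report, testing = evaluate_holdout(fit_c, te_c))
    tr_r <- tsw_data(trv, candidates)
    te_r <- tsw_data(tev, candidates)
    fit_r <- train_regressor(tr_r$X, tr_r$y, rf_run)
    model_reports[[paste0("regression_", view_kind)]] <-
      list(training = fit_r$report, testing = evaluate_holdout(fit_r, te_r))
  }

  scan <- NULL
  if (!is.null(config$conditions)) {
    scan <- threshold_scan(train_views$within, test_views$within, candidates,
                           config$conditions, config$rf)
  }

  manifest <- list(
    config = config,
    counts = counts,
    characterization = list(individual = ind_cat, group = grp_cat),
    filter_report = filt,
    selections = selections,
    candidates = candidates,
    candidate_table = cand_tab,
    model_reports = model_reports,
    threshold_scan = scan,
    views = list(train = train_views, test = test_views)
  )
  manifest$checksums <- list(
    filter = object_checksum(filt),
    candidates = object_checksum(candidates),
    models = object_checksum(model_reports)
  )
  class(manifest) <- "run_manifest"
  manifest
}

#' Run the recovery-after-sleep validation
#'
#' Builds the pre/post-sleep contrasts for both designs (clock-matched and
#' evening/morning) across the supplied protocols and fits the mixed-model
#' contrasts; optionally compares meal-timing influence on a well-rested day.
#'
#' @param tables named list of within-view tables (`data_view` or z-scored
#'   `feature_table`) per protocol; must include at least one
#'   sleep-deprivation experiment and the matched control.
#' @param candidates character vector of candidate feature ids (>= 1).
#' @return list with one `recovery_result` per design plus the stacked
#'   tables.
#' @export
run_recovery <- function(tables, candidates) {
  if (length(candidates) == 0) stop("candidate list is empty")
  out <- list()
  for (kind in c("clock_matched", "evening_morning")) {
    stacked <- build_pre_post(tables, prepost_design(kind), candidates)
    out[[kind]] <- list(stacked = stacked, result = fit_prepost_model(stacked))
  }
  out
}
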