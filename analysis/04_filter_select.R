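#!/usr/bin/env Rscript
# Step 4 — a priori filter and three-stage variable selection.
#
# Training-experiment features must be significantly, consistently linear in
# a majority of participants and at the group level, and rhythmic in no more
# than a quarter of participants. Survivors enter the three-stage
# random-forest selection (thresholding / interpretation / prediction) run
# for classification and regression on both views; candidates are the
# variables selected by a strict majority of the interpretation sets.

library(wakemark)

exp1 <- read_feature_table("results/data", "exp1")
v1 <- prepare_views(exp1, imputation_seed = 1)

ind <- characterize(v1$within, "individual")
grp <- characterize(v1$within, "group")
filt <- apply_apriori_filter(ind, grp)
cat(sprintf("a priori filter: %d of %d features pass (%.1f%%)\n",
            sum(filt$passed), nrow(filt), 100 * mean(filt$passed)))
utils::write.csv(filt, "results/filter_report.csv", row.names = FALSE)

feats <- filt$feature_id[filt$passed]
selections <- list()
for (app in c("classification_within", "classification_between",
              "regression_within", "regression_between")) {
  task <- if (grepl("classification", app)) "classification" else "regression"
  view <- if (grepl("within", app)) v1$within else v1$between
  dd <- if (task == "classification") {
    assign_conditions(view, condition_def(), feats)
  } else {
    tsw_data(view, feats)
  }
  sel <- vsurf_select(dd$X, dd$y, vsurf_config(seed = 5, task = task))
  selections[[app]] <- sel
  cat(sprintf("%s: %d thresholded -> %d interpretation -> %d prediction\n",
              app, length(sel$vars_thresholded),
              length(sel$vars_interpretation), length(sel$vars_prediction)))
}
cons <- consensus_candidates(selections, target_size = 5)
utils::write.csv(cons, "results/candidates.csv", row.names = FALSE)
cat("consensus candidates:",
    paste(cons$variable[cons$consensus], collapse = ", "), "\n")
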