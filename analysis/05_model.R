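#!/usr/bin/env Rscript
# Step 5 — hold-out modeling of the biomarker candidates.
#
# Using the consensus candidates from step 4 (experiment 1 training only),
# random forests classify well-rested [0,16 h] vs sleep-deprived [24,38 h]
# and regress time since wake, on both views; every model is then evaluated
# on the unseen experiment 2, followed by the six stepwise
# threshold-narrowing comparisons and the all-subsets combination scan.

library(wakemark)

exp1 <- read_feature_table("results/data", "exp1")
exp2 <- read_feature_table("results/data", "exp2")
v1 <- prepare_views(exp1, imputation_seed = 1)
v2 <- prepare_views(exp2, imputation_seed = 1)
cons <- utils::read.csv("results/candidates.csv")
cands <- cons$variable[cons$consensus]
if (length(cands) < 2) cands <- utils::head(cons$variable, 5)
cands <- intersect(cands, v2$within$table$feature_meta$feature_id)
cat("candidates:", paste(cands, collapse = ", "), "\n")
rf <- rf_config(mtry = min(3, length(cands)))

rows <- list()
for (vk in c("within", "between")) {
  tr <- assign_conditions(v1[[vk]], condition_def(), cands)
  te <- assign_conditions(v2[[vk]], condition_def(), cands)
  fit <- train_classifier(tr$X, tr$y, rf)
  rep <- evaluate_holdout(fit, te)
  cat(sprintf(
    "%s classification: train acc %.1f%%, test acc %.1f%% (%.1f-%.1f), AUC %.1f%%\n",
    vk, fit$report$accuracy_pct, rep$accuracy_pct,
    rep$ci95_pct[1], rep$ci95_pct[2], rep$auc_pct))
  rows[[paste0("cls_", vk)]] <- data.frame(
    view = vk, task = "classification",
    train = fit$report$accuracy_pct, test = rep$accuracy_pct,
    auc = rep$auc_pct, r2 = NA, rmse = NA)
  trr <- tsw_data(v1[[vk]], cands)
  ter <- tsw_data(v2[[vk]], cands)
  fr <- train_regressor(trr$X, trr$y, rf)
  rr <- evaluate_holdout(fr, ter)
  cat(sprintf("%s regression: train R2 %.1f%%, test R2 %.1f%%, RMSE %.2f h, median |err| %.2f h\n",
              vk, fr$report$r2_pct, rr$r2_pct, rr$rmse_h,
              rr$percentile_error_h[[1]]))
  rows[[paste0("reg_", vk)]] <- data.frame(
    view = vk, task = "regression", train = fr$report$r2_pct,
    test = rr$r2_pct, auc = NA, r2 = rr$r2_pct, rmse = rr$rmse_h)
}
utils::write.csv(do.call(rbind, rows), "results/holdout_models.csv",
                 row.names = FALSE)

scan <- threshold_scan(v1$within, v2$within, cands, rf = rf)
print(scan$summary[, c("label", "n_test", "accuracy_pct", "auc_pct")])
utils::write.csv(scan$summary, "results/threshold_scan.csv", row.names = FALSE)

combos <- combo_scan(v1$within, v2$within, utils::head(cands, 5), rf = rf)
cat(sprintf("combination scan: %d models, accuracy %.1f-%.1f%%, %d significant after Bonferroni\n",
            nrow(combos), min(combos$accuracy_pct), max(combos$accuracy_pct),
            sum(combos$p_bonferroni < 0.05)))
utils::write.csv(combos, "results/combo_scan.csv", row.names = FALSE)
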