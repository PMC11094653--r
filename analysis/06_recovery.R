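#!/usr/bin/env Rscript
# Step 6 — does the biomarker recover after a night of sleep?
#
# Candidate z-scores in 4-h blocks before and after the habitual sleep
# interval are contrasted with mixed models (random participant intercept),
# for both the clock-matched and evening/morning designs, in the
# sleep-deprivation experiments and the matched control; finally the
# well-rested day is compared across meal schedules.

library(wakemark)

exp1 <- read_feature_table("results/data", "exp1")
exp2 <- read_feature_table("results/data", "exp2")
ctrl <- read_feature_table("results/data", "ctrl")
v1 <- prepare_views(exp1, imputation_seed = 1)
v2 <- prepare_views(exp2, imputation_seed = 1)
vc <- prepare_views(ctrl, imputation_seed = 1)
cons <- utils::read.csv("results/candidates.csv")
cands <- cons$variable[cons$consensus]
if (length(cands) < 2) cands <- utils::head(cons$variable, 5)
cands <- Reduce(intersect, list(cands,
                                vc$within$table$feature_meta$feature_id,
                                v2$within$table$feature_meta$feature_id))

rec <- run_recovery(list(sleep_deprivation_exp1 = v1$within,
                         sleep_deprivation_exp2 = v2$within,
                         matched_control = vc$within), cands)
for (design in names(rec)) {
  res <- rec[[design]]$result
  cat("\n==", design, "==\n")
  print(res[, c("metabolite", "protocol", "estimate", "df", "t_ratio",
                "p_fdr", "trend")], digits = 3)
  utils::write.csv(res, file.path("results",
                                  paste0("recovery_", design, ".csv")),
                   row.names = FALSE)
}

# meal timing: z-score each protocol across its compared well-rested day
sd_day <- zscore_within_participant(ft_subset(
  v1$between$table,
  samples = which(v1$between$table$sample_meta$tsw_hours <= 16)))
ctrl_day <- zscore_within_participant(ft_subset(
  vc$between$table,
  samples = which(vc$between$table$sample_meta$day_index == 3)))
meals <- meal_timing_comparison(ctrl_day, sd_day, cands)
cat("\nmeal-timing interaction p-values (large = trend not diet-dependent):\n")
print(meals, digits = 3)
utils::write.csv(meals, "results/meal_timing.csv", row.names = FALSE)
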