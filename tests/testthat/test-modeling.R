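test_that("condition assignment uses closed intervals and drops the gap", {
  study <- synth_study(c(linear = 3, null = 7),
                       seeds = c(11, 12, 13))
  full <- generate_sleep_dep_experiment(
    study$panel, protocol_spec("sleep_deprivation", 12, seed = 21), "full")
  d <- assign_conditions(full, condition_def())
  expect_true(all(d$meta$tsw_hours <= 16 | d$meta$tsw_hours >= 24))
  # boundary membership: 16 h is WR, 24 h is SD, 18-22 h excluded
  expect_true(all(d$y[d$meta$tsw_hours == 16] == "WR"))
  expect_true(all(d$y[d$meta$tsw_hours == 24] == "SD"))
  expect_equal(d$n_excluded, 12 * 3) # 18, 20, 22 h for each participant
  # 8 WR + 8 SD per complete participant on the bi-hourly grid
  per_part <- table(d$meta$participant_id, d$y)
  expect_true(all(per_part == 8))
  expect_error(assign_conditions(full, condition_def(c(0, 1), c(39, 40))),
               "empty class")
  expect_error(condition_def(c(0, 25), c(24, 38)), "overlap")
})

test_that("classifier training is deterministic, separable when separable, null when null", {
  set.seed(31)
  n <- 120
  X <- data.frame(a = c(rnorm(n / 2, -3), rnorm(n / 2, 3)), b = rnorm(n))
  y <- factor(rep(c("WR", "SD"), each = n / 2), levels = c("WR", "SD"))
  rf <- rf_config(mtry = 2)
  fit <- train_classifier(X, y, rf)
  expect_gte(fit$report$accuracy_pct, 99)
  expect_identical(stats::predict(fit$model, X),
                   stats::predict(train_classifier(X, y, rf)$model, X))
  # permuted labels: OOB accuracy consistent with the class-balance baseline
  set.seed(32)
  yperm <- sample(y)
  fitp <- train_classifier(X, yperm, rf)
  ci <- exact_binomial_ci(round(fitp$report$accuracy_pct / 100 * n), n)
  expect_true(0.5 >= ci[1] - 0.05 && 0.5 <= ci[2] + 0.05)
  expect_error(train_classifier(X, y, rf_config(mtry = 5)), "mtry")
})

test_that("regressor recovers a deterministic signal and fails an independent one", {
  set.seed(33)
  n <- 150
  X <- data.frame(a = runif(n, 0, 10), b = rnorm(n))
  fit <- train_regressor(X, X$a^2, rf_config(mtry = 2))
  expect_gte(fit$report$r2_pct, 95)
  fit0 <- train_regressor(X, rnorm(n), rf_config(mtry = 2))
  expect_lte(fit0$report$r2_pct, 5) # OOB R^2 of noise hovers at/below zero
})

test_that("hold-out evaluation reproduces its accuracy identity and per-participant split", {
  study <- synth_study(c(linear = 6, null = 24), seeds = c(41, 42, 43))
  v1 <- prepare_views(study$exp1)
  v2 <- prepare_views(study$exp2)
  cands <- planted_candidates(study$panel, 4)
  cands <- intersect(cands, v1$within$table$feature_meta$feature_id)
  tr <- assign_conditions(v1$within, condition_def(), cands)
  te <- assign_conditions(v2$within, condition_def(), cands)
  fit <- train_classifier(tr$X, tr$y, rf_config())
  rep <- evaluate_holdout(fit, te)
  expect_equal(rep$accuracy_pct,
               100 * (rep$confusion[["tn"]] + rep$confusion[["tp"]]) / rep$n)
  expect_equal(sum(rep$confusion), rep$n)
  expect_setequal(names(rep$per_participant), unique(te$meta$participant_id))
  pp_n <- vapply(rep$per_participant, `[[`, numeric(1), "n")
  expect_equal(sum(pp_n), rep$n)
  # feature mismatch is an error
  bad <- te
  names(bad$X)[1] <- "wrong"
  expect_error(evaluate_holdout(fit, bad), "mismatch")
  # regression path: signed test R^2 with percentile errors
  trr <- tsw_data(v1$within, cands)
  ter <- tsw_data(v2$within, cands)
  fr <- train_regressor(trr$X, trr$y, rf_config())
  rr <- evaluate_holdout(fr, ter)
  expect_true(is.finite(rr$r2_pct))
  expect_equal(rr$rmse_h, rmse(stats::predict(fr$model, ter$X), ter$y))
})

test_that("threshold scan survives degenerate definitions and flags them", {
  study <- synth_study(c(linear = 5, null = 15), seeds = c(51, 52, 53))
  v1 <- prepare_views(study$exp1)
  v2 <- prepare_views(study$exp2)
  cands <- intersect(planted_candidates(study$panel, 3),
                     v1$within$table$feature_meta$feature_id)
  conds <- list(condition_def(), condition_def(c(0, 16), c(39, 40)))
  scan <- threshold_scan(v1$within, v2$within, cands, conds,
                         rf_config(ntree = 100))
  expect_equal(nrow(scan$summary), 2)
  expect_true(is.na(scan$summary$error[1]))
  expect_false(is.na(scan$summary$error[2]))
  expect_gt(scan$summary$accuracy_pct[1], 50)
})

test_that("combination scan enumerates subsets and tolerates redundancy", {
  study <- synth_study(c(linear = 8, null = 12), seeds = c(61, 62, 63))
  v1 <- prepare_views(study$exp1)
  v2 <- prepare_views(study$exp2)
  cands <- intersect(planted_candidates(study$panel, 5),
                     v1$within$table$feature_meta$feature_id)[1:3]
  combos <- combo_scan(v1$within, v2$within, cands, rf = rf_config(ntree = 100))
  expect_equal(nrow(combos), 4) # C(3,2) + C(3,3)
  expect_true(all(combos$p_bonferroni >= combos$p_value))
  expect_true(all(combos$p_bonferroni <= 1))
  # removing one of several redundant strong features barely moves accuracy
  full_acc <- combos$accuracy_pct[combos$size == 3]
  pair_acc <- max(combos$accuracy_pct[combos$size == 2])
  expect_lt(full_acc - pair_acc, 10)
  expect_error(combo_scan(v1$within, v2$within, cands[1]), ">= 2")
})
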