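test_that("pre/post stacking selects exactly the designed blocks", {
  study <- synth_study(c(linear = 4, null = 6), seeds = c(71, 72, 73))
  v1 <- prepare_views(study$exp1)
  vc <- prepare_views(study$ctrl)
  cands <- intersect(planted_candidates(study$panel, 2),
                     intersect(v1$within$table$feature_meta$feature_id,
                               vc$within$table$feature_meta$feature_id))
  tabs <- list(sleep_dep = v1$within, matched_control = vc$within)
  st <- build_pre_post(tabs, prepost_design("clock_matched"), cands)
  sd_rows <- st[st$protocol == "sleep_dep", ]
  expect_true(all(sd_rows$tsw_hours[sd_rows$period == "pre"] >= 2 &
                    sd_rows$tsw_hours[sd_rows$period == "pre"] <= 6))
  expect_true(all(sd_rows$tsw_hours[sd_rows$period == "post"] >= 26 &
                    sd_rows$tsw_hours[sd_rows$period == "post"] <= 30))
  ev <- build_pre_post(tabs, prepost_design("evening_morning"), cands)
  ctrl_pre <- ev[ev$protocol == "matched_control" & ev$period == "pre", ]
  expect_true(all(ctrl_pre$tsw_hours >= 12 & ctrl_pre$tsw_hours <= 16))
  ctrl_post <- ev[ev$protocol == "matched_control" & ev$period == "post", ]
  expect_true(all(ctrl_post$tsw_hours >= 2 & ctrl_post$tsw_hours <= 6))
  # control: 15 samples per condition (5 participants x 3 block samples)
  expect_equal(sum(ev$protocol == "matched_control" & ev$period == "pre"),
               15 * length(cands))
  expect_error(build_pre_post(tabs, prepost_design(), character(0)), "empty")
  expect_error(build_pre_post(tabs, prepost_design(), "NOPE"), "absent")
})

test_that("mixed-model contrasts detect a planted shift and stay quiet without one", {
  set.seed(81)
  parts <- rep(sprintf("P%02d", 1:8), each = 6)
  period <- rep(rep(c("pre", "post"), each = 3), 8)
  base <- rnorm(8, 0, 0.5)[rep(1:8, each = 6)]
  noise <- rnorm(48, 0, 0.3)
  shifted <- data.frame(
    value_z = base + noise + ifelse(period == "post", 1, 0),
    period = period, participant = parts, protocol = "sleep_dep",
    metabolite = "M1")
  flat <- shifted
  flat$value_z <- base + noise
  flat$metabolite <- "M2"
  res <- fit_prepost_model(rbind(shifted, flat))
  r1 <- res[res$metabolite == "M1", ]
  expect_equal(r1$estimate, 1, tolerance = 0.25)
  expect_equal(r1$trend, "increasing")
  expect_equal(res$trend[res$metabolite == "M2"], "not_significant")
  expect_true(all(res$p_fdr >= res$p_value - 1e-12))
})

test_that("an exactly unchanged series degrades gracefully to a zero estimate", {
  d <- data.frame(value_z = rep(c(1, 2, 3), 4),
                  period = rep(c("pre", "post"), each = 3),
                  participant = rep(c("A", "B"), each = 6),
                  protocol = "p", metabolite = "M")
  res <- suppressMessages(fit_prepost_model(d))
  expect_equal(res$estimate, 0, tolerance = 1e-9)
  expect_equal(res$trend, "not_significant")
})

test_that("planted reversal: rises under extended wake, resets after sleep", {
  study <- synth_study(c(linear = 10, circadian = 20, null = 170),
                       seeds = c(91, 92, 93))
  v1 <- prepare_views(study$exp1)
  vc <- prepare_views(study$ctrl)
  cands <- intersect(planted_candidates(study$panel, 5),
                     intersect(v1$within$table$feature_meta$feature_id,
                               vc$within$table$feature_meta$feature_id))
  rec <- run_recovery(list(sleep_dep = v1$within, matched_control = vc$within),
                      cands)
  res <- rec$clock_matched$result
  truth_sign <- sign(study$panel$slope[match(res$metabolite,
                                             study$panel$feature_id)])
  sd_rows <- res$protocol == "sleep_dep"
  expect_true(all(res$trend[sd_rows] ==
                    ifelse(truth_sign[sd_rows] > 0, "increasing", "decreasing")))
  ctrl_rows <- res$protocol == "matched_control"
  ok <- res$trend[ctrl_rows] == "not_significant" |
    (sign(res$estimate[ctrl_rows]) != truth_sign[ctrl_rows])
  expect_true(all(ok))
})

test_that("meal-timing interaction is null for a shared process, detected when planted", {
  study <- synth_study(c(linear = 5, null = 45), seeds = c(95, 96, 97))
  # well-rested day: control day-3 vs sleep-deprivation first 16 h,
  # z-scored across the compared day only so the scales are commensurate
  v1 <- prepare_views(study$exp1, views = "between")
  vc <- prepare_views(study$ctrl, views = "between")
  cands <- intersect(planted_candidates(study$panel, 3),
                     intersect(v1$between$table$feature_meta$feature_id,
                               vc$between$table$feature_meta$feature_id))
  sd_day <- zscore_within_participant(ft_subset(
    v1$between$table,
    samples = which(v1$between$table$sample_meta$tsw_hours <= 16)))
  ctrl_day <- zscore_within_participant(ft_subset(
    vc$between$table,
    samples = which(vc$between$table$sample_meta$day_index == 3)))
  got <- meal_timing_comparison(ctrl_day, sd_day, cands)
  expect_equal(nrow(got), length(cands))
  expect_true(all(got$p_interaction > 0.001)) # same generating process
  # the same table twice: interaction exactly zero
  same <- suppressMessages(meal_timing_comparison(sd_day, sd_day, cands[1]))
  expect_lt(abs(same$interaction_estimate), 1e-6)
  # planted protocol-specific slope: double the drift in one protocol
  doubled <- sd_day
  cand1 <- cands[1]
  doubled$intensities[, cand1] <- doubled$intensities[, cand1] +
    0.1 * doubled$sample_meta$tsw_hours
  det <- meal_timing_comparison(ctrl_day, doubled, cand1)
  expect_lt(det$p_interaction, 0.05)
})
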