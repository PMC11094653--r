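tt <- seq(2, 38, by = 2) # the bi-hourly extended-wake sampling grid

test_that("linear fit recovers exact and noisy slopes with sane p-values", {
  f <- fit_linear(0.5 * tt, tt)
  expect_equal(f$slope, 0.5)
  expect_lt(f$p_value, 1e-12)
  expect_equal(f$direction, 1)
  # flat series is non-significant, not spuriously certain
  f0 <- fit_linear(rep(3, 19), tt)
  expect_equal(f0$slope, 0)
  expect_equal(f0$p_value, 1)
  set.seed(5)
  fn <- fit_linear(tt + rnorm(19), tt)
  expect_lt(abs(fn$slope - 1), 0.1)
  expect_error(fit_linear(c(1, 2), c(1, 2)), "distinct times")
  expect_error(fit_linear(1:5, rep(2, 5)), "distinct times")
})

test_that("cosinor fit recovers amplitude, acrophase and quadrature shift exactly", {
  w <- 2 * pi / 24
  f <- fit_cosinor(2 + cos(w * tt), tt)
  expect_equal(f$amplitude, 1, tolerance = 1e-9)
  expect_equal(f$acrophase_h, 0, tolerance = 1e-9)
  expect_equal(f$mesor, 2, tolerance = 1e-9)
  expect_lt(f$p_value, 1e-12)
  fs <- fit_cosinor(2 + sin(w * tt), tt)
  expect_equal(fs$amplitude, 1, tolerance = 1e-9)
  expect_equal(fs$acrophase_h, 6, tolerance = 1e-9)
  expect_error(fit_cosinor(1:4, c(1, 2, 3, 4)), "span")
})

test_that("cosinor joint test holds its nominal type-I rate on white noise", {
  set.seed(1)
  p <- replicate(1000, fit_cosinor(rnorm(19), tt)$p_value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
  # roughly uniform: KS against U(0,1)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("amplitude is invariant to time-origin shifts; acrophase moves mod 24", {
  w <- 2 * pi / 24
  y <- 5 + 2 * cos(w * (tt - 8)) + c(rnorm(19, 0, 0.3))
  f1 <- fit_cosinor(y, tt)
  f2 <- fit_cosinor(y, tt + 10)
  expect_equal(f1$amplitude, f2$amplitude, tolerance = 1e-9)
  expect_equal((f1$acrophase_h + 10) %% 24, f2$acrophase_h, tolerance = 1e-6)
})

test_that("joint linear+cosinor fit separates drift from rhythm over 1.5 cycles", {
  w <- 2 * pi / 24
  # noiseless: with the linear covariate the amplitude is exact at any phase
  for (phi in c(0, 5, 13, 20)) {
    y <- 10 + 3 * tt + 2 * cos(w * (tt - phi))
    expect_equal(fit_cosinor(y, tt, linear_covariate = TRUE)$amplitude, 2,
                 tolerance = 1e-9)
  }
  # mixed-profile draw: slope 2/h, amplitude 5, unit noise, 19 samples
  spec <- feature_profile_spec("mixed", slope_per_hour = 2, amplitude = 5,
                               acrophase_h = 8, baseline_log_mean = 5,
                               noise_sd = 1)
  set.seed(99)
  y <- simulate_feature_profile(spec, tt)
  expect_lt(abs(fit_cosinor(y, tt, linear_covariate = TRUE)$amplitude - 5), 0.5)
  expect_lt(abs(fit_linear(y, tt)$slope - 2), 0.2)
})

test_that("group characterization flags planted homeostatic features", {
  study <- synth_study(c(linear = 20, circadian = 50, mixed = 0, null = 430))
  v <- prepare_views(study$exp1)
  cat_g <- characterize(v$within, "group")
  truth <- study$panel$true_class[match(cat_g$categories$feature_id,
                                        study$panel$feature_id)]
  lin_flag <- cat_g$categories$increasing | cat_g$categories$decreasing
  expect_gte(sum(lin_flag[truth == "linear"]), 18)
  # q-values never fall below raw p (BH property) and are monotone in p
  e <- cat_g$entries
  expect_true(all(e$q_lin >= e$p_lin - 1e-12))
  ord <- order(e$p_lin)
  expect_true(all(diff(e$q_lin[ord]) >= -1e-12))
})

test_that("null features are flagged at no more than the FDR level", {
  panel <- make_feature_panel(c(null = 500), seed = 9)
  e <- generate_sleep_dep_experiment(
    panel, protocol_spec("sleep_deprivation", 12, seed = 10), "null_exp")
  v <- prepare_views(e)
  cat_g <- characterize(v$within, "group")
  # BH at 5% across 500 independent null features: expect ~0 flags, allow a few
  expect_lte(sum(cat_g$categories$increasing | cat_g$categories$decreasing), 10)
  expect_lte(sum(cat_g$categories$cycling), 10)
  # raw rejection near the nominal rate
  expect_lt(abs(mean(cat_g$entries$p_lin < 0.05) - 0.05), 0.03)
})

test_that("single-participant group characterization equals the individual one", {
  set.seed(2)
  tab <- tiny_table(matrix(rnorm(19 * 4, 100, 5), 19, 4), tsw = tt)
  g <- characterize(tab, "group")
  i <- characterize(tab, "individual")
  expect_equal(g$entries$slope, i$entries$slope)
  expect_equal(g$entries$p_cos, i$entries$p_cos)
})

fake_group_catalog <- function(counts) {
  # counts: named c(increasing, cycling_only, neither ...) feature tallies
  n <- sum(counts)
  cats <- data.frame(
    feature_id = paste0("F", seq_len(n)),
    cycling = rep(names(counts) == "cycling", counts),
    increasing = rep(names(counts) == "increasing", counts),
    decreasing = rep(names(counts) == "decreasing", counts)
  )
  structure(list(level = "group", entries = NULL, categories = cats,
                 alpha = 0.05), class = "trend_catalog")
}

test_that("experiment comparison chi-square matches the hand-computed oracle", {
  a <- fake_group_catalog(c(increasing = 10, cycling = 20))
  b <- fake_group_catalog(c(increasing = 20, cycling = 10))
  got <- compare_experiments(a, b)
  # 2x2 table [[10,20],[20,10]]: all expected cells 15, chi = 4*25/15
  expect_equal(got$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(got$df, 1)
  expect_equal(got$p_value, pchisq(20 / 3, 1, lower.tail = FALSE))
  ident <- compare_experiments(a, a)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
})
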