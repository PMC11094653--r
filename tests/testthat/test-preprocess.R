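test_that("zero-fraction filter applies a strict boundary and is idempotent", {
  m <- cbind(F1 = c(rep(0, 5), 6:20),  # 25% zeros -> dropped
             F2 = c(rep(0, 4), 5:20),  # exactly 20% -> retained
             F3 = 1:20)
  tab <- tiny_table(m)
  got <- filter_zero_features(tab, 0.20)
  expect_equal(got$dropped, "F1")
  expect_equal(got$table$feature_meta$feature_id, c("F2", "F3"))
  again <- filter_zero_features(got$table, 0.20)
  expect_equal(length(again$dropped), 0)
  expect_identical(again$table$intensities, got$table$intensities)
})

test_that("a 1035-feature cleanup retains exactly the sub-threshold features", {
  # 106 features with 9/40 zeros (22.5%), 929 with 8/40 (20%) or fewer
  set.seed(30)
  n <- 40
  zeros_per_feature <- c(rep(9, 106), sample(0:8, 929, replace = TRUE))
  m <- sapply(zeros_per_feature, function(z) {
    v <- runif(n, 5, 50)
    v[sample(n, z)] <- 0
    v
  })
  colnames(m) <- sprintf("M%04d", seq_len(ncol(m)))
  got <- filter_zero_features(tiny_table(m), 0.20)
  expect_equal(ncol(got$table$intensities), 929)
  expect_equal(length(got$dropped), 106)
})

test_that("left-censored imputation fills below the observed minimum, deterministically", {
  tab <- tiny_table(cbind(F1 = c(0, 8, 10, 12)))
  got <- impute_left_censored(tab, seed = 42)
  v <- got$intensities[1, "F1"]
  expect_gt(v, 0)
  expect_lt(v, 8)
  expect_equal(got$intensities[2:4, "F1"], tab$intensities[2:4, "F1"],
               ignore_attr = TRUE)
  expect_identical(impute_left_censored(tab, seed = 42)$intensities,
                   got$intensities)
  # no zeros -> untouched
  clean <- tiny_table(cbind(F1 = c(4, 8, 10, 12)))
  expect_identical(impute_left_censored(clean), clean)
  # all-censored feature falls back with a warning
  allz <- tiny_table(cbind(F1 = rep(0, 4), F2 = c(2, 3, 4, 5)))
  expect_warning(impute_left_censored(allz), "entirely censored")
})

test_that("imputed values match the censored-tail mean of the generating normal", {
  # latent N(10, 2) censored at its 15% quantile; tail mean is the oracle
  set.seed(77)
  n <- 200
  x <- rnorm(n, 10, 2)
  lod <- qnorm(0.15, 10, 2)
  xc <- ifelse(x < lod, 0, x)
  tab <- tiny_table(cbind(F1 = xc))
  got <- impute_left_censored(tab, seed = 5)
  imputed <- got$intensities[xc == 0, "F1"]
  tail_mean <- 10 - 2 * dnorm(qnorm(0.15)) / 0.15
  expect_lt(abs(mean(imputed) - tail_mean), 0.5)
  expect_true(all(imputed > 0 & imputed < min(xc[xc > 0])))
})

test_that("median normalization equalizes per-sample medians multiplicatively", {
  m <- rbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6), s3 = c(4, 8, 12))
  tab <- tiny_table(m) # medians 2, 4, 8 -> reference 4 -> factors 2, 1, 0.5
  got <- median_normalize(tab)
  expect_equal(unname(got$intensities / m), matrix(rep(c(2, 1, 0.5), 3), 3, 3),
               tolerance = 1e-12)
  expect_equal(unname(apply(got$intensities, 1, median)), rep(4, 3))
  # idempotence and the single-sample identity
  twice <- median_normalize(got)
  expect_equal(twice$intensities, got$intensities, tolerance = 1e-9)
  one <- tiny_table(rbind(c(3, 5, 7)))
  expect_equal(median_normalize(one)$intensities, one$intensities)
  # random table: all medians equal afterwards
  set.seed(14)
  r <- tiny_table(matrix(runif(200, 1, 100), 20, 10))
  expect_equal(diff(range(apply(median_normalize(r)$intensities, 1, median))),
               0, tolerance = 1e-9)
  expect_error(median_normalize(tiny_table(rbind(c(0, 0, 1)))), "median")
})

test_that("within-participant z-scores standardize each series", {
  tab <- tiny_table(cbind(F1 = c(1, 2, 3)))
  expect_equal(unname(zscore_within_participant(tab)$intensities[, 1]),
               c(-1, 0, 1))
  expect_warning(
    z <- zscore_within_participant(tiny_table(cbind(F1 = c(5, 5, 5)))),
    "constant")
  expect_equal(unname(z$intensities[, 1]), c(0, 0, 0))
  expect_error(zscore_within_participant(
    tiny_table(cbind(F1 = 1:3), participants = c("A", "A", "B"))),
    "single sample")
  # two participants with the same shape at different baselines coincide
  shape <- c(1, 4, 2, 6, 3)
  tab2 <- tiny_table(cbind(F1 = c(shape, 100 + 7 * shape)),
                     participants = rep(c("A", "B"), each = 5),
                     tsw = rep(seq(2, 10, 2), 2))
  z2 <- zscore_within_participant(tab2)$intensities[, 1]
  expect_equal(unname(z2[1:5]), unname(z2[6:10]), tolerance = 1e-9)
})

test_that("prepared views satisfy their invariants and report provenance", {
  study <- synth_study(c(linear = 5, circadian = 10, null = 85))
  vs <- prepare_views(study$exp1)
  Z <- vs$within$table$intensities
  pid <- vs$within$table$sample_meta$participant_id
  for (p in unique(pid)) {
    sub <- Z[pid == p, , drop = FALSE]
    expect_lt(max(abs(colMeans(sub))), 1e-9)
    expect_lt(max(abs(apply(sub, 2, sd) - 1)), 1e-9)
  }
  expect_true(all(vs$between$table$intensities > 0))
  expect_length(prepare_views(study$exp1, views = "between"), 1)
  # within view is invariant to per-participant affine rescaling of the input
  between <- vs$between$table
  scaled <- between
  mult <- ifelse(between$sample_meta$participant_id %in% c("P01", "P03"), 3, 1)
  offs <- ifelse(between$sample_meta$participant_id %in% c("P01", "P03"), 50, 0)
  scaled$intensities <- between$intensities * mult + offs
  expect_equal(zscore_within_participant(scaled)$intensities,
               zscore_within_participant(between)$intensities,
               tolerance = 1e-9)
  # everything censored away -> explicit error
  allzero <- tiny_table(cbind(F1 = c(0, 0, 0, 1)))
  expect_error(prepare_views(allzero), "no features survive")
})
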