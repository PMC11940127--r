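test_that("baseline back-computation preserves subsets and is permutation-invariant", {
  cfg <- reduced_config(21, n_channels = 6L)
  coh <- generate_cohort(cfg)
  beta <- reduced_bands()$beta
  bt_f <- band_trials_noref(coh, beta, "follow_up")
  bt_b <- band_trials_noref(coh, beta, "baseline")
  grp <- cohort_groups(coh)
  tr <- run_gsa(bt_f, grp, "TC", "maximize", max_order = 4, band = "beta")

  # identical data: back-computed values equal the trace values
  same <- baseline_backcompute(tr, bt_f)
  for (k in names(tr$steps))
    expect_equal(same[[k]], tr$steps[[k]]$values)

  bv <- baseline_backcompute(tr, bt_b)
  expect_named(bv, names(tr$steps))
  # reordering the subset channels leaves the measure unchanged
  s3 <- tr$steps[["3"]]$subset
  R <- copula_correlation(bt_b[["T03"]])
  expect_equal(hoinet:::measure_from_correlation(R, s3, "TC"),
               hoinet:::measure_from_correlation(R, rev(s3), "TC"))

  expect_error(baseline_backcompute(tr, bt_b[-1]), "missing baseline.*T01")
})

test_that("ANCOVA recovers hand-worked fits and flags degenerate ones", {
  g <- c("treatment", "treatment", "treatment", "control", "control", "control")

  # identical (baseline, follow-up) pairs in both groups: no adjusted effect
  r0 <- ancova_group_effect(c(1, 2, 3, 1, 2, 3), c(5, 6, 7, 5, 6, 7), g)
  expect_equal(r0$group_coef, 0)
  expect_equal(r0$F, 0)

  # unit offset with zero residuals: degenerate perfect fit
  r1 <- ancova_group_effect(c(2, 3, 4, 1, 2, 3), c(1, 2, 3, 1, 2, 3), g)
  expect_true(r1$degenerate)
  expect_identical(r1$F, Inf)
  expect_equal(r1$group_coef, 1)
  expect_identical(r1$df2, 3L)           # m - 3

  expect_error(ancova_group_effect(1:6, rep(1, 6), g), "constant")
  expect_error(ancova_group_effect(1:4, c(1, 2, 1, 2),
                                   c("treatment", "treatment",
                                     "control", "control")),
               "at least 3")
})

test_that("ANCOVA type-I error is nominal and F is scale-invariant", {
  set.seed(11)
  g <- rep(c("treatment", "control"), c(17, 15))
  rej <- mean(replicate(2000, {
    b <- rnorm(32); y <- 0.5 * b + rnorm(32)
    ancova_group_effect(y, b, g)$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)

  set.seed(12)
  b <- rnorm(32); y <- 0.5 * b + rnorm(32)
  f1 <- ancova_group_effect(y, b, g)
  f2 <- ancova_group_effect(y, 100 * b - 7, g)
  expect_equal(f1$F, f2$F)
  expect_equal(f1$p, f2$p)
})

test_that("White's test calibrates under homoskedasticity and detects power", {
  r_flat <- rep(0.3, 20)
  X <- cbind(1, rnorm(20), rbinom(20, 1, 0.5))
  w0 <- white_test(r_flat, X)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p, 1)

  set.seed(13)
  null_rate <- mean(replicate(500, {
    x <- rnorm(200); g <- rbinom(200, 1, 0.5)
    white_test(lm(1 + x + g + rnorm(200) ~ g + x))$p < 0.05
  }))
  expect_gte(null_rate, 0.03)
  expect_lte(null_rate, 0.07)

  set.seed(14)
  power <- mean(replicate(200, {
    x <- rnorm(200); g <- rbinom(200, 1, 0.5)
    y <- 1 + x + g + rnorm(200, sd = sqrt(0.2 + x^2))
    white_test(lm(y ~ g + x))$p < 0.05
  }))
  expect_gt(power, 0.8)
})

test_that("Benjamini-Hochberg step-up matches hand-worked families", {
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(bh$significant))
  expect_equal(bh$critical_p, 0.04)

  none <- benjamini_hochberg(rep(1, 6), q = 0.05)
  expect_false(any(none$significant))
  expect_true(is.na(none$critical_p))

  all_small <- benjamini_hochberg(rep(0.001, 37), q = 0.05)
  expect_true(all(all_small$significant))

  # significant set is a prefix of the sorted p values; agrees with p.adjust
  set.seed(15)
  p <- runif(40)^2
  bh2 <- benjamini_hochberg(p, 0.05)
  expect_identical(bh2$significant, stats::p.adjust(p, "BH") <= 0.05)
  sig_sorted <- bh2$significant[order(p)]
  expect_true(all(diff(sig_sorted) <= 0))

  expect_error(benjamini_hochberg(numeric(0)), "empty")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the ANCOVA grid spans traces and controls FDR per family", {
  plant <- plant_spec(c(2, 5, 7), reduced_bands()$delta, "collider",
                      amplitude = collider_amplitude(0.65, 2))
  cfg <- reduced_config(22, plants = list(plant))
  rc <- run_config(cohort = cfg, measures = c("TC", "negO"), max_order = 4,
                   seed = 22)
  res <- run_pipeline(rc)
  grid <- res$ancova
  # TC: 2 bands x 2 directions x orders 2:4; negO: 2 x 2 x orders 3:4
  expect_identical(nrow(grid), 12L + 8L)
  expect_true(all(grid$df2 == 32L - 3L))
  expect_true(all(grid$F >= 0))
  expect_true(all(grid$p >= 0 & grid$p <= 1))
  # FDR families are (measure, direction); critical value constant per family
  fam <- split(grid$fdr_critical_p, paste(grid$measure, grid$direction))
  for (f in fam) expect_length(unique(f), 1L)
})
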