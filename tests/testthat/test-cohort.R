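test_that("cohort configuration enforces its invariants", {
  cfg <- cohort_config()
  expect_identical(cfg$n_treatment, 17L)
  expect_identical(cfg$n_control, 15L)
  expect_identical(cfg$n_time, 800L)      # 800 ms at 1000 Hz
  expect_identical(cfg$n_trials, 576L)

  expect_error(cohort_config(n_treatment = 1), ">= 2")
  expect_error(cohort_config(fs = 1000, epoch_ms = 800.3), "integer sample count")
  expect_error(cohort_config(n_trials = 104), "divisible by 16")
  expect_error(reduced_config(1, plants = list(
    plant_spec(c(1, 2, 99), band_spec("delta", 0.5, 4), "collider"))),
    "out of range")
})

test_that("cohort generation is seed-deterministic with paper-sized groups", {
  cfg <- reduced_config(3, n_channels = 4L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$epochs, b$epochs)

  expect_identical(nrow(a$participants), 32L)
  expect_identical(sum(a$participants$group == "treatment"), 17L)
  expect_identical(sum(a$participants$group == "control"), 15L)
  expect_identical(dim(a$epochs[["T01_baseline"]]),
                   c(4L, 200L, 16L))
  expect_setequal(names(a$epochs),
                  paste0(rep(a$participants$id, each = 2),
                         "_", c("baseline", "follow_up")))

  # the paper-scale epoch grid: 800 samples per trial at 1000 Hz
  tiny <- cohort_config(n_channels = 3L, fs = 1000, epoch_ms = 800,
                        n_trials = 16L, bands = list(band_spec("theta", 4, 8)),
                        seed = 3)
  coh <- generate_cohort(tiny)
  expect_identical(dim(coh$epochs[["C01_follow_up"]])[2], 800L)
})

test_that("zero-amplitude plants reproduce the null cohort exactly", {
  band <- band_spec("beta", 12, 30)
  null_cfg <- reduced_config(4, n_channels = 6L)
  zero_cfg <- reduced_config(4, n_channels = 6L, plants = list(
    plant_spec(c(1, 2, 3), band, "collider", amplitude = 0)))
  expect_identical(generate_cohort(null_cfg)$epochs,
                   generate_cohort(zero_cfg)$epochs)

  set.seed(1)
  e <- array(rnorm(3 * 200 * 4), dim = c(3, 200, 4))
  spec0 <- plant_spec(1:3, band, "common_driver", amplitude = 0)
  expect_identical(plant_structure(e, spec0, 250), e)
})

test_that("plant_structure modifies only target channels", {
  band <- band_spec("beta", 12, 30)
  set.seed(2)
  e <- array(rnorm(6 * 200 * 4), dim = c(6, 200, 4))
  spec <- plant_spec(c(2, 4, 5), band, "common_driver", amplitude = 1)
  out <- plant_structure(e, spec, 250)
  expect_identical(out[c(1, 3, 6), , ], e[c(1, 3, 6), , ])
  expect_false(identical(out[c(2, 4, 5), , ], e[c(2, 4, 5), , ]))
  # identical trial-invariant addition on every trial
  expect_equal(out[2, , 1] - e[2, , 1], out[2, , 4] - e[2, , 4])

  expect_error(plant_structure(e, plant_spec(c(5, 7, 8), band, "collider"), 250),
               "out of range")
})

test_that("planted correlations match the implied correlation matrix", {
  band <- band_spec("beta", 12, 30)
  fs <- 250; nt <- 200L
  drv <- plant_spec(1:3, band, "common_driver",
                    amplitude = driver_amplitude(0.5))
  col <- plant_spec(1:3, band, "collider",
                    amplitude = collider_amplitude(1 / sqrt(3), 2))
  set.seed(20)
  measure_R <- function(spec) {
    reps <- replicate(40, {
      bg <- t(vapply(1:3, function(i) hoinet:::band_noise(nt, band, fs),
                     numeric(nt)))
      planted <- plant_structure(array(bg, dim = c(3, nt, 1)), spec, fs)
      stats::cor(t(bandpass_trial(planted[, , 1], band, fs)))
    })
    apply(reps, c(1, 2), mean)
  }
  expect_lt(max(abs(measure_R(drv) - plant_correlation(drv))), 0.05)
  expect_lt(max(abs(measure_R(col) - plant_correlation(col))), 0.05)
})

test_that("amplitude helpers invert the correlation models", {
  expect_equal(driver_amplitude(0.5), 1)
  a <- collider_amplitude(1 / sqrt(3), 2)
  t_ <- a^2
  expect_equal(t_ / sqrt((1 + t_) * (1 + 2 * t_)), 1 / sqrt(3))
  expect_error(collider_amplitude(0.8, 2), "below 1/sqrt")

  R <- plant_correlation(plant_spec(1:3, band_spec("delta", 0.5, 4),
                                    "collider",
                                    amplitude = collider_amplitude(1 / sqrt(3), 2)))
  expect_equal(R, collider_R(), tolerance = 1e-10)
})

test_that("without plants, group TC distributions are indistinguishable", {
  band <- band_spec("beta", 12, 30)
  tvals <- c(); cvals <- c()
  for (sd_ in 1:20) {
    cfg <- cohort_config(n_treatment = 3L, n_control = 3L, n_channels = 4L,
                         fs = 250, epoch_ms = 800, n_trials = 16L,
                         bands = list(band), seed = sd_)
    coh <- generate_cohort(cfg)
    bt <- band_trials_noref(coh, band)
    grp <- cohort_groups(coh)
    v <- vapply(names(bt), function(id)
      total_correlation(bt[[id]][1:3, ]), numeric(1))
    tvals <- c(tvals, v[grp[names(v)] == "treatment"])
    cvals <- c(cvals, v[grp[names(v)] == "control"])
  }
  expect_gt(stats::wilcox.test(tvals, cvals)$p.value, 0.01)
})

test_that("behavior tables honor the task design", {
  cfg <- cohort_config(n_channels = 2L, n_trials = 576L,
                       bands = list(band_spec("theta", 4, 8)))
  set.seed(6)
  tt <- generate_behavior(cfg, "treatment", "baseline")
  expect_identical(nrow(tt), 576L)
  expect_true(all(table(tt$block) == 144L))
  for (b in 1:4) {
    blk <- tt[tt$block == b, ]
    expect_identical(sum(blk$imType == "face"), 72L)
    expect_identical(sum(blk$imType == "car"), 72L)
    expect_identical(sum(blk$imCoh == 37.5), 72L)
  }
  expect_true(all(is.na(tt$rt_ms) == (tt$outcome == "timeout")))
  expect_true(all(tt$rt_ms <= 1250, na.rm = TRUE))

  # location far below the 300 ms validity floor: most trials filtered out
  fast_cfg <- cohort_config(n_channels = 2L, n_trials = 576L,
                            bands = list(band_spec("theta", 4, 8)),
                            rt_median_ms = 150)
  set.seed(7)
  fast <- generate_behavior(fast_cfg, "control", "baseline")
  expect_lt(mean(filter_trials(fast)), 0.2)
})
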