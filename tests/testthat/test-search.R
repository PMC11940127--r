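test_that("Cohen's d uses the pooled-SD convention", {
  e <- cohens_d(c(2, 4), c(1, 3))
  expect_equal(e$d, 1 / sqrt(2))
  expect_equal(e$s, sqrt(2))
  expect_identical(e$m_treatment, 2L)

  same <- cohens_d(c(1, 2, 3), c(2, 1, 3))
  expect_equal(same$d, 0)

  a <- rnorm(5); b <- rnorm(7)
  expect_equal(cohens_d(a, b)$d, -cohens_d(b, a)$d)

  expect_warning(flat <- cohens_d(c(1, 1), c(2, 2)), "signed infinity")
  expect_identical(flat$d, -Inf)
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("score_all_subsets enumerates and contrasts subsets", {
  cfg <- reduced_config(11, n_channels = 4L)
  coh <- generate_cohort(cfg)
  bt <- band_trials_noref(coh, reduced_bands()$beta)
  grp <- cohort_groups(coh)

  tab <- score_all_subsets(bt, grp, 2, "TC")
  expect_equal(nrow(tab), choose(4, 2))
  expect_identical(tab$subset[1], "1+2")

  expect_error(score_all_subsets(bt, grp, 2, "O"), "identically zero")

  # identical values across participants give d = 0 everywhere
  flat <- lapply(bt, function(m) bt[[1]])
  names(flat) <- names(bt)
  tab0 <- score_all_subsets(flat, grp, 2, "TC")
  expect_true(all(tab0$d == 0))
})

test_that("candidate expansion adds exactly one channel each way", {
  cands <- expand_candidates(c(3, 7), 64)
  expect_length(cands, 62L)
  expect_true(all(vapply(cands, function(s) all(c(3, 7) %in% s), logical(1))))
  expect_true(all(lengths(cands) == 3L))
  expect_identical(cands[[1]], c(1L, 3L, 7L))

  expect_length(expand_candidates(1:63, 64), 1L)
  expect_error(expand_candidates(1:64, 64), "spans the montage")
})

test_that("greedy traces are nested, ordered, and count their evaluations", {
  cfg <- reduced_config(12, n_channels = 8L)
  coh <- generate_cohort(cfg)
  bt <- band_trials_noref(coh, reduced_bands()$beta)
  grp <- cohort_groups(coh)

  tr <- run_gsa(bt, grp, "DTC", "maximize", max_order = 6, band = "beta")
  orders <- vapply(tr$steps, `[[`, numeric(1), "order")
  expect_identical(orders, setNames(2:6 * 1.0, as.character(2:6)))
  for (i in 2:length(tr$steps))
    expect_true(all(tr$steps[[i - 1]]$subset %in% tr$steps[[i]]$subset))

  # greedy cost contract: C(n, k0) + sum_{k=k0}^{max-1} (n - k)
  expect_equal(tr$eval_count, choose(8, 2) + sum(8 - 2:5))

  # O search seeds at triplets by default
  tro <- run_gsa(bt, grp, "O", "maximize", max_order = 4, band = "beta")
  expect_identical(tro$start_order, 3L)
  expect_equal(tro$eval_count, choose(8, 3) + (8 - 3))
})

test_that("greedy order-3 selection matches exhaustive search under a planted driver", {
  hits <- 0L
  for (sd_ in 1:5) {
    plant <- plant_spec(c(2, 5, 7), reduced_bands()$beta, "common_driver",
                        amplitude = driver_amplitude(0.5))
    cfg <- reduced_config(sd_, n_channels = 8L, plants = list(plant))
    coh <- generate_cohort(cfg)
    bt <- band_trials_noref(coh, reduced_bands()$beta)
    grp <- cohort_groups(coh)
    tr <- run_gsa(bt, grp, "TC", "maximize", max_order = 3, band = "beta")
    ex <- score_all_subsets(bt, grp, 3, "TC")
    hits <- hits +
      (ex$subset[which.max(ex$d)] == paste(tr$steps[["3"]]$subset, collapse = "+"))
  }
  expect_gte(hits, 4L)
})

test_that("maximizing negO equals minimizing O", {
  cfg <- reduced_config(13, n_channels = 8L, plants = list(
    plant_spec(c(1, 4, 6), reduced_bands()$beta, "collider",
               amplitude = collider_amplitude(0.65, 2))))
  coh <- generate_cohort(cfg)
  bt <- band_trials_noref(coh, reduced_bands()$beta)
  grp <- cohort_groups(coh)
  tr_neg <- run_gsa(bt, grp, "negO", "maximize", max_order = 5, band = "beta")
  tr_min <- run_gsa(bt, grp, "O", "minimize", max_order = 5, band = "beta")
  expect_identical(lapply(tr_neg$steps, `[[`, "subset"),
                   lapply(tr_min$steps, `[[`, "subset"))
  expect_equal(tr_neg$steps[["4"]]$effect$d, -tr_min$steps[["4"]]$effect$d)
})

test_that("negO search recovers a planted collider at its first containable order", {
  hits <- 0L
  for (sd_ in 1:5) {
    plant <- plant_spec(c(2, 5, 7), reduced_bands()$beta, "collider",
                        amplitude = collider_amplitude(0.65, 2))
    cfg <- reduced_config(sd_ + 100, n_channels = 8L, plants = list(plant))
    coh <- generate_cohort(cfg)
    bt <- band_trials_noref(coh, reduced_bands()$beta)
    grp <- cohort_groups(coh)
    tr <- run_gsa(bt, grp, "negO", "maximize", max_order = 3, band = "beta")
    hits <- hits + setequal(tr$steps[["3"]]$subset, c(2, 5, 7))
  }
  expect_gte(hits, 4L)
})

test_that("sign reversal of O tables is an involution", {
  tbl <- data.frame(measure = "O", value = c(0.12, -0.3),
                    value_normalized = c(0.04, -0.1))
  neg <- negate_o_information(tbl)
  expect_identical(neg$measure, c("negO", "negO"))
  expect_equal(neg$value, c(-0.12, 0.3))
  neg$measure <- "O"
  expect_equal(negate_o_information(neg)$value, tbl$value)
  expect_error(negate_o_information(data.frame(measure = "TC", value = 1)),
               "must be 'O'")
})
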