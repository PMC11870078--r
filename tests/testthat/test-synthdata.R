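test_that("flat series hit the requested mean and SD exactly and reproduce under a seed", {
  for (case in list(c(300, 790, 270), c(300, 18, 2), c(50, 18, 6))) {
    s <- withr::with_seed(11, simulate_flat_series(case[1], case[2], case[3]))
    expect_equal(length(s$values), case[1])
    expect_equal(mean(s$values), case[2], tolerance = 1e-12)
    expect_equal(sd(s$values), case[3], tolerance = 1e-12)
  }
  # zero-dispersion case is constant
  s0 <- simulate_flat_series(300, 790, 0)
  expect_true(all(s0$values == 790))
  # determinism under a fixed seed
  a <- withr::with_seed(42, simulate_flat_series(300, 18, 2, "bf"))
  b <- withr::with_seed(42, simulate_flat_series(300, 18, 2, "bf"))
  expect_identical(a$values, b$values)
  expect_error(simulate_flat_series(1, 790, 270), "n_cycles")
  expect_error(simulate_flat_series(300, 790, -1), "non-negative")
})

test_that("trend curves anchor at rest/end means and rise monotonically", {
  n <- 300
  for (shape in c("linear", "logarithmic", "exponential")) {
    tc <- trend_curve(shape, n, 790, 2130)
    expect_equal(tc[1], 790)
    expect_equal(tc[n], 2130)
    expect_true(all(diff(tc) >= 0))
  }
  expect_equal(trend_curve("flat", 10, 790, 2130), rep(790, 10))
})

test_that("apply_trend adds the anchored offset; noiseless linear matches closed forms", {
  s0 <- simulate_flat_series(300, 790, 0)
  expect_identical(apply_trend(s0, "flat", 790, 2130)$values, s0$values)
  lin <- apply_trend(s0, "linear", 790, 2130)
  expect_equal(lin$values[300] - lin$values[1], 1340)
  # population SD of a noiseless linear BF ramp: arithmetic progression
  b0 <- simulate_flat_series(300, 18, 0, "bf")
  bl <- apply_trend(b0, "linear", 18, 39)
  n <- 300; d <- 21 / 299
  pop_sd <- sqrt(d^2 * (n^2 - 1) / 12)
  expect_equal(sqrt(mean((bl$values - mean(bl$values))^2)), pop_sd,
               tolerance = 1e-10)
  # noisy series: trend is a pure additive offset, sighs ride it too
  s <- make_flat(seed = 3)
  tr <- apply_trend(s, "logarithmic", 790, 2130)
  tc <- trend_curve("logarithmic", 300, 790, 2130)
  expect_equal(tr$values - s$values, tc - tc[1], tolerance = 1e-12)
  expect_error(apply_trend(s, "cubic", 790, 2130))
})

test_that("sigh insertion respects the minimum gap over many draws", {
  withr::with_seed(99, {
    for (i in 1:10000) {
      pos <- breathvar:::draw_sigh_positions(300, sigh_spec())
      if (length(pos) > 1) expect_true(min(diff(pos)) >= 4)
    }
  })
})

test_that("sigh insertion replaces values, records positions and hits the target SD exactly", {
  s <- make_flat(seed = 5)
  out <- withr::with_seed(6, insert_sighs(s, sigh_spec(), target_sd = 270))
  expect_equal(sd(out$values), 270, tolerance = 1e-12)
  expect_gt(length(out$sigh_positions), 0)
  # mean preserved by the rescaling (about the post-insertion mean)
  expect_false(isTRUE(all.equal(mean(out$values), mean(s$values))))
  # sighs are large relative to the rescaled bulk
  expect_true(all(out$values[out$sigh_positions] >
                  mean(out$values) + 2 * 270))
  # expected count from the gap distribution: one draw within +-5 of 20,
  # mean over 1000 draws within 19..21
  counts <- withr::with_seed(7, replicate(1000, {
    length(breathvar:::draw_sigh_positions(300, sigh_spec()))
  }))
  expect_lte(abs(counts[1] - 20), 5)
  expect_gte(mean(counts), 19)
  expect_lte(mean(counts), 21)
})

test_that("a series too short for a sigh is returned unmodified with a warning", {
  s <- withr::with_seed(1, simulate_flat_series(3, 790, 270))
  expect_warning(out <- withr::with_seed(1, insert_sighs(s, sigh_spec(), 270)),
                 "too short")
  expect_identical(out$values, s$values)
})

test_that("pooled standardized flat values pass a normality sanity check", {
  z <- withr::with_seed(8, {
    unlist(lapply(1:100, function(i) {
      s <- simulate_flat_series(300, 790, 270)
      (s$values - mean(s$values)) / sd(s$values)
    }))
  })
  expect_lt(abs(e1071::skewness(z)), 0.1)
  expect_lt(abs(e1071::kurtosis(z)), 0.1)
})

test_that("replicates are independent, individually regenerable, and sigh/trend scenarios compose", {
  sc <- breath_scenario("vt", true_sd = 270, trend = "logarithmic",
                        sighs = TRUE, n_reps = 3, seed = 21)
  reps <- generate_replicates(sc)
  expect_length(reps, 3)
  expect_false(identical(reps[[1]]$values, reps[[2]]$values))
  expect_false(identical(reps[[2]]$values, reps[[3]]$values))
  # regenerate replicate 2 alone
  r2 <- generate_replicates(sc, rep_index = 2)[[1]]
  expect_identical(r2$values, reps[[2]]$values)
  for (r in reps) {
    expect_gt(length(r$sigh_positions), 0)
    if (length(r$sigh_positions) > 1)
      expect_gte(min(diff(r$sigh_positions)), 4)
  }
  # flat scenario: every replicate's sample SD is exact
  scf <- breath_scenario("vt", true_sd = 270, trend = "flat", n_reps = 5,
                         seed = 2)
  for (r in generate_replicates(scf))
    expect_equal(sd(r$values), 270, tolerance = 1e-12)
})

test_that("scenario validation rejects inconsistent specifications", {
  expect_error(breath_scenario("bf", true_sd = 4, sighs = TRUE),
               "tidal volume")
  expect_error(breath_scenario("vt", true_sd = -1), "positive")
  expect_error(breath_scenario("vt", true_sd = 60, trend = "linear",
                               rest_mean = 2000, end_mean = 790),
               "rest_mean")
  expect_error(sigh_spec(min_gap = 0), "min_gap")
  expect_error(sigh_spec(interval_mean = 3, min_gap = 4), "exceed")
})

test_that("scenario presets mirror the study grid", {
  p <- scenario_presets()
  expect_setequal(names(p), c("bf", "vt", "vt_sighs"))
  expect_equal(p$bf$sd_levels, c(2, 4, 6))
  expect_equal(p$vt$sd_levels, c(60, 270, 500))
  expect_true(p$vt_sighs$sighs)
  expect_equal(p$vt$n_reps, 10000)
})
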