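test_that("plain_sd matches hand computations and rejects degenerate input", {
  expect_equal(plain_sd(c(5, 5, 5, 5)), 0)
  expect_equal(plain_sd(c(1, 2, 3)), 1)  # variance (1 + 0 + 1)/2
  expect_error(plain_sd(5), "at least 2")
  s <- make_flat(sd = 2, mean = 18, parameter = "bf")
  expect_equal(plain_sd(s), 2, tolerance = 1e-12)
})

test_that("moving_sd averages fully contained window SDs", {
  expect_equal(moving_sd(rep(3.2, 40), 7), 0)
  expect_equal(moving_sd(c(1, 2, 3, 4, 5), 3), 1)
  v <- withr::with_seed(2, rnorm(123, 50, 9))
  for (w in c(2, 7, 19))
    expect_equal(moving_sd(v, w), brute_moving_sd(v, w), tolerance = 1e-10)
  expect_error(moving_sd(1:5, 6), "longer than")
  expect_error(moving_sd(1:5, 1), "window")
})

test_that("sd_bias_factor is the normal-theory c4 ratio", {
  expect_equal(sd_bias_factor(2), sqrt(2 / pi), tolerance = 1e-12)
  under <- 100 * (1 - sd_bias_factor(c(3, 5)))
  expect_equal(round(under), c(11, 6))
  expect_equal(under[1], 11.38, tolerance = 0.001)
  expect_error(sd_bias_factor(1), ">= 2")
  # Monte-Carlo cross-check at n = 5
  m <- withr::with_seed(3, matrix(rnorm(5 * 2e5), nrow = 5))
  sds <- breathvar:::col_sds(m)
  se <- sd(sds) / sqrt(length(sds))
  expect_lt(abs(mean(sds) - sd_bias_factor(5)), 3 * se)
})

test_that("local polynomial fit reproduces polynomials up to its degree", {
  x <- 1:50
  y <- 3 + 0.5 * x - 0.02 * x^2
  for (span in c(0.4, 0.75, 1)) {
    f <- loess_fit(x, y, span = span, degree = 2)
    expect_lt(max(abs(f$residuals)), 1e-8)
  }
  # linear equivariance: adding a + b*x leaves residuals unchanged
  y2 <- withr::with_seed(4, rnorm(50))
  r0 <- loess_fit(x, y2, span = 0.75)$residuals
  r1 <- loess_fit(x, y2 + 7 - 2.5 * x, span = 0.75)$residuals
  expect_equal(r1, r0, tolerance = 1e-8)
})

test_that("loess_fit agrees with an independent per-point normal-equations oracle", {
  withr::with_seed(5, {
    for (n in c(10, 17, 30)) {
      x <- as.numeric(1:n)
      y <- rnorm(n, 100, 10)
      for (span in c(0.5, 0.75, 1)) {
        ours <- loess_fit(x, y, span = span, degree = 2)$fitted
        expect_equal(ours, brute_loess_fitted(x, y, span), tolerance = 1e-8)
      }
    }
    # non-equispaced x takes the per-point path
    x <- sort(runif(25, 0, 10))
    y <- rnorm(25)
    expect_equal(loess_fit(x, y, span = 0.8)$fitted,
                 brute_loess_fitted(x, y, 0.8), tolerance = 1e-8)
  })
})

test_that("loess_fit tracks stats::loess with direct surface evaluation", {
  x <- 1:120
  y <- withr::with_seed(6, 500 + 5 * x + rnorm(120, 0, 40))
  ref <- stats::loess(y ~ x, span = 0.75, degree = 2, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  ours <- loess_fit(x, y, span = 0.75)
  expect_equal(ours$fitted, unname(stats::fitted(ref)), tolerance = 1e-3)
  expect_equal(sd(ours$residuals), sd(stats::residuals(ref)),
               tolerance = 1e-3)
})

test_that("loess_fit rejects degenerate and undersized problems", {
  expect_error(loess_fit(rep(1, 10), rnorm(10)), "degenerate")
  expect_error(loess_fit(1:3, rnorm(3), span = 1, degree = 2), "length")
  expect_error(loess_fit(1:10, rnorm(10), span = 0), "span")
  expect_error(loess_fit(1:10, rnorm(9)), "same length")
})

test_that("loess_residual_sd: constant, linear-trend invariance, short input", {
  expect_equal(loess_residual_sd(rep(4, 30)), 0, tolerance = 1e-10)
  s <- make_flat(sd = 4, mean = 18, parameter = "bf", seed = 9)
  tr <- apply_trend(s, "linear", 18, 39)
  expect_equal(loess_residual_sd(tr, 0.75), loess_residual_sd(s, 0.75),
               tolerance = 1e-8)
  expect_error(loess_residual_sd(rnorm(5)), "at least 8")
})

test_that("every estimator is scale-equivariant and translation-invariant", {
  v <- withr::with_seed(10, rnorm(60, 800, 100))
  specs <- list(method_spec("sd"), method_spec("msd", window = 7),
                method_spec("loess", span = 0.75))
  for (spec in specs) {
    e0 <- unname(estimate_dispersion(v, spec))
    for (k in c(0.5, 3)) {
      expect_equal(unname(estimate_dispersion(k * v, spec)), k * e0,
                   tolerance = 1e-8)
    }
    for (cc in c(-5, 1000)) {
      expect_equal(unname(estimate_dispersion(v + cc, spec)), e0,
                   tolerance = 1e-8)
    }
  }
})

test_that("mean MSD over normal replicates equals sigma * c4(n)", {
  nrep <- 2000
  for (sigma in c(2, 60)) {
    Y <- withr::with_seed(12, matrix(rnorm(300 * nrep, 0, sigma), 300))
    for (n in c(7L, 11L, 19L)) {
      msds <- apply(Y, 2, moving_sd, window = n)
      se <- sd(msds) / sqrt(nrep)
      expect_lt(abs(mean(msds) - sigma * sd_bias_factor(n)), 3 * se)
    }
  }
})

test_that("increasing the MSD window reduces the small-sample bias on flat data", {
  sc <- breath_scenario("bf", true_sd = 4, trend = "flat", n_reps = 500,
                        seed = 13)
  V <- vapply(generate_replicates(sc), `[[`, numeric(300), "values")
  m <- vapply(c(7L, 11L, 19L),
              function(n) mean(apply(V, 2, moving_sd, window = n)),
              numeric(1))
  expect_true(all(diff(m) > 0))
  expect_lt(m[3], 4)
})

test_that("estimate_dispersion dispatches and validates method specs", {
  expect_equal(unname(estimate_dispersion(c(1, 2, 3), method_spec("sd"))), 1)
  expect_equal(names(estimate_dispersion(1:3, method_spec("sd"))), "SD")
  expect_equal(unname(estimate_dispersion(rep(2, 30),
                                          method_spec("msd", window = 7))), 0)
  quadr <- breath_series(5 + (1:40)^2 / 10, "vt")
  expect_equal(unname(estimate_dispersion(quadr, method_spec("loess",
                                                             span = 1))),
               0, tolerance = 1e-8)
  expect_error(method_spec("loess", span = 2), "span")
  expect_error(method_spec("msd", window = 1), "window")
  expect_error(estimate_dispersion(1:10, list(method = "sd")),
               "method_spec")
})
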