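# Independent oracles used across the suite. These deliberately take a
# different computational path from the package internals.

# brute-force local degree-2 fit: one lm() per target point (QR path),
# nearest-neighbour tricube weights as in the package's definition
brute_loess_fitted <- function(x, y, span, degree = 2) {
  n <- length(x)
  q <- max(degree + 2, ceiling(span * n))
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    idx <- order(d, seq_len(n))[seq_len(q)]
    w <- (1 - (d[idx] / max(d[idx]))^3)^3
    df <- data.frame(yy = y[idx], xx = x[idx])
    fit <- stats::lm(yy ~ xx + I(xx^2), data = df, weights = w)
    unname(stats::predict(fit, data.frame(xx = x[i])))
  }, numeric(1))
}

# naive sliding-window sample SDs
brute_moving_sd <- function(v, w) {
  k <- length(v) - w + 1
  mean(vapply(seq_len(k), function(i) stats::sd(v[i:(i + w - 1)]),
              numeric(1)))
}

# expected plain sample SD of an exact-SD flat series plus a linear ramp
# of per-cycle slope d over n cycles: arithmetic-progression variance
# (population d^2 (n^2 - 1) / 12, times n/(n-1) for the sample version;
# the noise-trend cross term has expectation zero)
linear_trend_sd <- function(sigma, rest, end, n) {
  d <- (end - rest) / (n - 1)
  sqrt(sigma^2 + d^2 * (n^2 - 1) / 12 * n / (n - 1))
}

make_flat <- function(n = 300, mean = 790, sd = 270, seed = 1,
                      parameter = "vt") {
  withr::with_seed(seed, simulate_flat_series(n, mean, sd, parameter))
}
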