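#' Plain sample standard deviation
#'
#' Sample SD with the n-1 denominator. At rest (no trend) this is a
#' perfectly acceptable dispersion measure; under an exercise trend it is
#' inflated by the trend itself, which is what the detrending estimators
#' avoid.
#'
#' @param values A [breath_series()] or numeric vector (length at least 2).
#' @return The sample SD, parameter units.
#' @export
plain_sd <- function(values) {
  v <- as_breath_values(values)
  if (length(v) < 2L) stop("need at least 2 values for a sample SD")
  stats::sd(v)
}

#' Moving standard deviation (MSD)
#'
#' The average of the sample SDs of all fully contained sliding windows of
#' `window` consecutive cycles (stride 1, no partial edge windows). Small
#' windows underestimate the true SD (see [sd_bias_factor()]); large
#' windows are inflated by the exercise trend, so `window` trades the two
#' off. Windows of 7, 11, 15 and 19 cycles are the values studied.
#'
#' @param values A [breath_series()] or numeric vector.
#' @param window Window length in cycles (2 to `length(values)`).
#' @return Mean sliding-window sample SD, parameter units.
#' @examples
#' moving_sd(c(1, 2, 3, 4, 5), window = 3)  # each window has SD 1
#' @export
moving_sd <- function(values, window) {
  v <- as_breath_values(values)
  window <- as.integer(window)
  if (is.na(window) || window < 2L) stop("window must be an integer >= 2")
  if (window > length(v))
    stop("window (", window, ") longer than series (", length(v), ")")
  base::mean(rolling_sd(v, window))
}

# vectorised sliding sample SDs via running sums on centred values;
# global centring keeps the squared terms well conditioned
rolling_sd <- function(v, w) {
  v <- v - base::mean(v)
  s1 <- stats::filter(v, rep(1, w), sides = 1)
  s2 <- stats::filter(v * v, rep(1, w), sides = 1)
  keep <- !is.na(s1)
  sqrt(pmax((s2[keep] - s1[keep]^2 / w) / (w - 1), 0))
}

#' Small-sample bias factor of the sample SD
#'
#' For samples of size `n` from a normal distribution the sample SD (n-1
#' denominator) underestimates the true SD on average by the factor
#' `c4(n) = sqrt(2/(n-1)) * Gamma(n/2) / Gamma((n-1)/2)`, i.e. an expected
#' underestimation of `100 * (1 - c4(n))` percent: about 11% at n = 3 and
#' 6% at n = 5. This is the bias that pulls the moving SD below the true
#' dispersion at small windows.
#'
#' @param window_n Sample (window) size, at least 2. Vectorised.
#' @return `c4(window_n)`, the expected ratio E(sample SD) / true SD.
#' @examples
#' 100 * (1 - sd_bias_factor(c(3, 5, 7)))  # percent underestimation
#' @export
sd_bias_factor <- function(window_n) {
  n <- as.numeric(window_n)
  if (any(is.na(n)) || any(n < 2)) stop("window_n must be >= 2")
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

## ---- local polynomial (LOESS) machinery -----------------------------------

# smoother matrices for equispaced cycles are expensive to build and reused
# constantly (every study replicate shares one), so cache by (n, span, degree)
.loess_cache <- new.env(parent = emptyenv())

loess_q <- function(n, span, degree) {
  if (!is.numeric(span) || span <= 0 || span > 1)
    stop("span must be in (0, 1]")
  degree <- as.integer(degree)
  if (degree < 0L) stop("degree must be >= 0")
  q <- max(degree + 2L, as.integer(ceiling(span * n)))
  if (q > n)
    stop("neighbourhood size ", q, " exceeds series length ", n,
         " (series too short for degree ", degree, ")")
  q
}

# fitted value at x0 as a linear functional of y: indices + coefficients of
# the first row of (X'WX)^-1 X'W for the local polynomial basis centred at x0
loess_local_coef <- function(x, x0, q, degree) {
  d <- abs(x - x0)
  ord <- order(d, seq_along(x))           # distance ties -> lower index
  idx <- ord[seq_len(q)]
  dmax <- max(d[idx])
  if (dmax == 0)
    stop("degenerate neighbourhood at x = ", x0,
         ": all selected predictor values identical")
  w <- (1 - (d[idx] / dmax)^3)^3          # tricube
  X <- outer(x[idx] - x0, 0:degree, `^`)
  XtW <- t(X * w)
  a <- tryCatch(solve(XtW %*% X, XtW)[1L, ],
                error = function(e)
                  stop("degenerate weighted design at x = ", x0, ": ",
                       conditionMessage(e)))
  list(idx = idx, coef = a)
}

#' Smoother matrix of the local polynomial fit on equispaced cycles
#'
#' The n-by-n matrix `L` with `fitted = L %*% y` for a local polynomial
#' fit at predictor values `1..n`. Because the fit is linear in `y`, a
#' whole Monte-Carlo study at one series length reuses a single matrix.
#' Matrices are cached per `(n, span, degree)`.
#'
#' @param n Series length.
#' @param span Fraction of points in each local neighbourhood, in (0, 1].
#' @param degree Local polynomial degree (default 2).
#' @return An `n x n` matrix.
#' @keywords internal
#' @export
loess_smoother_matrix <- function(n, span, degree = 2L) {
  key <- paste(n, span, degree, sep = "|")
  L <- .loess_cache[[key]]
  if (!is.null(L)) return(L)
  x <- as.numeric(seq_len(n))
  q <- loess_q(n, span, degree)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lc <- loess_local_coef(x, x[i], q, degree)
    L[i, lc$idx] <- lc$coef
  }
  .loess_cache[[key]] <- L
  L
}

#' Local polynomial (LOESS) trend fit
#'
#' Locally estimated scatterplot smoothing with nearest-neighbour
#' bandwidth and tricube weights: for each target point the
#' `q = max(degree + 2, ceiling(span * n))` nearest predictor values are
#' selected, weighted by `(1 - (d/dmax)^3)^3`, and a weighted
#' least-squares polynomial of the given degree is evaluated at the target.
#' Evaluation is exact at every point (no interpolation grid) and no
#' robustness iterations are performed. The residuals are the vertical
#' differences between each point and the fitted trend curve; their sample
#' SD is the dispersion estimator (see [loess_residual_sd()]).
#'
#' @param x Predictor values (typically cycle indices `1..n`).
#' @param y Response values, same length as `x`.
#' @param span Neighbourhood fraction in (0, 1]. 0.75 is the recommended
#'   default; 0.5 and 1 bracket it in the validation study.
#' @param degree Local polynomial degree (default 2).
#' @return An object of class `"loess_fit"`: list with `x`, `y`, `fitted`,
#'   `residuals`, `span`, `degree` and the neighbourhood size `q`.
#' @examples
#' x <- 1:60
#' y <- 0.01 * (x - 30)^2 + rnorm(60)
#' f <- loess_fit(x, y, span = 0.75)
#' sd(f$residuals)
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 2L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  q <- loess_q(n, span, degree)
  if (identical(x, as.numeric(seq_len(n)))) {
    fitted <- drop(loess_smoother_matrix(n, span, degree) %*% y)
  } else {
    fitted <- vapply(x, function(x0) {
      lc <- loess_local_coef(x, x0, q, degree)
      sum(lc$coef * y[lc$idx])
    }, numeric(1))
  }
  structure(list(x = x, y = y, fitted = fitted, residuals = y - fitted,
                 span = span, degree = as.integer(degree), q = q),
            class = "loess_fit")
}

#' @export
print.loess_fit <- function(x, ...) {
  cat(sprintf(
    "Local polynomial fit: span %g, degree %d, q = %d of %d points\n",
    x$span, x$degree, x$q, length(x$x)))
  cat(sprintf("  residual SD: %.6g\n", stats::sd(x$residuals)))
  invisible(x)
}

# evaluate an existing loess fit at arbitrary new predictor values
loess_eval <- function(fit, newx) {
  vapply(as.numeric(newx), function(x0) {
    lc <- loess_local_coef(fit$x, x0, fit$q, fit$degree)
    sum(lc$coef * fit$y[lc$idx])
  }, numeric(1))
}

#' LOESS residual-SD dispersion estimate
#'
#' Fits a local degree-2 polynomial trend over the cycle indices and
#' returns the sample SD (n-1 denominator) of its residuals — the
#' dispersion of the parameter around its exercise trend. Because the
#' local fit absorbs any affine trend exactly, the estimate is identical
#' with and without a linear exercise trend.
#'
#' @param series A [breath_series()] or numeric vector, length at least 8.
#' @param span Neighbourhood fraction (default 0.75).
#' @param degree Local polynomial degree (default 2).
#' @return The residual sample SD, parameter units.
#' @examples
#' s <- withr::with_seed(1, simulate_flat_series(300, 18, 4, "bf"))
#' loess_residual_sd(s, span = 0.75)
#' @export
loess_residual_sd <- function(series, span = 0.75, degree = 2L) {
  v <- as_breath_values(series)
  if (length(v) < 8L)
    stop("need at least 8 cycles for a LOESS dispersion estimate")
  f <- loess_fit(seq_along(v), v, span = span, degree = degree)
  stats::sd(f$residuals)
}

## ---- method specification and dispatch ------------------------------------

#' Dispersion method specification
#'
#' Identifies one dispersion estimator with its tuning parameters, as
#' compared in the validation study: the plain sample SD, the moving SD
#' with a given window, or the LOESS residual SD with a given span.
#'
#' @param method `"sd"`, `"msd"` or `"loess"`.
#' @param window Window length for `"msd"` (default 7).
#' @param span Span for `"loess"` (default 0.75).
#' @param degree Local polynomial degree for `"loess"` (default 2).
#' @return An object of class `"method_spec"` with a display `label` such
#'   as `"MSD_7"` or `"LOESS_0.75"`.
#' @seealso [estimate_dispersion()], [study_methods()]
#' @export
method_spec <- function(method = c("sd", "msd", "loess"), window = 7L,
                        span = 0.75, degree = 2L) {
  method <- match.arg(method)
  if (method == "msd") {
    window <- as.integer(window)
    if (is.na(window) || window < 2L) stop("msd needs a window >= 2")
  }
  if (method == "loess") {
    if (!is.numeric(span) || span <= 0 || span > 1)
      stop("loess needs a span in (0, 1]")
    if (as.integer(degree) < 0L) stop("loess degree must be >= 0")
  }
  label <- switch(method,
    sd = "SD",
    msd = paste0("MSD_", window),
    loess = paste0("LOESS_", format(span, trim = TRUE)))
  structure(list(method = method, window = window, span = span,
                 degree = as.integer(degree), label = label),
            class = "method_spec")
}

#' @export
print.method_spec <- function(x, ...) {
  cat("Dispersion method:", x$label, "\n")
  invisible(x)
}

#' The method grid of the validation study
#'
#' Plain SD, LOESS at spans 1, 0.75 and 0.5, and moving SD at windows 7,
#' 11, 15 and 19 — the eight rows of the study's result tables.
#'
#' @return A named list of [method_spec()] objects.
#' @export
study_methods <- function() {
  m <- c(list(method_spec("sd")),
         lapply(c(1, 0.75, 0.5), function(s) method_spec("loess", span = s)),
         lapply(c(7L, 11L, 15L, 19L), function(w) method_spec("msd",
                                                              window = w)))
  stats::setNames(m, vapply(m, `[[`, "", "label"))
}

#' Compute one dispersion estimate
#'
#' Routes a series to [plain_sd()], [moving_sd()] or [loess_residual_sd()]
#' according to a [method_spec()].
#'
#' @param series A [breath_series()] or numeric vector.
#' @param spec A [method_spec()].
#' @return A length-1 named numeric (name = method label), parameter units.
#' @examples
#' estimate_dispersion(c(1, 2, 3), method_spec("sd"))
#' @export
estimate_dispersion <- function(series, spec) {
  if (!inherits(spec, "method_spec"))
    stop("'spec' must be a method_spec object")
  v <- as_breath_values(series)
  val <- switch(spec$method,
    sd = plain_sd(v),
    msd = moving_sd(v, spec$window),
    loess = loess_residual_sd(v, span = spec$span, degree = spec$degree))
  stats::setNames(val, spec$label)
}
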