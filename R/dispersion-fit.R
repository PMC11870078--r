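#' Fit a dispersion model to a breath series
#'
#' The central fitting function: estimates the dispersion of a
#' breath-by-breath parameter around its exercise trend. With
#' `method = "loess"` a local degree-2 polynomial trend is fitted (per
#' phase, if a segmentation is supplied) and the dispersion is the sample
#' SD of the residuals; `"msd"` averages sliding-window SDs; `"sd"` is the
#' plain sample SD (appropriate only for untrended data).
#'
#' For multi-phase tests the recommended procedure is an independent LOESS
#' (span 0.75) per exercise phase, because a single whole-series fit
#' adapts slowly to the abrupt trend changes at phase transitions; the fit
#' then reports a dispersion per phase and one pooled over all residuals.
#'
#' @param x A [breath_series()] or numeric vector of per-cycle values.
#' @param method `"loess"` (default), `"msd"` or `"sd"`.
#' @param span LOESS neighbourhood fraction (default 0.75).
#' @param window MSD window length in cycles (default 7).
#' @param degree LOESS polynomial degree (default 2).
#' @param phases `NULL` for a whole-series fit, `TRUE` to take the phase
#'   labels carried by `x`, or a [phase_segmentation()]. Only supported
#'   for `method = "loess"`.
#' @param parameter Parameter kind when `x` is a bare numeric vector.
#' @return An object of class `"dispersion_fit"` with methods [coef()],
#'   [fitted()], [residuals()], [predict()], [simulate()], [plot()],
#'   [print()] and [summary()]. `coef()` returns the dispersion
#'   estimate(s) in parameter units.
#' @examples
#' s <- withr::with_seed(7, {
#'   flat <- simulate_flat_series(300, 790, 270)
#'   apply_trend(flat, "linear", 790, 2130)
#' })
#' fit <- dispersion_fit(s, method = "loess", span = 0.75)
#' coef(fit)
#' @export
dispersion_fit <- function(x, method = c("loess", "msd", "sd"),
                           span = 0.75, window = 7L, degree = 2L,
                           phases = NULL, parameter = "vt") {
  method <- match.arg(method)
  series <- if (inherits(x, "breath_series")) x
            else breath_series(x, parameter = parameter)
  spec <- method_spec(method, window = window, span = span, degree = degree)
  v <- series$values
  n <- length(v)

  seg <- NULL
  if (!is.null(phases) && !isFALSE(phases)) {
    if (method != "loess")
      stop("per-phase fitting is the LOESS procedure; method '", method,
           "' does not support a segmentation")
    seg <- if (isTRUE(phases)) {
      if (is.null(series$phase))
        stop("phases = TRUE but the series carries no phase labels")
      phase_segmentation(series$phase)
    } else if (inherits(phases, "phase_segmentation")) phases
    else stop("'phases' must be NULL, TRUE or a phase_segmentation")
    if (max(seg$end) != n)
      stop("segmentation covers ", max(seg$end), " cycles but the series ",
           "has ", n)
  }

  fitted_v <- NULL; resid_v <- NULL
  phase_estimates <- NULL
  if (method == "loess") {
    if (is.null(seg)) {
      f <- loess_fit(seq_len(n), v, span = span, degree = degree)
      fitted_v <- f$fitted
      resid_v <- f$residuals
      estimate <- stats::sd(resid_v)
    } else {
      fitted_v <- numeric(n); resid_v <- numeric(n)
      phase_estimates <- numeric(nrow(seg))
      for (k in seq_len(nrow(seg))) {
        rng <- seg$start[k]:seg$end[k]
        f <- loess_fit(seq_along(rng), v[rng], span = span, degree = degree)
        fitted_v[rng] <- f$fitted
        resid_v[rng] <- f$residuals
        phase_estimates[k] <- stats::sd(f$residuals)
      }
      names(phase_estimates) <- seg$label
      estimate <- stats::sd(resid_v)  # pooled over all residuals
    }
  } else if (method == "msd") {
    estimate <- moving_sd(v, window)
  } else {
    estimate <- plain_sd(v)
  }

  structure(
    list(call = match.call(), series = series, method = spec,
         estimate = estimate, phase_estimates = phase_estimates,
         segmentation = seg, fitted = fitted_v, residuals = resid_v,
         n = n),
    class = "dispersion_fit"
  )
}

#' @export
coef.dispersion_fit <- function(object, ...) {
  if (!is.null(object$phase_estimates))
    c(object$phase_estimates, pooled = object$estimate)
  else
    stats::setNames(object$estimate, object$method$label)
}

#' @export
fitted.dispersion_fit <- function(object, ...) object$fitted

#' @export
residuals.dispersion_fit <- function(object, ...) object$residuals

#' @export
print.dispersion_fit <- function(x, ...) {
  unit <- param_unit(x$series$parameter)
  cat(sprintf("Dispersion fit (%s) on %d cycles of %s\n", x$method$label,
              x$n, toupper(x$series$parameter)))
  if (!is.null(x$phase_estimates)) {
    cat("  per-phase dispersion [", unit, "]:\n", sep = "")
    for (k in seq_along(x$phase_estimates))
      cat(sprintf("    %-9s %.4g\n", names(x$phase_estimates)[k],
                  x$phase_estimates[k]))
    cat(sprintf("  pooled dispersion: %.4g %s\n", x$estimate, unit))
  } else {
    cat(sprintf("  dispersion: %.4g %s\n", x$estimate, unit))
  }
  invisible(x)
}

#' Residual diagnostics of a dispersion fit
#'
#' For LOESS fits, per-phase (or whole-series) summaries of the residuals
#' — n, mean, SD and skewness — supporting the recommended visual check
#' that the local fit is adequate: residual means should sit near zero and
#' the distribution should be roughly symmetric.
#'
#' @param object A [dispersion_fit()].
#' @param ... Unused.
#' @return An object of class `"summary.dispersion_fit"`.
#' @export
summary.dispersion_fit <- function(object, ...) {
  diag <- NULL
  if (!is.null(object$residuals)) {
    seg <- object$segmentation
    if (is.null(seg)) {
      grp <- list(whole = seq_len(object$n))
    } else {
      grp <- stats::setNames(
        lapply(seq_len(nrow(seg)), function(k) seg$start[k]:seg$end[k]),
        seg$label)
    }
    diag <- do.call(rbind, lapply(names(grp), function(g) {
      r <- object$residuals[grp[[g]]]
      data.frame(phase = g, n = length(r), mean = base::mean(r),
                 sd = stats::sd(r), skewness = e1071::skewness(r))
    }))
  }
  structure(list(fit = object, diagnostics = diag),
            class = "summary.dispersion_fit")
}

#' @export
print.summary.dispersion_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$diagnostics)) {
    cat("\nResidual diagnostics:\n")
    print(format(x$diagnostics, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Predict the fitted trend at arbitrary cycles
#'
#' Evaluates the local polynomial trend of a whole-series LOESS fit at new
#' cycle positions (exact local fits, not interpolation). For per-phase
#' fits or non-LOESS methods only the in-sample fitted values
#' (`cycles = NULL`) are available.
#'
#' @param object A [dispersion_fit()].
#' @param cycles Numeric cycle positions, or `NULL` for in-sample fitted
#'   values.
#' @param ... Unused.
#' @return Numeric vector of trend values.
#' @export
predict.dispersion_fit <- function(object, cycles = NULL, ...) {
  if (is.null(cycles)) {
    if (is.null(object$fitted))
      stop("method '", object$method$label, "' fits no trend curve")
    return(object$fitted)
  }
  if (object$method$method != "loess" || !is.null(object$segmentation))
    stop("out-of-sample prediction needs a whole-series LOESS fit")
  f <- loess_fit(seq_len(object$n), object$series$values,
                 span = object$method$span, degree = object$method$degree)
  loess_eval(f, cycles)
}

#' Simulate series from a fitted dispersion model
#'
#' Draws new breath series as fitted trend plus homoscedastic normal noise
#' at the estimated dispersion — the generative model under which the
#' estimators were validated. For methods without a trend curve
#' (`msd`/`sd`) the series mean is used as a flat trend.
#'
#' @param object A [dispersion_fit()].
#' @param nsim Number of series to simulate.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` [breath_series()] objects.
#' @export
simulate.dispersion_fit <- function(object, nsim = 1, seed = NULL, ...) {
  trend <- object$fitted %||% rep(base::mean(object$series$values),
                                  object$n)
  gen <- function() breath_series(
    trend + stats::rnorm(object$n, 0, object$estimate),
    parameter = object$series$parameter, phase = object$series$phase)
  if (!is.null(seed)) withr::with_seed(seed, replicate(nsim, gen(),
                                                       simplify = FALSE))
  else replicate(nsim, gen(), simplify = FALSE)
}

#' Plot a dispersion fit
#'
#' Top panel: the unfiltered cycle-by-cycle series with the fitted trend
#' curve(s) overlaid (one curve per phase for segmented fits). Bottom
#' panel: residuals around zero with a +-1 estimated-SD band. Methods
#' without a trend curve plot only the series.
#'
#' @param x A [dispersion_fit()].
#' @param ... Passed to the series panel.
#' @return `x`, invisibly.
#' @export
plot.dispersion_fit <- function(x, ...) {
  if (is.null(x$fitted)) {
    plot(x$series, main = x$method$label, ...)
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$series, main = x$method$label, ...)
  seg <- x$segmentation
  if (is.null(seg)) {
    graphics::lines(seq_len(x$n), x$fitted, col = "forestgreen", lwd = 2)
  } else {
    for (k in seq_len(nrow(seg))) {
      rng <- seg$start[k]:seg$end[k]
      graphics::lines(rng, x$fitted[rng], col = "forestgreen", lwd = 2)
    }
  }
  graphics::plot(seq_len(x$n), x$residuals, pch = 16, cex = 0.5,
                 xlab = "respiratory cycle", ylab = "residual")
  graphics::abline(h = 0, col = "grey40")
  graphics::abline(h = c(-1, 1) * x$estimate, lty = 2, col = "red")
  invisible(x)
}
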