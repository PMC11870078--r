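#' Exercise-phase segmentation of a CPET series
#'
#' Splits a test into contiguous, non-overlapping phases (`rest`,
#' `warmup`, `exercise`, `recovery`) covering every cycle. Phase
#' boundaries are operator-annotated (automatic detection is out of
#' scope). Each phase must hold at least 8 cycles — the minimum for a
#' local degree-2 fit at span 0.75.
#'
#' @param x Either a character vector of per-cycle phase labels (contiguous
#'   runs become phases), or a data frame with columns `label`, `start`,
#'   `end` (1-based, inclusive cycle ranges).
#' @return An object of class `"phase_segmentation"`: a data frame with
#'   columns `label`, `start`, `end`.
#' @examples
#' seg <- phase_segmentation(rep(c("rest", "exercise", "recovery"),
#'                               c(60, 180, 60)))
#' seg
#' @export
phase_segmentation <- function(x) {
  valid <- c("rest", "warmup", "exercise", "recovery")
  if (is.data.frame(x)) {
    if (!all(c("label", "start", "end") %in% names(x)))
      stop("segmentation data frame needs columns label, start, end")
    seg <- data.frame(label = as.character(x$label),
                      start = as.integer(x$start),
                      end = as.integer(x$end))
  } else {
    lab <- as.character(x)
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    seg <- data.frame(label = r$values,
                      start = c(1L, utils::head(ends, -1L) + 1L),
                      end = as.integer(ends))
  }
  bad <- setdiff(seg$label, valid)
  if (length(bad))
    stop("unknown phase label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(valid, collapse = "/"), ")")
  if (anyDuplicated(seg$label))
    stop("phase labels must be unique (contiguous blocks)")
  if (seg$start[1L] != 1L)
    stop("segmentation must start at cycle 1")
  if (nrow(seg) > 1L &&
      any(seg$start[-1L] != utils::head(seg$end, -1L) + 1L))
    stop("phases must be contiguous and non-overlapping")
  len <- seg$end - seg$start + 1L
  if (any(len < 8L))
    stop("phase '", seg$label[which(len < 8L)[1L]],
         "' has fewer than 8 cycles; too short for a local degree-2 fit")
  class(seg) <- c("phase_segmentation", "data.frame")
  seg
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("Phase segmentation:\n")
  for (k in seq_len(nrow(x)))
    cat(sprintf("  %-9s cycles %d-%d (%d)\n", x$label[k], x$start[k],
                x$end[k], x$end[k] - x$start[k] + 1L))
  invisible(x)
}

#' Per-phase LOESS dispersion of a multi-phase test
#'
#' The recommended procedure for real tests: fit an independent local
#' degree-2 polynomial (LOESS, span 0.75) within each exercise phase and
#' estimate the dispersion from the residuals. A single whole-series fit
#' adapts slowly to the abrupt trend reversals at phase transitions
#' (e.g. rest to exercise), inflating residuals there; separate per-phase
#' fits avoid that. Returns the residual SD per phase and the SD of all
#' residuals pooled across phases (single n-1 denominator).
#'
#' @param series A [breath_series()] covering all phases.
#' @param segmentation A [phase_segmentation()]; defaults to the phase
#'   labels carried by the series.
#' @param span LOESS span (default 0.75).
#' @param degree Local polynomial degree (default 2).
#' @return A [dispersion_fit()] whose `coef()` holds the per-phase
#'   dispersions plus the pooled estimate, and whose `fitted()` values are
#'   the per-phase trend curves (for overlay plots).
#' @examples
#' s <- withr::with_seed(2, {
#'   v <- c(rnorm(60, 500, 60), 500 + 16 * (1:180) + rnorm(180, 0, 60),
#'          rnorm(60, 900, 60))
#'   breath_series(v, "vt", phase = rep(c("rest", "exercise", "recovery"),
#'                                      c(60, 180, 60)))
#' })
#' fit <- per_phase_dispersion(s)
#' coef(fit)
#' @export
per_phase_dispersion <- function(series, segmentation = NULL, span = 0.75,
                                 degree = 2L) {
  stopifnot(inherits(series, "breath_series"))
  phases <- if (is.null(segmentation)) TRUE else segmentation
  dispersion_fit(series, method = "loess", span = span, degree = degree,
                 phases = phases)
}
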