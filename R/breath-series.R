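#' Breath-by-breath series
#'
#' Container for one breathing parameter recorded once per respiratory cycle
#' during a cardiopulmonary exercise test (CPET): tidal volume (VT, mL) or
#' breathing frequency (BF, breaths/min). Cycles are implicitly indexed
#' `1..N`. Optional per-cycle phase labels (`rest`, `warmup`, `exercise`,
#' `recovery`) must form contiguous blocks; sigh positions mark cycles whose
#' value was replaced by a sigh-sized breath.
#'
#' @param values Numeric vector, one finite value per respiratory cycle
#'   (length at least 2).
#' @param parameter `"vt"` (tidal volume, mL) or `"bf"` (breathing
#'   frequency, breaths/min).
#' @param phase Optional character/factor vector of per-cycle phase labels,
#'   same length as `values`, forming contiguous blocks.
#' @param sigh_positions Optional integer vector of cycle indices that hold
#'   sighs.
#' @return An object of class `"breath_series"`: a list with elements
#'   `values`, `parameter`, `phase` and `sigh_positions`.
#' @seealso [simulate_flat_series()], [dispersion_fit()], [read_breath_csv()]
#' @examples
#' bs <- breath_series(rnorm(50, 790, 270), parameter = "vt")
#' bs
#' @export
breath_series <- function(values, parameter = c("vt", "bf"), phase = NULL,
                          sigh_positions = NULL) {
  parameter <- match.arg(parameter)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a breath series needs at least 2 cycles, got ", length(values))
  if (!all(is.finite(values)))
    stop("breath series values must all be finite")
  if (!is.null(phase)) {
    phase <- as.character(phase)
    if (length(phase) != length(values))
      stop("'phase' must have one label per cycle")
    blocks <- rle(phase)$values
    if (anyDuplicated(blocks))
      stop("phase labels must form contiguous blocks; '",
           blocks[anyDuplicated(blocks)], "' appears in disjoint runs")
  }
  if (!is.null(sigh_positions)) {
    sigh_positions <- sort(unique(as.integer(sigh_positions)))
    if (length(sigh_positions) &&
        (min(sigh_positions) < 1L || max(sigh_positions) > length(values)))
      stop("sigh positions out of range 1..", length(values))
  }
  structure(
    list(values = values, parameter = parameter, phase = phase,
         sigh_positions = sigh_positions),
    class = "breath_series"
  )
}

#' @export
length.breath_series <- function(x) length(x$values)

#' Coerce a breath series to a data frame
#'
#' One row per respiratory cycle with columns `cycle`, `value`, `is_sigh`
#' and, when phase labels are present, `phase`.
#'
#' @param x A [breath_series()] object.
#' @param ... Unused.
#' @return A data frame with `length(x)` rows.
#' @export
as.data.frame.breath_series <- function(x, ...) {
  n <- length(x$values)
  d <- data.frame(
    cycle = seq_len(n),
    value = x$values,
    is_sigh = seq_len(n) %in% (x$sigh_positions %||% integer())
  )
  if (!is.null(x$phase)) d$phase <- x$phase
  d
}

#' @export
print.breath_series <- function(x, ...) {
  unit <- param_unit(x$parameter)
  cat(sprintf("Breath series: %d cycles of %s [%s]\n", length(x$values),
              toupper(x$parameter), unit))
  cat(sprintf("  mean %.4g, sample SD %.4g\n", mean(x$values),
              stats::sd(x$values)))
  if (!is.null(x$sigh_positions))
    cat(sprintf("  %d sighs at cycles: %s\n", length(x$sigh_positions),
                paste(x$sigh_positions, collapse = ", ")))
  if (!is.null(x$phase)) {
    r <- rle(x$phase)
    cat("  phases:", paste(sprintf("%s (%d)", r$values, r$lengths),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot a breath series as an unfiltered cycle-by-cycle graph
#'
#' Scatter of the per-cycle values against cycle index, the standard visual
#' used to assess breathing-pattern variability; sighs (if recorded) are
#' highlighted and phase boundaries (if labelled) are drawn as dashed lines.
#'
#' @param x A [breath_series()] object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.breath_series <- function(x, ...) {
  n <- length(x$values)
  unit <- param_unit(x$parameter)
  graphics::plot(seq_len(n), x$values, pch = 16, cex = 0.6,
                 xlab = "respiratory cycle",
                 ylab = sprintf("%s [%s]", toupper(x$parameter), unit), ...)
  if (!is.null(x$sigh_positions) && length(x$sigh_positions))
    graphics::points(x$sigh_positions, x$values[x$sigh_positions],
                     pch = 1, cex = 1.2, col = "red")
  if (!is.null(x$phase)) {
    r <- rle(x$phase)
    bounds <- cumsum(r$lengths)
    if (length(bounds) > 1L)
      graphics::abline(v = bounds[-length(bounds)] + 0.5, lty = 2,
                       col = "grey50")
  }
  invisible(x)
}

# unit string for a parameter kind
param_unit <- function(parameter) {
  switch(parameter, vt = "mL", bf = "breaths/min",
         stop("unknown parameter kind: ", parameter))
}

# accept a breath_series or a bare numeric vector
as_breath_values <- function(x) {
  if (inherits(x, "breath_series")) x$values
  else if (is.numeric(x)) as.numeric(x)
  else stop("expected a breath_series or a numeric vector")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
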