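#' Sigh model specification
#'
#' Sighs are isolated, much larger-than-usual breaths. They are modelled by
#' replacing randomly chosen tidal-volume values with draws from a
#' high-mean normal distribution: sigh sizes are Normal(`mean`, `sd`) mL,
#' inter-sigh gaps are Normal(`interval_mean`, `interval_sd`) cycles rounded
#' to integers and floored at `min_gap`, so no two sighs are closer than
#' `min_gap` cycles. Defaults reflect sighing observed in patients with
#' dysfunctional breathing after COVID-19: 3500 (200) mL sighs about every
#' 15 (3) cycles, never closer than 4 cycles.
#'
#' @param mean Mean sigh volume, mL.
#' @param sd SD of sigh volume, mL (positive).
#' @param interval_mean Mean gap between consecutive sighs, cycles.
#' @param interval_sd SD of the gap, cycles.
#' @param min_gap Minimum allowed gap, cycles (at least 1, and smaller than
#'   `interval_mean`).
#' @return An object of class `"sigh_spec"`.
#' @seealso [insert_sighs()], [breath_scenario()]
#' @export
sigh_spec <- function(mean = 3500, sd = 200, interval_mean = 15,
                      interval_sd = 3, min_gap = 4L) {
  min_gap <- as.integer(min_gap)
  if (sd <= 0) stop("sigh sd must be positive")
  if (interval_sd <= 0) stop("interval_sd must be positive")
  if (min_gap < 1L) stop("min_gap must be at least 1 cycle")
  if (interval_mean <= min_gap)
    stop("interval_mean must exceed min_gap")
  structure(list(mean = mean, sd = sd, interval_mean = interval_mean,
                 interval_sd = interval_sd, min_gap = min_gap),
            class = "sigh_spec")
}

#' Simulation scenario specification
#'
#' Describes one simulation scenario for validating dispersion estimators:
#' which breathing parameter is simulated, its true dispersion (the sample
#' SD of the flat series before any trend), the exercise trend shape, an
#' optional sigh model, the series length and the number of Monte-Carlo
#' replicates. Defaults mirror CPET values observed in a post-COVID
#' dysfunctional-breathing case series: 300 cycles per test, VT rising from
#' 790 mL at rest to 2130 mL at peak exercise, BF from 18 to 39 breaths/min.
#'
#' @param parameter `"vt"` or `"bf"`.
#' @param true_sd True dispersion in parameter units (positive). Study
#'   levels are 60/270/500 mL for VT and 2/4/6 breaths/min for BF.
#' @param trend Trend shape: `"flat"`, `"linear"`, `"logarithmic"` (typical
#'   extreme for VT) or `"exponential"` (typical extreme for BF).
#' @param sighs `NULL` (no sighs), `TRUE` (default [sigh_spec()]) or a
#'   [sigh_spec()] object. Sighs are only modelled for VT.
#' @param n_cycles Number of respiratory cycles per test (default 300).
#' @param rest_mean,end_mean Mean parameter value at the first and last
#'   cycle. Defaults: 790/2130 mL (VT), 18/39 breaths/min (BF).
#' @param trend_constant Curvature constant of the exponential trend, in
#'   cycles (default 40).
#' @param n_reps Number of Monte-Carlo replicates (default 10000, the scale
#'   of the original simulation study).
#' @param seed Optional master seed; replicate `r` uses a sub-seed derived
#'   from `(seed, r)` so individual replicates are reproducible.
#' @return An object of class `"breath_scenario"`.
#' @seealso [generate_replicates()], [dispersion_study()],
#'   [scenario_presets()]
#' @examples
#' sc <- breath_scenario("vt", true_sd = 270, trend = "logarithmic",
#'                       n_reps = 10, seed = 1)
#' reps <- generate_replicates(sc)
#' sapply(reps[1:3], function(s) stats::sd(s$values))
#' @export
breath_scenario <- function(parameter = c("vt", "bf"), true_sd,
                            trend = c("flat", "linear", "logarithmic",
                                      "exponential"),
                            sighs = NULL, n_cycles = 300L,
                            rest_mean = NULL, end_mean = NULL,
                            trend_constant = 40, n_reps = 10000L,
                            seed = NULL) {
  parameter <- match.arg(parameter)
  trend <- match.arg(trend)
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 2L) stop("n_cycles must be at least 2")
  if (!is.numeric(true_sd) || true_sd <= 0)
    stop("true_sd must be a positive number")
  rest_mean <- rest_mean %||% switch(parameter, vt = 790, bf = 18)
  end_mean <- end_mean %||% switch(parameter, vt = 2130, bf = 39)
  if (trend != "flat" && end_mean < rest_mean)
    stop("end_mean must be >= rest_mean for a rising trend")
  if (isTRUE(sighs)) sighs <- sigh_spec()
  if (isFALSE(sighs)) sighs <- NULL
  if (!is.null(sighs)) {
    if (!inherits(sighs, "sigh_spec"))
      stop("'sighs' must be NULL, TRUE or a sigh_spec object")
    if (parameter != "vt")
      stop("sighs are only modelled for tidal volume (parameter = \"vt\")")
  }
  if (n_reps < 1L) stop("n_reps must be positive")
  structure(
    list(parameter = parameter, true_sd = true_sd, trend = trend,
         sighs = sighs, n_cycles = n_cycles, rest_mean = rest_mean,
         end_mean = end_mean, trend_constant = trend_constant,
         n_reps = as.integer(n_reps), seed = seed),
    class = "breath_scenario"
  )
}

#' @export
print.breath_scenario <- function(x, ...) {
  cat(sprintf(
    "Breath scenario: %s, true SD %g %s, %s trend%s\n",
    toupper(x$parameter), x$true_sd, param_unit(x$parameter), x$trend,
    if (is.null(x$sighs)) "" else ", with sighs"))
  cat(sprintf("  %d cycles, means %g -> %g, %d replicates%s\n",
              x$n_cycles, x$rest_mean, x$end_mean, x$n_reps,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Simulate a flat (untrended) breath series with exact sample SD
#'
#' Draws `n_cycles` values from a normal distribution, then re-centres and
#' rescales the deviations so the sample mean equals `mean` and the sample
#' SD (n-1 denominator) equals `sd` exactly. The exact rescaling makes the
#' true dispersion of every replicate identical, so the plain SD of a flat
#' replicate has zero Monte-Carlo spread.
#'
#' Uses the current RNG state; wrap in [withr::with_seed()] or use
#' [generate_replicates()] for reproducible streams.
#'
#' @param n_cycles Series length (at least 2).
#' @param mean Target sample mean, parameter units.
#' @param sd Target sample SD, parameter units (non-negative; 0 gives a
#'   constant series).
#' @param parameter `"vt"` or `"bf"`.
#' @return A [breath_series()].
#' @examples
#' s <- withr::with_seed(1, simulate_flat_series(300, 790, 270))
#' stats::sd(s$values)  # exactly 270
#' @export
simulate_flat_series <- function(n_cycles, mean, sd, parameter = "vt") {
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 2L)
    stop("n_cycles must be an integer >= 2")
  if (!is.numeric(sd) || sd < 0) stop("sd must be non-negative")
  if (sd == 0) {
    v <- rep(mean, n_cycles)
  } else {
    v <- stats::rnorm(n_cycles, mean, sd)
    v <- rescale_exact(v, mean, sd)
  }
  breath_series(v, parameter = parameter)
}

# centre/scale so sample mean and SD (n-1) are hit exactly
rescale_exact <- function(v, target_mean, target_sd) {
  s <- stats::sd(v)
  if (s == 0) stop("cannot rescale a constant vector to a positive SD")
  (v - base::mean(v)) * (target_sd / s) + target_mean
}

#' Insert sighs into a flat breath series
#'
#' Replaces randomly spaced values of a flat (untrended) tidal-volume
#' series by sigh-sized breaths and rescales the whole series about its
#' post-insertion mean so the overall sample SD equals `target_sd` exactly.
#' Sigh positions start from the series start with one draw of the gap
#' distribution (no sigh is forced at cycle 1); each gap is
#' Normal(`interval_mean`, `interval_sd`) rounded to integer and floored at
#' `min_gap`; positions beyond the series end are discarded.
#'
#' @param series A flat [breath_series()] (trend not yet applied).
#' @param spec A [sigh_spec()].
#' @param target_sd Overall sample SD after insertion and rescaling
#'   (positive).
#' @return A [breath_series()] with `sigh_positions` recorded. If the
#'   series is too short to hold a single sigh the input is returned
#'   unmodified with a warning.
#' @examples
#' s <- withr::with_seed(1, {
#'   flat <- simulate_flat_series(300, 790, 270)
#'   insert_sighs(flat, sigh_spec(), target_sd = 270)
#' })
#' stats::sd(s$values)  # exactly 270
#' length(s$sigh_positions)
#' @export
insert_sighs <- function(series, spec = sigh_spec(), target_sd) {
  stopifnot(inherits(series, "breath_series"), inherits(spec, "sigh_spec"))
  if (!is.numeric(target_sd) || target_sd <= 0)
    stop("target_sd must be positive")
  v <- series$values
  n <- length(v)
  pos <- draw_sigh_positions(n, spec)
  if (length(pos) == 0L) {
    warning("series too short to hold a sigh; returned unmodified")
    return(series)
  }
  v[pos] <- stats::rnorm(length(pos), spec$mean, spec$sd)
  v <- rescale_exact(v, base::mean(v), target_sd)
  breath_series(v, parameter = series$parameter, phase = series$phase,
                sigh_positions = pos)
}

# gap-chain sigh placement: cumulative rounded normal gaps, floored at
# min_gap, truncated at n
draw_sigh_positions <- function(n, spec) {
  pos <- integer()
  p <- 0
  repeat {
    gap <- max(spec$min_gap, round(stats::rnorm(1, spec$interval_mean,
                                                spec$interval_sd)))
    p <- p + gap
    if (p > n) break
    pos <- c(pos, as.integer(p))
  }
  pos
}

#' Trend curve values
#'
#' The deterministic exercise trend evaluated at cycles `1..n`, anchored at
#' `rest_mean` (first cycle) and `end_mean` (last cycle). Shapes, with
#' `i = 1..n`:
#' \describe{
#'   \item{flat}{constant `rest_mean`.}
#'   \item{linear}{`rest + (end - rest) * (i - 1) / (n - 1)`.}
#'   \item{logarithmic}{`rest + (end - rest) * log(i) / log(n)` — a
#'     markedly curved rise, the extreme VT trend.}
#'   \item{exponential}{`rest + (end - rest) *
#'     (exp((i - 1) / c) - 1) / (exp((n - 1) / c) - 1)` with curvature
#'     constant `c` (default 40 cycles) — the extreme BF trend.}
#' }
#'
#' @param shape Trend shape name.
#' @param n Number of cycles.
#' @param rest_mean,end_mean Anchor values at the first and last cycle.
#' @param constant Exponential curvature constant, cycles.
#' @return Numeric vector of length `n`.
#' @export
trend_curve <- function(shape = c("flat", "linear", "logarithmic",
                                  "exponential"),
                        n, rest_mean, end_mean, constant = 40) {
  shape <- match.arg(shape)
  i <- seq_len(n)
  span <- end_mean - rest_mean
  switch(shape,
    flat = rep(rest_mean, n),
    linear = rest_mean + span * (i - 1) / (n - 1),
    logarithmic = rest_mean + span * log(i) / log(n),
    exponential = rest_mean +
      span * expm1((i - 1) / constant) / expm1((n - 1) / constant)
  )
}

#' Apply an exercise trend to a flat breath series
#'
#' Adds the additive offset `T(i) - T(1)` of a [trend_curve()] to every
#' value, so a noiseless flat series at `rest_mean` rises exactly from
#' `rest_mean` to `end_mean`. Sigh values receive the same offset as their
#' neighbours (sighs ride the trend). The flat shape returns the input
#' unchanged.
#'
#' @param series A [breath_series()] (optionally with sighs inserted).
#' @param shape Trend shape, see [trend_curve()].
#' @param rest_mean,end_mean Trend anchors, parameter units.
#' @param constant Exponential curvature constant, cycles.
#' @return A [breath_series()] with the trend added.
#' @export
apply_trend <- function(series, shape, rest_mean, end_mean, constant = 40) {
  stopifnot(inherits(series, "breath_series"))
  shape <- match.arg(shape, c("flat", "linear", "logarithmic",
                              "exponential"))
  if (shape == "flat") return(series)
  n <- length(series$values)
  tc <- trend_curve(shape, n, rest_mean, end_mean, constant)
  breath_series(series$values + (tc - tc[1L]), parameter = series$parameter,
                phase = series$phase,
                sigh_positions = series$sigh_positions)
}

#' Generate Monte-Carlo replicates of a scenario
#'
#' Builds `n_reps` independent series, each as
#' `simulate_flat_series()` (exact mean/SD), then optional
#' [insert_sighs()], then [apply_trend()]. Replicate `r` runs under a
#' sub-seed derived deterministically from `(seed, r)`, so any single
#' replicate can be regenerated on its own with `rep_index`.
#'
#' @param scenario A [breath_scenario()].
#' @param n_reps Override the scenario's replicate count.
#' @param seed Override the scenario's master seed (an integer; required
#'   here if the scenario has none).
#' @param rep_index Optional integer vector of replicate indices to
#'   generate (default all of `1..n_reps`).
#' @return A list of [breath_series()] objects.
#' @export
generate_replicates <- function(scenario, n_reps = NULL, seed = NULL,
                                rep_index = NULL) {
  stopifnot(inherits(scenario, "breath_scenario"))
  n_reps <- as.integer(n_reps %||% scenario$n_reps)
  seed <- seed %||% scenario$seed
  if (is.null(seed))
    stop("a master seed is required (in the scenario or as 'seed')")
  idx <- as.integer(rep_index %||% seq_len(n_reps))
  lapply(idx, function(r) {
    withr::with_seed(derive_seed(seed, r), {
      s <- simulate_flat_series(scenario$n_cycles, scenario$rest_mean,
                                scenario$true_sd, scenario$parameter)
      if (!is.null(scenario$sighs))
        s <- insert_sighs(s, scenario$sighs, scenario$true_sd)
      apply_trend(s, scenario$trend, scenario$rest_mean, scenario$end_mean,
                  scenario$trend_constant)
    })
  })
}

# deterministic sub-seed from (master, r); stays below 2^31 and exact in
# doubles (terms < 2^53)
derive_seed <- function(master, r) {
  m <- as.double(master) %% 65521
  as.integer((m * 65537 + as.double(r) * 2654435 + 1) %% 2147483647)
}

#' Scenario presets of the simulation study
#'
#' The preset grid of the validation study, read from a YAML file shipped
#' with the package: for each parameter family (BF, VT, VT with sighs) the
#' rest/peak means, the three true-SD levels and the trend shapes tested.
#'
#' @return A named list; each element has entries `parameter`, `rest_mean`,
#'   `end_mean`, `sd_levels`, `trends`, `sighs`, `n_cycles`, `n_reps`.
#' @examples
#' names(scenario_presets())
#' @export
scenario_presets <- function() {
  path <- system.file("extdata", "scenarios.yaml", package = "breathvar")
  yaml::read_yaml(path)
}
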