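#' Run one bias/precision study cell
#'
#' Generates Monte-Carlo replicates of a scenario, applies one dispersion
#' method to each, and summarises: mean estimate, bias (mean minus true
#' SD), precision (SD of the estimates across replicates) and Monte-Carlo
#' standard error (precision / sqrt(n_reps)).
#'
#' @param scenario A [breath_scenario()].
#' @param method A [method_spec()], or a function taking a
#'   [breath_series()] and returning one numeric dispersion value.
#' @param n_reps,seed Optional overrides of the scenario's replicate count
#'   and master seed.
#' @return A one-row data frame with columns `parameter`, `true_sd`,
#'   `trend`, `sighs`, `method`, `mean`, `bias`, `precision`, `mc_se`,
#'   `n_reps`.
#' @examples
#' sc <- breath_scenario("bf", true_sd = 4, trend = "flat", n_reps = 50,
#'                       seed = 1)
#' run_cell(sc, method_spec("loess", span = 0.75))
#' @export
run_cell <- function(scenario, method, n_reps = NULL, seed = NULL) {
  stopifnot(inherits(scenario, "breath_scenario"))
  reps <- generate_replicates(scenario, n_reps = n_reps, seed = seed)
  est_fun <- if (inherits(method, "method_spec")) {
    function(s) unname(estimate_dispersion(s, method))
  } else if (is.function(method)) method
  else stop("'method' must be a method_spec or a function")
  ests <- vapply(seq_along(reps), function(r)
    tryCatch(est_fun(reps[[r]]),
             error = function(e) stop("replicate ", r, " (sub-seed ",
                                      derive_seed(seed %||% scenario$seed, r),
                                      ") failed: ", conditionMessage(e))),
    numeric(1))
  label <- if (inherits(method, "method_spec")) method$label else "custom"
  cell_summary(ests, scenario, scenario$trend, label)
}

cell_summary <- function(ests, scenario, trend, label) {
  n <- length(ests)
  prec <- stats::sd(ests)
  data.frame(parameter = scenario$parameter, true_sd = scenario$true_sd,
             trend = trend, sighs = !is.null(scenario$sighs),
             method = label, mean = base::mean(ests),
             bias = base::mean(ests) - scenario$true_sd,
             precision = prec, mc_se = prec / sqrt(n), n_reps = n)
}

#' Run a full bias/precision simulation study
#'
#' The factorial Monte-Carlo validation: for each true-SD level, flat
#' replicates (optionally with sighs) are generated once, every trend
#' shape is applied to the same replicate streams, and every method is
#' evaluated on the same trended series (common random numbers, so method
#' and trend contrasts carry reduced Monte-Carlo noise). Results mirror
#' the published table layout: one cell per (SD level, trend, method).
#'
#' Defaults reproduce the study grids: BF at SD 2/4/6 breaths/min under
#' flat/linear/exponential trends, VT at SD 60/270/500 mL under
#' flat/linear/logarithmic trends, eight methods (plain SD, LOESS at spans
#' 1/0.75/0.5, MSD at windows 7/11/15/19).
#'
#' @param parameter `"bf"` or `"vt"`.
#' @param sd_levels True-SD levels; defaults 2/4/6 (BF) or 60/270/500 (VT).
#' @param trends Trend shapes; defaults flat/linear/exponential (BF) or
#'   flat/linear/logarithmic (VT).
#' @param methods List of [method_spec()]s (default [study_methods()]).
#' @param sighs `FALSE`, `TRUE` (default [sigh_spec()]) or a
#'   [sigh_spec()]; VT only.
#' @param n_cycles Cycles per test (default 300).
#' @param rest_mean,end_mean Trend anchors; defaults per parameter.
#' @param n_reps Replicates per cell (default 1000; the original study
#'   used 10000).
#' @param seed Master seed (required for reproducibility).
#' @param trend_constant Exponential curvature constant, cycles.
#' @return An object of class `"dispersion_study"`: a data frame of cells
#'   (columns as in [run_cell()]) with the study settings as attributes.
#' @examples
#' st <- dispersion_study("bf", sd_levels = 4, trends = c("flat", "linear"),
#'                        methods = study_methods()[c("SD", "LOESS_0.75")],
#'                        n_reps = 50, seed = 1)
#' st
#' @export
dispersion_study <- function(parameter = c("bf", "vt"), sd_levels = NULL,
                             trends = NULL, methods = study_methods(),
                             sighs = FALSE, n_cycles = 300L,
                             rest_mean = NULL, end_mean = NULL,
                             n_reps = 1000L, seed = 1L,
                             trend_constant = 40) {
  parameter <- match.arg(parameter)
  sd_levels <- sd_levels %||%
    switch(parameter, bf = c(2, 4, 6), vt = c(60, 270, 500))
  trends <- trends %||%
    switch(parameter, bf = c("flat", "linear", "exponential"),
           vt = c("flat", "linear", "logarithmic"))
  trends <- match.arg(trends, c("flat", "linear", "logarithmic",
                                "exponential"), several.ok = TRUE)
  if (isTRUE(sighs)) sighs <- sigh_spec()
  if (isFALSE(sighs)) sighs <- NULL
  if (!length(sd_levels) || !length(trends) || !length(methods))
    stop("sd_levels, trends and methods must be non-empty")
  if (!all(vapply(methods, inherits, TRUE, "method_spec")))
    stop("'methods' must be a list of method_spec objects")
  n_cycles <- as.integer(n_cycles)
  n_reps <- as.integer(n_reps)

  rows <- list()
  for (k in seq_along(sd_levels)) {
    sdk <- sd_levels[k]
    sc <- breath_scenario(parameter, true_sd = sdk, trend = "flat",
                          sighs = sighs, n_cycles = n_cycles,
                          rest_mean = rest_mean, end_mean = end_mean,
                          trend_constant = trend_constant, n_reps = n_reps,
                          seed = derive_seed(seed, 7919L * k))
    base_reps <- generate_replicates(sc)
    V <- vapply(base_reps, `[[`, numeric(n_cycles), "values")
    for (tr in trends) {
      tc <- trend_curve(tr, n_cycles, sc$rest_mean, sc$end_mean,
                        trend_constant)
      Y <- V + (tc - tc[1L])
      for (m in methods) {
        ests <- method_estimates(Y, m)
        sc_tr <- sc; sc_tr$trend <- tr
        rows[[length(rows) + 1L]] <- cell_summary(ests, sc_tr, tr, m$label)
      }
    }
  }
  res <- do.call(rbind, rows)
  structure(res, class = c("dispersion_study", "data.frame"),
            parameter = parameter, n_reps = n_reps, seed = seed,
            n_cycles = n_cycles,
            sighs_on = !is.null(sighs))
}

# column-wise estimates of one method over a matrix of replicate series
# (cycles x replicates); loess uses one shared smoother matrix
method_estimates <- function(Y, m) {
  switch(m$method,
    sd = col_sds(Y),
    msd = apply(Y, 2L, moving_sd, window = m$window),
    loess = {
      L <- loess_smoother_matrix(nrow(Y), m$span, m$degree)
      col_sds(Y - L %*% Y)
    })
}

col_sds <- function(m) {
  n <- nrow(m)
  ctr <- sweep(m, 2L, colMeans(m))
  sqrt(colSums(ctr * ctr) / (n - 1))
}

#' @export
print.dispersion_study <- function(x, ...) {
  unit <- param_unit(attr(x, "parameter"))
  cat(sprintf("Dispersion study: %s [%s], %d replicates/cell, seed %s%s\n",
              toupper(attr(x, "parameter")), unit, attr(x, "n_reps"),
              format(attr(x, "seed")),
              if (attr(x, "sighs_on")) ", with sighs" else ""))
  d <- as.data.frame(x)
  for (sdk in unique(d$true_sd)) {
    cat(sprintf("\nTrue SD %g %s (mean estimate, +-precision):\n", sdk,
                unit))
    sub <- d[d$true_sd == sdk, ]
    trends <- unique(sub$trend)
    methods <- unique(sub$method)
    tab <- sapply(trends, function(tr) {
      s <- sub[sub$trend == tr, ]
      sprintf("%.4g (+-%.2g)", s$mean[match(methods, s$method)],
              s$precision[match(methods, s$method)])
    })
    tab <- matrix(tab, nrow = length(methods),
                  dimnames = list(methods, trends))
    print(tab, quote = FALSE)
  }
  invisible(x)
}

#' Bias/precision summary of a study
#'
#' Long-format table of bias and precision per (method, trend, true SD) —
#' the numbers behind the study's bias/precision panel figures. The same
#' layout is drawn by [plot.dispersion_study()].
#'
#' @param results A [dispersion_study()] result (or any data frame with
#'   its columns).
#' @return A data frame with columns `true_sd`, `trend`, `method`, `mean`,
#'   `bias`, `precision`, `mc_se`, `n_reps`.
#' @export
summarize_bias_precision <- function(results) {
  d <- as.data.frame(results)
  need <- c("true_sd", "trend", "method", "mean", "bias", "precision")
  if (!all(need %in% names(d)))
    stop("results lack required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  out <- d[order(d$trend, d$true_sd, d$method),
           intersect(c(need, "mc_se", "n_reps"), names(d))]
  rownames(out) <- NULL
  out
}

#' Plot bias and precision panels of a study
#'
#' One row of panels per trend shape; left column bias, right column
#' precision, plotted against the true SD with one line per method. The
#' red reference line marks zero bias / perfect precision.
#'
#' @param x A [dispersion_study()] result.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.dispersion_study <- function(x, ...) {
  d <- as.data.frame(x)
  trends <- unique(d$trend)
  methods <- unique(d$method)
  cols <- grDevices::hcl.colors(length(methods), "Dark 3")
  op <- graphics::par(mfrow = c(length(trends), 2),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (tr in trends) {
    sub <- d[d$trend == tr, ]
    for (what in c("bias", "precision")) {
      rng <- range(0, sub[[what]])
      graphics::plot(NA, xlim = range(sub$true_sd), ylim = rng,
                     xlab = "true SD", ylab = what,
                     main = sprintf("%s trend", tr))
      graphics::abline(h = 0, col = "red")
      for (j in seq_along(methods)) {
        s <- sub[sub$method == methods[j], ]
        s <- s[order(s$true_sd), ]
        graphics::lines(s$true_sd, s[[what]], col = cols[j], type = "b",
                        pch = 16, cex = 0.7)
      }
      if (tr == trends[1L] && what == "bias")
        graphics::legend("topleft", legend = methods, col = cols, lty = 1,
                         pch = 16, cex = 0.6, bty = "n")
    }
  }
  invisible(x)
}
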