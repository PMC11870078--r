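---
title: "Measuring breathing-pattern dispersion around an exercise trend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring breathing-pattern dispersion around an exercise trend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathvar)
```

## The problem

Breath-by-breath analysis of a cardiopulmonary exercise test (CPET) yields
one tidal volume (VT, mL) and one breathing frequency (BF, breaths/min)
value per respiratory cycle — typically around 300 cycles for a full test.
Patients with dysfunctional breathing show erratic cycle-to-cycle
variability and frequent sighs on these unfiltered graphs. Turning that
visual impression into an objective number requires a dispersion measure,
and the obstacle is the exercise trend: VT and BF rise during exercise
along an individual, usually non-linear trajectory, so the plain sample SD
of a test mixes the trend with the breath-to-breath scatter. The quantity
of interest is the dispersion *around* the trended parameter.

Formally, the model behind everything in this package is

$$y_i = T(i) + \varepsilon_i, \qquad \varepsilon_i \sim
\mathcal{N}(0, \sigma^2), \qquad i = 1, \dots, N,$$

where $T$ is a smooth monotone trend over cycle index and $\sigma$ is the
true dispersion. Two non-parametric estimators of $\sigma$ are
implemented; both avoid assumptions about the form of $T$.

## The estimators

**Moving SD.** `moving_sd(y, n)` averages the sample SDs of all $N-n+1$
fully contained sliding windows (stride 1, no partial edge windows;
edge padding is deliberately avoided because it would mix window sizes).
Its behaviour is a tug-of-war between two biases:

* downward: the sample SD of $n$ normal observations underestimates
  $\sigma$ by the factor $c_4(n) = \sqrt{2/(n-1)}\,
  \Gamma(n/2)/\Gamma((n-1)/2)$ (`sd_bias_factor()`), about 11% at $n=3$,
  6% at $n=5$ and 4% at $n=7$;
* upward: within a window the trend contributes roughly
  $\mathrm{Var}[T] \approx d^2(n^2-1)/12$ for local slope $d$, so large
  windows are inflated whenever a trend is present.

Windows of 7, 11, 15 and 19 cycles span the useful range and are the
defaults of `study_methods()`.

**LOESS residual SD.** `loess_fit(x, y, span, degree = 2)` is a locally
estimated scatterplot smoothing with nearest-neighbour bandwidth: at each
target point the $q = \max(\text{degree}+2, \lceil \text{span}\cdot N
\rceil)$ nearest predictors are selected (distance ties broken towards the
lower index), weighted by the tricube $(1-(d/d_{\max})^3)^3$, and a
weighted least-squares polynomial of degree 2 is evaluated at the target.
`loess_residual_sd()` then takes the sample SD of $y - \hat T$. All SDs in
the package use the $n-1$ denominator; this is what makes the $c_4$
figures above exact.

Two implementation choices deserve a note. First, the fit is evaluated
exactly at every point — there is no interpolation grid and no robustness
iteration; on 300-cycle series the fitted values agree with
`stats::loess(..., surface = "direct")` to well under 0.1%, and the test
suite checks both that agreement and exact equivalence with a brute-force
per-point normal-equations solver. Second, because the fit is linear in
$y$, the whole smoother is a matrix $L$ with $\hat y = Ly$;
`loess_smoother_matrix()` caches $L$ per $(N, \text{span}, \text{degree})$,
which reduces a full Monte-Carlo study to a handful of matrix products.
A degenerate neighbourhood (all selected $x$ identical, impossible with
integer cycle indices) or a singular weighted design raises an error
naming the offending point.

The decisive property of the LOESS estimator is *linear equivariance*: a
degree $\ge 1$ local fit reproduces any affine function of the cycle index
exactly, so adding a linear trend leaves every residual — and hence the
estimate — unchanged, replicate by replicate. This is why flat and linear
columns of the study tables are identical for all LOESS rows.

## The synthetic-data generator

`breath_scenario()` + `generate_replicates()` emulate the conditions under
which the estimators were validated, with parameters taken from real CPET
tests of patients with dysfunctional breathing after COVID-19:

* 300 cycles per test; VT from 790 mL (rest) to 2130 mL (peak), BF from
  18 to 39 breaths/min;
* true dispersion levels 60/270/500 mL (VT) and 2/4/6 breaths/min (BF);
* normally distributed cycle values, re-centred and rescaled so each
  replicate's sample mean and SD are *exact*. The exact-SD rescaling makes
  the flat-column plain SD deterministic (zero spread), so every bias in
  the study is attributable to the estimator, not to sampling of the
  ground truth;
* trends: linear, plus one markedly curved extreme per parameter. The
  curved forms are, with $u = $ rest mean, $v = $ peak mean,
  logarithmic $T(i) = u + (v-u)\ln i/\ln N$ and exponential
  $T(i) = u + (v-u)(e^{(i-1)/c}-1)/(e^{(N-1)/c}-1)$ with $c = 40$ cycles.
  The published study names the shapes but not their closed forms; these
  parameterisations were chosen because they reproduce the raw-SD table
  cells under each trend to within a few tenths of a percent, and they are
  arguments (`trend_constant`, or a custom curve via `apply_trend`) rather
  than constants, so an alternative form can be swapped in. If the methods
  are robust at these two extremes, trends between them are covered;
* sighs (VT only): values *replaced* by draws from
  $\mathcal{N}(3500, 200)$ mL at gaps of $\mathcal{N}(15, 3)$ cycles,
  rounded and floored at 4 (so sighs are never closer than 4 cycles); the
  position chain starts with one gap draw from cycle 1, and positions past
  the end are discarded, giving about 20 sighs per test. After insertion
  the series is rescaled about its post-insertion mean to the target SD —
  the mean is preserved because only the SD adjustment is part of the
  design. Trends are applied after sighs, so sighs grow with exercise; in
  real patients sigh amplitude often stays constant, making the simulated
  case the harder one.

Randomness is controlled by a master seed; replicate $r$ runs under a
sub-seed derived from $(\text{seed}, r)$, so single replicates are
regenerable without generating their predecessors.

What the generator does **not** emulate: serial autocorrelation of breath
parameters, non-normal (skewed or heavy-tailed) dispersion,
within-test changes of $\sigma$, breathing-frequency sighs, and recovery
phases (a single rest-to-peak trend is simulated). Passing the validation
study therefore shows correctness of the estimators under the stated
generative model, not universal adequacy for every real test — which is
why the per-phase procedure and residual diagnostics below exist.

## The bias/precision study

`dispersion_study()` runs the factorial grid (SD level × trend × method)
and reports per cell the mean estimate, the bias (mean − true SD), the
precision (SD of the estimates across replicates) and the Monte-Carlo
standard error. Two design choices:

* *Common random numbers*: flat replicates are generated once per SD
  level; every trend (a deterministic transform) and every method is
  applied to the same streams, so method and trend contrasts carry less
  Monte-Carlo noise than independent cells would.
* *Replicate count*: the original study used 10,000 replicates per cell;
  the package default is 1,000, at which the cell means carry a
  Monte-Carlo standard error of roughly 0.03% (LOESS) to 0.15% (MSD) of
  the estimate — ample for reproducing table cells printed to 3 significant
  digits. The acceptance suite uses 1,000; `n_reps` scales it freely.

```{r study, eval = TRUE}
st <- dispersion_study("bf", sd_levels = 4, trends = c("flat", "linear"),
                       methods = study_methods()[c("SD", "LOESS_0.75",
                                                   "MSD_7")],
                       n_reps = 200, seed = 1)
st
```

The qualitative picture this study reproduces: LOESS is globally less
biased and more precise than MSD, except under an extreme curved trend
combined with very low dispersion (e.g. VT at 60 mL under the logarithmic
trend), where the local quadratic cannot follow the initial steep bend and
LOESS overestimates while `MSD_7` happens to sit closer to the truth.
`LOESS_0.75` is the recommended trade-off between the tighter fit of span
0.5 (better under extreme trends, slight overfit when flat) and the
smoother span 1.

## Per-phase fitting for real tests

A real test concatenates phases (rest, warm-up, exercise, recovery) with
abrupt trend reversals at the transitions. A single whole-series LOESS
adapts slowly there, inflating residuals, so `per_phase_dispersion()` fits
an independent LOESS per phase (operator-annotated boundaries; either
three or four phases, as the protocol defines them) and reports both
per-phase residual SDs and one pooled SD over all residuals (single $n-1$
denominator; residuals are already centred by their phase fits). Each
phase must contain at least 8 cycles — the minimum for a degree-2 local
fit at span 0.75. `summary()` on the fit gives per-phase residual mean,
SD and skewness, and `plot()` overlays the fitted curves, supporting the
recommended visual check of fit adequacy before the number is trusted.

```{r phases, eval = TRUE}
s <- withr::with_seed(2, {
  v <- c(rnorm(60, 500, 60), 500 + 10 * (1:180) + rnorm(180, 0, 60),
         rnorm(60, 900, 60))
  breath_series(v, "vt", phase = rep(c("rest", "exercise", "recovery"),
                                     c(60, 180, 60)))
})
coef(per_phase_dispersion(s, span = 0.75))
```

## Numerical choices and degenerate inputs

* Sliding-window SDs are computed from running sums of globally centred
  values (`stats::filter`), exact to ~12 digits at CPET magnitudes and
  vectorised; a naive per-window `sd()` is kept as the test oracle.
* The smoother-matrix cache keys on $(N, \text{span}, \text{degree})$ and
  only engages for the equispaced cycle grid; arbitrary $x$ takes the
  per-point path.
* Zero requested dispersion yields a constant series; rescaling a
  constant series to a positive SD is an error.
* A series too short to hold one sigh is returned unmodified with a
  warning rather than an error, so scenario sweeps over short series do
  not abort.
* File input auto-detects comma/semicolon/tab delimiters and normalises
  decimal commas; cycle indices are 1-based and must be strictly
  increasing (no silent reindexing), and a VT column with median below 15
  triggers a litres-vs-mL warning. Units are never converted.

## Known limitations

* The logarithmic/exponential trend forms are reconstructions (see above);
  MSD cells under those trends are sensitive to the exact within-window
  slope and are treated as indicative, not as exact references.
* Robust (iteratively reweighted) LOESS, confidence intervals for the
  dispersion, entropy-based irregularity measures and diagnostic cutoffs
  for dysfunctional breathing are out of scope.
* The estimators quantify dispersion but not its cause: sighs and erratic
  breathing both raise VT dispersion, and distinguishing them remains a
  clinical judgement.
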