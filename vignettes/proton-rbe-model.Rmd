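---
title: "Modelling proton RBE from photon radiosensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling proton RBE from photon radiosensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbekit)
```

## The model

Clonogenic survival after a dose $D$ of radiation is described by the
linear-quadratic (LQ) model, $SF(D) = \exp(-\alpha D - \beta D^2)$. The
relative biological effectiveness (RBE) of a proton beam is the ratio of the
photon dose to the proton dose producing the same survival. Empirical RBE
models have traditionally parameterised how $\alpha_p/\alpha_x$ and
$\beta_p/\beta_x$ vary with the beam's dose-weighted linear energy transfer
(LET$_d$). `rbekit` implements a different empirical strategy: iso-survival
doses such as $D_{10\%}$ are linearly correlated between photons and
protons, and that correlation is far better determined than $\alpha$ or
$\beta$ individually, because the strongly negative $\alpha$–$\beta$ fit
covariance cancels in the propagation to an iso-survival dose (see
`propagate_endpoint_error()`).

The model asserts, for any survival level $SF$:

$$D_{SF,p} = slope(L)\, D_{SF,x} + intercept(L), \qquad
  slope(L) = c\,e^{-fL},\quad intercept(L) = p\,L.$$

Two endpoints are enough to pin down an LQ curve. The shipped model uses
$SF_1 = e^{-1}$ and $SF_2 = e^{-3}$ (near 37% and 5% survival), each with
its own $(c, f, p)$ triple — six parameters in all. These two levels make
the zero-intercept regression of $\ln SF$ on $(D, D^2)$ fully closed-form:
`reconstruct_alpha_beta_two_point()` returns the interpolating
$(\alpha_p, \beta_p)$, clamping a negative parameter to zero and re-solving
the other (the usual non-negativity constraint of LQ fitting;
`reconstruct_alpha_beta()` is the general $n$-endpoint version, and both are
verified in the tests against a box-constrained least-squares oracle).

A consequence worth noting: solving the endpoint law for RBE at a level the
curve interpolates gives
$RBE_{SF} = 1/(c\,e^{-fL} + pL/D_{SF,x})$,
which exceeds 1 for radioresistant cells (large $D_{SF,x}$) and drops below
1 exactly when $D_{SF,x} < pL/(1 - c\,e^{-fL})$ — sub-unity RBE for
extremely radiosensitive cells, which ratio-based empirical models cannot
produce.

## Parameters and defaults

`flint_default_model()` ships the fitted values (with the full 6×6
covariance) obtained on the published 397 cell-line/LET training
compilation:

| parameter | value | units |
|---|---|---|
| $c_1$ | 1.041543 | — |
| $f_1$ | 0.04709 | per keV/µm |
| $p_1$ | 0.02376 | Gy per keV/µm |
| $c_2$ | 1.045578 | — |
| $f_2$ | 0.03213 | per keV/µm |
| $p_2$ | 0.06550 | Gy per keV/µm |

The slope amplitudes $c_j$ are near 1 (protons resemble photons at zero
LET); $f_j$ sets how quickly proton effectiveness grows with LET; $p_j$
adds a dose offset that matters most for radiosensitive lines. Inputs are
the photon $(\alpha_x, \beta_x)$ of the tissue or cell line (1/Gy, 1/Gy²)
and LET$_d$ in keV/µm; `predict_proton_curve()` and `predict_rbe()` are the
scalar interface, `rbe_weighted_dose()` maps the same computation over
co-registered dose/LET grids (per-fraction dose semantics; total
RBE-weighted dose is the per-fraction result times the fraction count).

## Data model and quality filters

Training data are tables of paired photon/proton LQ parameters per cell
line/LET combination (`read_survival_table()`; a PIDE-style CSV dialect).
`apply_exclusion_filters()` implements the quality rules a clean training
set must satisfy: $\beta \le 0$ for either quality (survival integrals and
$\alpha/\beta$ diverge), hypoxic exposures (oxygen enhancement inflates
RBE), extreme radioresistance (iso-survival doses beyond 40 Gy, where LQ
extrapolation is untrustworthy — implemented as a reusable $D_{10\%}$ rule
rather than a hard-coded cell-line name, plus an optional name list),
viability (non-clonogenic) assays, LET$_d$ strictly above 37.8 keV/µm, and
photon references below 200 kVp. The $\beta$ rule is applied to *either*
radiation quality: the stated reasons (divergent integrals, divergent
$\alpha/\beta$) apply to both sides of a pair. Unparseable photon-source
descriptors are kept and reported, since the rule targets known low-energy
x-ray sources.

## Fitting

`rbe_fit()` estimates the six parameters on a filtered table under either
objective used in practice:

* **`l2`** (default): the sum over experiments of
  $\sqrt{\int_0^\infty (SF_{pred} - SF_{meas})^2\,dD} \big/ \bar D_{meas}$,
  where $\bar D$ is the mean inactivation dose $\int_0^\infty SF\,dD$.
  Conventions the literature leaves open are fixed here and isolated in
  `curve_l2_distance()`: the integrand is the survival-fraction difference
  (not log-survival), the range is $[0, \infty)$, the normalising curve is
  the *measured* one, and the dataset objective is the *sum* of
  per-experiment distances.
* **`rbe2gy`**: residual sum of squares of predicted vs measured RBE at a
  2 Gy proton dose (the clinically typical fraction dose).

All survival integrals have closed forms through the scaled complementary
error function; that function is itself computed from the log of the normal
tail below $x = 15$ and by its asymptotic series above (the naive
$e^{x^2}\mathrm{erfc}(x)$ product overflows in double precision near
$x \approx 27$, which the integrals hit routinely for low-$\beta$ curves).
The closed forms agree with adaptive quadrature to $10^{-8}$ relative in
the tests.

Two numerical properties of the `l2` objective shape the implementation:

1. *Non-smoothness at perfect fits.* A sum of norms is not differentiable
   where a residual vanishes, so optimizers stall short of an exact
   solution on clean data. The minimiser therefore runs a smooth
   sum-of-squared-distances pre-stage, then polishes the target objective
   (Nelder-Mead followed by BFGS; deterministic).
2. *Piecewise smoothness from the constraint.* Records switch
   reconstruction branches ($\beta = 0$ or $\alpha = 0$) as parameters
   move. Derivative-based quantities freeze each record's active branch at
   the optimum (the standard active-set treatment).

Parameter covariance is estimated by the M-estimator sandwich
$H^{-1} B H^{-1}$ with the Hessian measured at sampling-scale steps
(small-step curvature of a sum of norms is dominated by near-interpolated
records and is not the population curvature — the same phenomenon Powell's
smoothed estimator addresses for least absolute deviations). This is fast
but approximate; `se = "bootstrap"` provides the distribution-free pairs
bootstrap, which matches across-replicate scatter well in our simulations,
at ~25× the cost. Simulation studies in the test suite therefore judge
parameter recovery against the across-replicate sampling SD, the standard
convention for recovery checks.

## Model selection

`function_grid_search()` scores all 7 × 7 combinations of candidate
LET-function families for the correlation slope (exponential decay, with
offset, Gaussian, linear-times-exponential, log-times-exponential,
inverse-gamma, Poisson-like) and intercept (constant, linear, affine,
quadratic, exponential with/without offset, exponential-plus-linear) by
fitting each endpoint law under a relative squared-error objective and
comparing BIC. The BIC convention is the Gaussian-residual form
$n\ln(Q/n) + k\ln n$ with $n$ the number of survival curves and $k$ the
total free parameters; only differences matter for ranking, and the ranking
is invariant under uniform dose rescaling because the objective is
scale-free. Multi-modal families are fit from a fixed, seeded list of
multi-starts with a screening pass (brief runs of every start, full
polishing of the two best); families that nest a simpler one also start
from the nested solution padded with zeros, which guarantees objective
monotonicity under nesting. `endpoint_combination_search()` repeats the
exercise at the whole-curve level for every subset of 2–6 endpoints among
$D_{5\%} \dots D_{50\%}, SF_{2Gy}$, with the summed normalised curve
distance as the objective; on LQ-consistent data the two-endpoint models
win the BIC comparison, which is the pattern behind the shipped
two-endpoint design. The $SF_{2Gy}$ endpoint applies the same affine law to
survival fractions directly; it is supported in the search but never part
of the shipped model (its predictions are markedly less reliable, and
predicted fractions must be clamped to $(0,1)$).

## Comparison models

`benchmark_spec()` provides the Wedenberg ($RBE_{max} = 1 + q L /
(\alpha/\beta)_x$, $q = 0.434$; $RBE_{min} = 1$) and McNamara
($RBE_{max} = p_0 + p_1 L/(\alpha/\beta)_x$, $RBE_{min} = p_2 + p_3
\sqrt{(\alpha/\beta)_x}\,L$, published coefficients) forms, plus a
Mairani-style nonlinear-in-LET form
$RBE_{max} = 1 + (k_0 + k_1/(\alpha/\beta)_x)\,L\,e^{-k_2 L}$,
$RBE_{min} = 1 + k_3 L$ whose default coefficients are nominal seeds: that
family is meant to be retrained on the user's dataset
(`retrain_benchmark()`), as all comparison models are before any
goodness-of-fit claim. All three need $\beta_x > 0$. `compare_models()`
retrains every requested model on the same data under both objectives and
tabulates $\chi^2/\nu$ (RBE at 2 Gy; $\sigma_i$ from the record's
covariance when present, else a global 10% relative sigma — a documented
convention, since none is standard) and BIC under each objective, with
optional LET-range restriction.

## Validation machinery

`loocv()` holds out one cell-line/LET pair at a time (the unit of
analysis), refits on the remainder warm-started from the full-data fit, and
records percent deviations of predicted from measured RBE at 0.5, 1, 2 and
5 Gy. `bootstrap_intervals()` turns pooled deviations into asymmetric
central prediction intervals by the percentile bootstrap (default 10,000
resamples, seed mandatory); `accuracy_by_dose_level()` tabulates them per
dose level and flags the interval-width-versus-dose pattern (higher dose
levels are predicted more tightly, because a fixed endpoint-dose error is a
smaller relative error at higher dose).

## The synthetic generator

`simulate_survival_data()` emulates the statistical structure the model
assumes: photon curves drawn from log-normal distributions of $D_{37\%}$
(median 2.5 Gy, log-SD 0.35 — the centre of compiled photon
radiosensitivity) and $\alpha/\beta$ (median 8 Gy, log-SD 0.6, spanning
~2.5–25 Gy); LET either on the in-house grid {1.2, 2.6, 9.9} keV/µm or
log-uniform over [0.5, 37.8] (compiled proton survival data are dominated
by low-LET clinical beams; the 37.8 keV/µm ceiling is the inclusion limit);
proton endpoints from the true slope/intercept laws with multiplicative
log-normal noise (CV 10%, the scale of deviations seen in such
compilations); proton $(\alpha, \beta)$ via the two-point reconstruction.
Draws whose records would fail a quality filter (inverted or
$\beta_p \le 0$ endpoint ratios, iso-survival doses beyond 40 Gy) are
redrawn and counted, so clean generated data pass the filters by
construction; deliberate rule violations can be appended via the
`contamination` argument. Everything is deterministic per seed.

What the generator does *not* emulate: heteroscedastic and per-source
measurement error, correlated errors within publication or cell line,
non-LQ survival shapes, and LET-dependent noise. Passing recovery tests on
this generator therefore demonstrates the estimator's correctness under the
model's own assumptions, not robustness to the full messiness of compiled
literature data. One intrinsic feature the simulations do expose: because
records whose measured $\beta_p$ would be non-positive are excluded (in
real pipelines as in the generator), the retained sample is selectively
truncated at high LET and high $\alpha/\beta$, which leaves a small
downward bias (order one sampling SE at $n = 397$) in the slope amplitudes
even when the model is exactly true. This is a property of the
measurement-and-filtering process, not of the optimizer.

## Problem sizes and reproducibility

The simulation-based tests use the training-scale size $n = 397$ for
parameter recovery (100 replicates) and family selection (50 replicates),
smaller sizes (12–300) for interface and bookkeeping checks, and
`scripts/acceptance.R` regenerates a full $n = 397$ study — fit, LOOCV with
bootstrap intervals, model comparison, selection grid, and a synthetic
spread-out-Bragg-peak RBE-weighted dose map — from a single seed. All
randomness flows through explicit seeds; grid searches are reproducible
bit-for-bit.

## Known limitations

* The shipped parameters apply to protons; extension to other ions would
  need retraining and possibly a different beam-quality specifier.
* Photon $(\alpha_x, \beta_x)$ for the tissue of interest is a required
  input; no per-tissue defaults are asserted for voxel maps.
* The 2-D grid format is plain delimited text; 3-D arrays are supported
  in memory through the identical voxel-wise path (no DICOM).
* Per-fit analytic standard errors for the `l2` objective are approximate
  (see above); use the bootstrap when they matter.
* The comparison-model coefficients labelled nominal (Mairani-style) are
  optimizer seeds, not published values; retrain before quoting.
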