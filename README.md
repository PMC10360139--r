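# rbekit

Empirical modelling of proton relative biological effectiveness (RBE) from
photon radiosensitivity.

## The problem

Proton therapy plans still assume a fixed RBE of 1.1, although the
biological effectiveness of protons is known to rise with the beam's
dose-weighted linear energy transfer (LET_d), most sharply at the distal
edge of the field. Empirical RBE models predict a cell line's proton
survival curve from its photon linear-quadratic (LQ) parameters
(SF(D) = exp(−αD − βD²)) and LET_d, but models built on the LET trends of
α and β inherit the large noise of those fit parameters.

`rbekit` implements an alternative: iso-survival doses (D₁₀%, D₃₇%, ...)
are *linearly correlated* between photons and protons,

    D_SF,proton = slope(LET) · D_SF,x-ray + intercept(LET),
    slope(LET) = c·e^(−f·LET),   intercept(LET) = p·LET,

and these endpoints are far better determined than α or β because the
negative α–β fit covariance cancels in their error propagation. Two
survival levels (e⁻¹ and e⁻³) with one (c, f, p) triple each give a
six-parameter model from which the proton (α_p, β_p) follows in closed
form, and hence RBE at any dose or survival level, including the
characteristic sub-unity RBE this formalism predicts for extremely
radiosensitive cells:

    RBE_SF = 1 / (c·e^(−f·LET) + p·LET / D_SF,x-ray)

The package is aimed at radiobiology and medical-physics researchers who
work with paired clonogenic-survival compilations (PIDE-style tables) and
at treatment-plan evaluation with precomputed dose/LET_d grids.

## What is in the package

* LQ survival-curve mathematics with closed-form survival integrals and
  delta-method error propagation (`lq()`, `dose_for_sf()`,
  `mean_inactivation_dose()`, `curve_l2_distance()`,
  `propagate_endpoint_error()`, `fit_lq()`)
* PIDE-style CSV ingestion, the training-data quality filters, and
  photon–proton endpoint correlations (`read_survival_table()`,
  `apply_exclusion_filters()`, `correlation_by_let()`)
* The six-parameter model with shipped fitted parameters and covariance
  (`flint_default_model()`, `predict_proton_curve()`, `predict_rbe()`,
  `prediction_uncertainty()`) and the model fitter (`rbe_fit()`, an S3
  modelling interface with `coef`/`summary`/`predict`/`residuals`/
  `simulate`/`plot` methods)
* BIC-based selection among candidate LET functions and endpoint subsets
  (`function_grid_search()`, `endpoint_combination_search()`)
* Retrainable Wedenberg / McNamara / Mairani-style comparison models and
  goodness-of-fit tables (`benchmark_spec()`, `retrain_benchmark()`,
  `compare_models()`)
* Leave-one-out cross-validation with bootstrap prediction intervals
  (`loocv()`, `bootstrap_intervals()`, `accuracy_by_dose_level()`)
* A synthetic paired-survival generator for tests and power studies
  (`synth_config()`, `simulate_survival_data()`)
* Voxel-wise RBE-weighted dose and model-difference maps on co-registered
  dose/LET grids (`rbe_weighted_dose()`, `model_difference_map()`)
* A thin command-line wrapper (`inst/exec/rbekit`) over the same functions

## Worked example

Predict the proton response of a tissue with photon parameters
α = 0.35 /Gy, β = 0.035 /Gy² (α/β = 10 Gy) in a 9.9 keV/µm proton beam:

```r
library(rbekit)
ph <- lq(0.35, 0.035)
predict_proton_curve(ph, let = 9.9)
#> LQ curve: alpha = 0.54431 /Gy, beta = 0.0153371 /Gy^2

rbe <- predict_rbe(ph, let = 9.9, dose = 2)
u   <- prediction_uncertainty(ph, let = 9.9, dose = 2)
sprintf("RBE at 2 Gy: %.4f +/- %.4f (95%% CI %.3f-%.3f)",
        rbe, u$stderr, rbe - 1.96 * u$stderr, rbe + 1.96 * u$stderr)
#> "RBE at 2 Gy: 1.3032 +/- 0.0258 (95% CI 1.253-1.354)"
```

The proton curve steepens (α almost 0.55 /Gy versus 0.35 /Gy for photons)
and the predicted RBE at a 2 Gy fraction is about 1.30 — well above the
clinical 1.1 — with a 95% confidence band from the shipped parameter
covariance propagated through the prediction.

Refit the model to a (here, synthetic) paired survival table:

```r
d <- simulate_survival_data(synth_config(n = 100, seed = 42))
rbe_fit(d, se = "none")
#> Proton RBE model fit (2 endpoints, linear intercept, objective = l2)
#>       c1       f1       p1       c2       f2       p2
#> 1.060082 0.048457 0.018947 1.054379 0.052869 0.094311
#> n = 100 curves, k = 6 parameters, objective = 3.70508, BIC = -301.92
```

The fitted slope amplitudes sit near 1 (protons resemble photons at zero
LET) and the decay/intercept rates recover the generator's ground truth to
within sampling noise at n = 100.

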