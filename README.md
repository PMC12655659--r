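# radpk

Population pharmacokinetic modelling and simulation of **radotinib**, an oral
BCR-ABL1 tyrosine kinase inhibitor used in chronic-phase chronic myeloid
leukemia (CML-CP). The package implements, as reusable tidyverse-style R
machinery, the published population model for radotinib together with the
estimation, covariate-selection and diagnostic methods used to build such
models — so that the model can be simulated, refitted on synthetic or new
data, and stress-tested without access to the original trial data.

## The model

A two-compartment disposition model with first-order elimination, oral
absorption through a transit-compartment chain, and a circadian modulation of
clearance. For individual *i* at time *t* (hours since first dose):

    CL/F_i = 23.0 · [1 + 0.646·(1 − CML_i)] · [1 + 0.683·cos(2π(t − 7)/24)] · e^η_i
    Vc/F_i = 383 · [1 − 0.0129·(AGE_i − 31)] · e^η_IOV
    Q/F    = 132        Vp/F_i = 519 · e^η_IOV
    ka     = 1.59 h⁻¹   MTT_i  = 1.88 · e^η_i h     N_i = 6.58 · e^η_i

with transit-chain input rate `F·D·ktr·(ktr·t)^N·e^(−ktr·t)/Γ(N+1)`,
`ktr = (N+1)/MTT`; log-normal interindividual variability on CL/F (SD 0.389)
and on MTT and N (fixed SDs 0.316, 0.447); interoccasion variability
(SD 0.698) shared by the two volumes; proportional residual error (20% CV).
CML = 1 marks a patient, 0 a healthy volunteer: patients clear 39.2% slower
(23.0 vs 37.9 L/h), giving terminal half-lives of 28.8 h vs 18.2 h.

What the package provides, module by module:

* **Event tables** — NONMEM-dialect CSV input/output (`read_event_table()`,
  `write_event_table()`), validation, 5 ng/mL below-quantification policies,
  dosing regimens.
* **Structural model** — covariate algebra (`typical_params()`,
  `secondary_params()`, `circadian_factor()`, `transit_input_rate()`), a
  compiled adaptive Runge-Kutta integrator, and a pure-R right-hand side
  (`ode_rhs()`) for independent cross-checks.
* **Random effects** — `draw_etas()`, `realize_individual()`,
  `apply_residual_error()`, `eta_log_density()`.
* **Simulation** — `simulate_profile()`, `steady_state_window()`,
  `exposure_metrics()`, `monte_carlo_exposures()`, `sweep_dose_clock()`.
* **Estimation** — FOCE with interaction (`fit_foce()`, `foce_objective()`,
  `inner_ebe()`), conditional weighted residuals (`cwres()`, `gof_table()`),
  broom-style `tidy()`/`glance()` methods.
* **Covariate modelling** — stepwise forward/backward search (`scm()`) with
  the ΔOFV 3.84 / 6.63 thresholds, `covariate_function()`,
  `derive_covariates()` (Mosteller BSA, Cockcroft-Gault).
* **Diagnostics** — visual predictive checks (`vpc()`), cohort-stratified
  nonparametric bootstrap (`bootstrap_fit()`), `autoplot()` methods.
* **Synthetic studies** — `generate_study()` reproduces the two-cohort design
  (23 healthy volunteers, single 400 mg dose; 24 patients, 300 mg twice
  daily, Days 1 and 14) with matching covariate distributions, so every other
  module is testable without any download.

## Worked example

```r
library(radpk)

theta <- radotinib_theta()       # packaged final-model estimates
variance <- radotinib_variance()

# typical patient vs healthy volunteer
pat <- typical_params(data.frame(age = 31, cml = 1), theta)
hv  <- typical_params(data.frame(age = 31, cml = 0), theta)
secondary_params(dplyr::bind_rows(pat, hv))[, c("t_half_beta", "v_total")]
#> # A tibble: 2 × 2
#>   t_half_beta v_total
#>         <dbl>   <dbl>
#> 1        28.8     902
#> 2        18.2     902

# steady-state exposures in 500 virtual CML-CP patients, 300 mg twice daily
mc <- monte_carlo_exposures(theta, variance, dose_mg = 300, interval_h = 12,
                            n_subjects = 500, seed = 1)
tidy(mc)
#> # A tibble: 4 × 8
#>   regimen     metric     median      q25      q75      p05     p95     n
#>   <chr>       <chr>       <dbl>    <dbl>    <dbl>    <dbl>   <dbl> <int>
#> 1 300 mg q12h auc_0_24 26473.   20385.   34547.   13897.   50783.    500
#> 2 300 mg q12h cmax      1408.    1110.    1763.     804.    2411.    500
#> 3 300 mg q12h ctrough   1043.     784.    1397.     506.    2057.    500
#> 4 300 mg q12h tmax         3.25     2.75     3.75     2.25     4.5   500
```

The medians say: a typical virtual patient on the approved regimen sees a
daily exposure around 26,500 ng·h/mL with peaks near 1400 ng/mL and troughs
near 1000 ng/mL; the interquartile spread (roughly ±25%) is driven by the
clearance variability (SD 0.389 on the log scale). Re-running the same
population on 400 mg once daily drops the median daily AUC by 39% — the
pharmacokinetic case explored for once-daily dosing.

A synthetic study can be generated and refitted end to end:

```r
tab <- generate_study(theta, variance, seed = 7)   # 47 subjects, NONMEM dialect
fit <- fit_foce(tab, theta, variance, free = c("cl_pop", "omega_cl"))
glance(fit)
cwres(tab, fit)
```

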