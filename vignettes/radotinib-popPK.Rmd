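---
title: "Population pharmacokinetics of radotinib: model, simulation and estimation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of radotinib: model, simulation and estimation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpk)
```

## The model

Radotinib is an oral BCR-ABL1 tyrosine kinase inhibitor used in chronic-phase
chronic myeloid leukemia (CML-CP). Its plasma pharmacokinetics in healthy
volunteers (a single 400 mg dose) and CML-CP patients (300 mg every 12 h) are
described by a two-compartment disposition model with first-order elimination,
oral input through a chain of transit compartments, and a circadian (cosine)
modulation of apparent clearance:

* **Absorption.** A dose `D` enters the absorption depot at the analytic
  transit-chain rate `f·D·ktr·(ktr·t)^N·exp(-ktr·t)/Γ(N+1)` with
  `ktr = (N+1)/MTT`, and moves into the central compartment at the first-order
  rate `ka`. `N` is continuous (the gamma function interpolates non-integer
  chain lengths), which is exactly how the reported estimate `N = 6.58` must
  be read.
* **Disposition.** Central volume `Vc/F`, peripheral volume `Vp/F`,
  intercompartmental clearance `Q/F`, elimination clearance `CL/F` — all
  apparent (bioavailability-confounded) oral quantities, so `F` is fixed at 1.
* **Circadian elimination.** The elimination clearance is multiplied by
  `1 + A·cos(2π(t − t_peak)/24)` with amplitude `A = 0.683` and acrophase
  `t_peak = 7` h. `t` is *time since the subject's first dose* (the event
  table's TIME axis), not clock time: the model carries no information about
  when in the day the first dose was taken. The factor averages exactly to 1
  over any 24 h window, so secondary parameters that depend on a mean
  clearance (half-lives, AUC identities) use `CL/F` as-is.
* **Covariates.** Disease status enters clearance as
  `CL/F = 23.0·[1 + 0.646·(1 − CML)]` (CML = 0 for healthy volunteers: they
  clear 39.2% faster, 37.9 vs 23.0 L/h), and age enters the central volume
  linearly, `Vc/F = 383·[1 − 0.0129·(AGE − 31)]`, centred at the study median
  age of 31 years.

The default parameter profile is packaged:

```{r}
radotinib_theta()
radotinib_variance()
```

Random effects are log-normal: interindividual variability (IIV) on `CL/F`
(SD 0.389, estimated) and on `MTT` and `N` (SDs 0.316 and 0.447, fixed — note
0.316² ≈ 0.1 and 0.447² ≈ 0.2, the fixed variances), interoccasion
variability (IOV, SD 0.698) applied per subject-occasion *jointly* to `Vc/F`
and `Vp/F` (one draw shared by both volumes; an option allows independent
draws), and a proportional residual error with 20% CV. Occasions are
pharmacokinetic states: Day 1 of patient dosing is occasion 1 (non-steady
state), Day 14 is occasion 2 (steady state).

Typical-value algebra is exposed directly:

```{r}
pat <- typical_params(data.frame(age = 31, cml = 1), radotinib_theta())
secondary_params(pat)[, c("t_half_beta", "v_total")]
```

which reproduces the reported terminal half-life of 28.8 h for patients
(18.2 h for healthy volunteers via the disease-adjusted clearance) and the
total apparent volume of 902 L.

## Numerical engine

The differential equations are integrated by a compiled adaptive
Dormand-Prince 5(4) method with error control per step
(`rtol` 1e-8 for reported simulations; the estimation path uses 1e-5 by
default, which leaves concentration errors around 1e-6 relative — far below
the 20% residual error — while roughly doubling throughput). The integrator
restarts at every dose time and occasion boundary so right-hand-side kinks
never sit inside a step, carries its adapted step size across restarts, and
skips transit-input contributions from doses whose rate has decayed below
`exp(-40)` of scale. A pure-R right-hand side (`ode_rhs()`) defines the same
equations for independent cross-checks against `deSolve`; the test suite
holds the two routes together at 1e-6 relative, along with closed-form
oracles (biexponential disposition, transit-input mass conservation,
one-compartment steady-state superposition).

Degenerate inputs are handled explicitly: `q = 0` disconnects the peripheral
compartment and the half-life machinery switches to the mono-exponential
limit; a circadian amplitude of magnitude 1 or more is rejected at
construction (clearance could become non-positive); predictions entering the
proportional error variance are floored at 1 ng/mL, a fifth of the
quantification limit. The floor matters: under a pure proportional model the
residual variance vanishes with the prediction, so an early sample taken on
the steep transit-chain upswing — where the typical prediction is a fraction
of a ng/mL — would otherwise dominate the whole subject's likelihood and drag
the empirical Bayes etas to implausible corners.

## Steady-state exposure simulation

`steady_state_window()` simulates 14 days of dosing (more than ten terminal
half-lives for a typical patient) and returns the final 24 h window on a
0.25 h grid. Steady-state attainment is verified by comparing the pre-dose
troughs that open and close the final window; individuals still drifting by
more than 0.5% (slow-clearance tail of the IIV distribution) are extended in
7-day blocks. AUC(0-24h) uses the trapezoid on the grid; Cmax/tmax are the
grid maximum (grid-refinement invariance is tested at 0.5%); Ctrough is the
concentration immediately before the next dose.

`monte_carlo_exposures()` draws virtual CML-CP patients with the cohort's
baseline covariate distribution, applies IIV plus a single
steady-state-occasion IOV draw, and summarizes noise-free exposure metrics as
medians with interquartile ranges and 90% prediction intervals. Residual
(assay) error is excluded from exposure metrics: it describes measurement,
not exposure, and including it would mainly inflate grid maxima. The
headline population size is n = 2400 virtual patients per regimen.

Two choices here are genuinely open and are worth stating plainly:

* **Dose-clock alignment.** Because the circadian phase is anchored to time
  since first dose, the alignment of doses with the circadian peak is a free
  design choice. The default places doses at TIME ≡ 0 (and 12 for twice-daily
  regimens) modulo 24. `sweep_dose_clock()` re-runs the simulation over a
  grid of offsets with the same virtual population so the sensitivity of
  every exposure metric to this alignment can be inspected. Twice-daily AUC
  turns out to be almost alignment-invariant, while once-daily AUC moves by
  roughly ±9% across offsets; troughs move in the 10-20% range for both
  regimens.
* **IOV at steady state.** Virtual patients receive one IOV draw (a
  Day-14-like single occasion) rather than fresh draws per day.

## Estimation

`fit_foce()` implements first-order conditional estimation with interaction
as a per-subject Laplace-type approximation: for each subject the empirical
Bayes eta mode minimizes the conditional objective (extended least squares
with the proportional error variance evaluated at the *individual*
prediction, plus the eta prior), and the marginal contribution adds the
log-determinant of the Gauss-Newton curvature at the mode. The additive
`n·log(2π)` constant is omitted, following the usual OFV convention. The
inner problem is solved by a damped Gauss-Newton iteration with the exact
gradient of the interaction objective (given a central finite-difference
Jacobian with step 1e-4 on the eta scale), warm-started between outer
iterations; etas are boxed at ±6 prior SDs, which keeps line searches away
from parameter regions that would make the system needlessly stiff. Outer
optimization runs Nelder-Mead on transformed parameters
(log scale for positivity-constrained quantities, natural scale for covariate
slopes), and relative standard errors come from the inverse finite-difference
Hessian of the objective.

The approximation is validated against an adaptive-quadrature evaluation of
the exact marginal likelihood on one-eta problems (within 2% of the OFV), a
brute-force grid search for the eta mode, and closed-form reductions
(zero-variance extended least squares). Conditional weighted residuals
decorrelate each subject's residual vector with the model-implied covariance
`JΩJ' + diag(σ²·IPRED²)` at the eta mode and are calibrated on self-simulated
data (mean ≈ 0, SD ≈ 1).

**Parameter-recovery experiment.** Ten synthetic replicates of the two-cohort
design are generated with IIV on clearance only (SD 0.389) plus the 20%
proportional error, and refitted from 20%-perturbed starting values with
`cl_pop`, `theta_disease` and `omega_cl` free (the residual SD is held at its
generating value; the structural absorption/distribution constants, whose
variances the published model fixes at zero anyway, are likewise held).
Median bias for the clearance parameters stays within 15%. Restricting the
variance structure keeps each replicate's inner problem one-dimensional,
which is what makes a ten-replicate experiment routine on a single CPU; it is
an experiment design, not a claim that the full hierarchy is estimable from
47 subjects — the published analysis itself fixed most variance components.

**Stepwise covariate modelling.** `scm()` runs greedy forward addition
(largest ΔOFV first, include above 3.84) followed by backward elimination
(retain only effects whose removal raises the OFV by more than 6.63), with a
|r| > 0.9 collinearity guard and per-candidate failure isolation. Power and
type-I behaviour are exercised on synthetic replicates: with the disease
effect (0.646) in the generating model the disease-on-clearance candidate is
selected; with no covariate effects, retention through the stricter backward
threshold is rare. Continuous candidates are centred at the dataset median.

## The synthetic-data generator

`generate_study()` emulates the two-cohort design exactly: 23 healthy
volunteers, single 400 mg dose, sampling pre-dose and at 0.5-48 h (15
samples); 24 patients, 300 mg every 12 h, sampled pre-dose and to 12 h
post-dose on Days 1 and 14 (8 samples per day), with independent IOV draws
per occasion and the volume parameters switching at the Day-14 pre-dose
time. Pre-dose Day-1 samples are generated as true zeros and come out flagged
below the 5 ng/mL quantification limit; the default BLQ policy discards
(flags missing) below-limit observations, which never touches dose records.

Covariate distributions emulate the published cohort demographics: healthy
volunteers all male, ages uniform over 20-51; patients 54% male with a
truncated log-normal age distribution (median ≈ 32, range 21-72); weights,
heights and laboratory values from truncated log-normal distributions
spanning the observed ranges; creatinine clearance is drawn directly within
its observed range because no serum creatinine summary exists to derive it
from. These are emulations of summary statistics, not inferences about the
real joint distribution — the generator reproduces the design and the model's
stochastic structure, so passing tests validate the machinery, not the
biology of any real dataset (no dropout patterns, no concomitant-medication
structure, no assay batch effects).

## Known limitations

* The dose-clock alignment discussed above is the single largest free choice
  affecting steady-state exposure summaries; published exposure tables from
  any NONMEM-based simulation may sit anywhere inside (or, for
  alignment-insensitive metrics, slightly outside) the swept envelope,
  because the steady-state implementation details of that environment are not
  observable from its outputs.
* The real study data are not available, so the original objective function
  value and the real-data covariate ΔOFVs and bootstrap intervals are not
  reproducible targets; estimation is validated by oracle equivalence and
  synthetic recovery instead.
* No M3-type likelihood handling of below-limit observations (discard or
  half-limit imputation only), no infusion records, no saturable
  elimination, no food effects.
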