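#' Covariate-adjusted typical parameters
#'
#' Evaluates the deterministic covariate model at each row of `data`:
#' apparent clearance `cl = cl_pop * (1 + theta_disease * (1 - cml))`
#' (the circadian factor is *not* applied here; it multiplies clearance inside
#' the differential equations at run time) and central volume
#' `vc = vc_pop * (1 + theta_age * (age - age_ref))`. The remaining structural
#' parameters are copied from `theta`. Additional covariate effects found by
#' stepwise covariate modelling can be supplied via `extra_effects`.
#'
#' @param data A data frame with one row per individual carrying at least
#'   `age` and `cml` (case-insensitive; the NONMEM-style `AGE`/`CML` columns
#'   of an [event_table()] work directly).
#' @param theta A [theta_set()].
#' @param extra_effects Optional list of covariate effects as produced by
#'   [covariate_candidate()] together with a `theta` value each; every effect
#'   multiplies its target parameter through [covariate_function()].
#' @return A tibble with one row per input row and columns `cl` (pre-circadian
#'   L/h), `vc`, `q` (L/h), `vp` (L), `ka` (1/h), `mtt` (h), `n_transit`, `f`,
#'   plus `ID` if present in `data`.
#' @examples
#' typical_params(data.frame(age = 31, cml = 1), radotinib_theta())
#' @export
typical_params <- function(data, theta, extra_effects = NULL) {
  stopifnot(inherits(theta, "theta_set"))
  data <- as_tibble(data)
  lookup <- setNames(names(data), tolower(names(data)))
  need <- function(nm) {
    if (!nm %in% names(lookup)) abort(sprintf("`data` must contain a `%s` column.", nm))
    data[[lookup[[nm]]]]
  }
  age <- need("age")
  cml <- need("cml")
  if (any(!cml %in% c(0, 1))) abort("`cml` must be 0 (healthy volunteer) or 1 (patient).")
  if (any(!is.finite(age) | age <= 0)) abort("`age` must be positive.")

  cl <- theta$cl_pop * (1 + theta$theta_disease * (1 - cml))
  vc <- theta$vc_pop * (1 + theta$theta_age * (age - theta$age_ref))
  out <- tibble(
    cl = cl, vc = vc, q = theta$q_pop, vp = theta$vp_pop, ka = theta$ka,
    mtt = theta$mtt, n_transit = theta$n_transit, f = theta$bioavailability_f
  )

  for (ef in extra_effects) {
    x <- need(tolower(ef$covariate))
    mult <- covariate_function(ef$form, ef$theta, x, ef$center)
    if (ef$form == "additive") {
      out[[ef$parameter]] <- out[[ef$parameter]] + mult
    } else {
      out[[ef$parameter]] <- out[[ef$parameter]] * mult
    }
  }

  if (any(out$vc <= 0)) {
    abort("Central volume is non-positive for at least one individual: age outside the support of the linear age model.")
  }
  if (any(out$cl <= 0)) abort("Clearance is non-positive for at least one individual.")
  if ("ID" %in% names(data)) out <- dplyr::bind_cols(tibble(ID = data$ID), out)
  out
}

#' Circadian clearance multiplier
#'
#' `1 + amplitude * cos(2*pi*(t - acrophase)/period)`: a dimensionless
#' multiplier on apparent clearance, maximal `1 + amplitude` at the acrophase
#' and averaging exactly 1 over any full period. `t` is hours since the
#' subject's first dose (the event-table TIME axis), not clock time.
#'
#' @param t Time(s) in hours since first dose.
#' @param theta A [theta_set()].
#' @return Numeric vector of multipliers, strictly positive while
#'   `|theta_circadian| < 1`.
#' @examples
#' circadian_factor(7, radotinib_theta())   # peak: 1.683
#' circadian_factor(19, radotinib_theta())  # trough: 0.317
#' @export
circadian_factor <- function(t, theta) {
  stopifnot(inherits(theta, "theta_set"))
  1 + theta$theta_circadian *
    cos(2 * pi * (t - theta$circadian_acrophase) / theta$circadian_period)
}

#' Transit-chain absorption input rate
#'
#' Analytic input rate of the transit-compartment absorption model with a
#' continuous number of compartments:
#' `rate(t) = f * dose * ktr * (ktr t)^n * exp(-ktr t) / Gamma(n + 1)` with
#' `ktr = (n_transit + 1) / mtt` (the chain step feeding the absorption depot
#' is counted in the mean transit time). The rate integrates to `f * dose`
#' over `[0, Inf)`.
#'
#' @param t_since_dose Hours since the dose was administered (>= 0).
#' @param dose_mg Dose amount (mg).
#' @param params A one-row data frame or named list with `mtt`, `n_transit`
#'   and `f` (e.g. a row of [typical_params()]).
#' @return Input rate(s) into the absorption depot, mg/h.
#' @examples
#' p <- list(mtt = 1, n_transit = 1, f = 1)
#' transit_input_rate(0.5, 100, p)  # 100 * 2 * 1 * exp(-1)
#' @export
transit_input_rate <- function(t_since_dose, dose_mg, params) {
  mtt <- params$mtt
  n <- params$n_transit
  f <- if (is.null(params$f)) 1 else params$f
  if (!is.finite(mtt) || mtt <= 0) abort("`mtt` must be positive.")
  if (any(t_since_dose < 0)) abort("`t_since_dose` must be >= 0.")
  ktr <- (n + 1) / mtt
  lr <- log(f * dose_mg * ktr) + n * log(ktr * t_since_dose) -
    ktr * t_since_dose - lgamma(n + 1)
  rate <- exp(lr)
  rate[t_since_dose == 0] <- if (n > 0) 0 else f * dose_mg * ktr
  rate
}

#' Structural-model right-hand side (reference implementation)
#'
#' Derivatives of the amounts (mg) in the absorption depot, central and
#' peripheral compartments (plus cumulative eliminated mass), given a dose
#' history feeding the analytic transit-chain input. This pure-R form defines
#' the model; simulation uses a compiled adaptive Runge-Kutta integrator of
#' the same equations ([simulate_profile()]), and this function plugs directly
#' into `deSolve::ode()` for independent cross-checks.
#'
#' @param t Time (h since first dose).
#' @param state Numeric vector `(a_abs, a_central, a_peripheral, a_eliminated)`
#'   in mg (the fourth element optional).
#' @param params One-row data frame or list of individual parameters
#'   (`cl`, `vc`, `q`, `vp`, `ka`, `mtt`, `n_transit`, `f`).
#' @param theta A [theta_set()] (for the circadian term).
#' @param dose_history Data frame with columns `time` and `amount`
#'   (e.g. from [expand_regimen()]); only doses at times `< t` contribute.
#' @return List of one numeric vector of derivatives, `deSolve`-style.
#' @export
ode_rhs <- function(t, state, params, theta, dose_history) {
  active <- dose_history$time < t
  rate <- 0
  if (any(active)) {
    rate <- sum(transit_input_rate(t - dose_history$time[active],
                                   dose_history$amount[active], params))
  }
  clt <- params$cl * circadian_factor(t, theta)
  da <- rate - params$ka * state[1]
  dc <- params$ka * state[1] -
    (clt / params$vc + params$q / params$vc) * state[2] +
    (params$q / params$vp) * state[3]
  dp <- (params$q / params$vc) * state[2] - (params$q / params$vp) * state[3]
  de <- (clt / params$vc) * state[2]
  if (length(state) >= 4) list(c(da, dc, dp, de)) else list(c(da, dc, dp))
}

#' Secondary disposition parameters
#'
#' Micro rate constants, disposition eigenvalues and terminal half-life of the
#' two-compartment model, computed from the circadian-mean clearance (the
#' cosine averages to 1 over a period, so `cl` enters as-is):
#' `k10 = cl/vc`, `k12 = q/vc`, `k21 = q/vp`; `alpha` and `beta` are the
#' roots of `s^2 - (k10+k12+k21) s + k10 k21`.
#'
#' @param params Data frame with columns `cl`, `vc`, `q`, `vp` (one row per
#'   individual, e.g. from [typical_params()]).
#' @return A tibble with `k10`, `k12`, `k21`, `alpha`, `beta`,
#'   `t_half_alpha`, `t_half_beta` (h) and `v_total = vc + vp` (L).
#' @examples
#' secondary_params(typical_params(data.frame(age = 31, cml = 1),
#'                                 radotinib_theta()))
#' @export
secondary_params <- function(params) {
  params <- as_tibble(params)
  stopifnot(all(c("cl", "vc", "q", "vp") %in% names(params)))
  k10 <- params$cl / params$vc
  k12 <- params$q / params$vc
  k21 <- params$q / params$vp
  s <- k10 + k12 + k21
  disc <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  # q = 0 disconnects the peripheral compartment: elimination is
  # mono-exponential with rate k10
  mono <- k21 == 0
  alpha[mono] <- k10[mono]
  beta[mono] <- k10[mono]
  tibble(
    k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta,
    t_half_alpha = log(2) / alpha, t_half_beta = log(2) / beta,
    v_total = params$vc + params$vp
  )
}
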