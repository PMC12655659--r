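#' Fixed-effect parameter set for the radotinib structural model
#'
#' A `theta_set` collects every fixed-effect constant of the structural model:
#' population apparent clearance and its disease and circadian modifiers,
#' central volume and its age slope, intercompartmental clearance, peripheral
#' volume, first-order absorption rate constant, and the transit-chain
#' absorption parameters (mean transit time and number of transit
#' compartments). All parameters are apparent (oral, bioavailability
#' confounded) quantities.
#'
#' The typical clearance of an individual is
#' `cl_pop * (1 + theta_disease * (1 - cml))`, further multiplied at run time
#' by the circadian factor `1 + theta_circadian * cos(2*pi*(t - acrophase)/period)`.
#' The typical central volume is `vc_pop * (1 + theta_age * (age - age_ref))`.
#'
#' @param cl_pop Population apparent clearance CL/F for a CML-CP patient (L/h).
#' @param theta_disease Proportional increase in CL/F for a healthy volunteer
#'   relative to a patient (dimensionless).
#' @param theta_circadian Amplitude of the circadian cosine on CL/F; must lie
#'   strictly inside (-1, 1) so clearance stays positive.
#' @param circadian_acrophase Time (h after first dose) at which the circadian
#'   clearance multiplier peaks.
#' @param circadian_period Circadian period (h).
#' @param vc_pop Population apparent central volume Vc/F (L) at the reference age.
#' @param theta_age Linear slope of Vc/F per year of age (negative: smaller
#'   central volume in older individuals).
#' @param age_ref Reference (centering) age in years.
#' @param q_pop Apparent intercompartmental clearance Q/F (L/h).
#' @param vp_pop Apparent peripheral volume Vp/F (L).
#' @param ka First-order absorption rate constant (1/h).
#' @param mtt Mean transit time through the absorption chain (h).
#' @param n_transit Number of transit compartments (continuous, via the gamma
#'   function).
#' @param bioavailability_f Relative bioavailability fraction (fixed at 1 for
#'   an apparent-parameter model).
#'
#' @return An object of class `theta_set` (a named list).
#' @seealso [radotinib_theta()] for the packaged default estimates,
#'   [typical_params()] to apply covariates.
#' @export
theta_set <- function(cl_pop, theta_disease = 0, theta_circadian = 0,
                      circadian_acrophase = 7, circadian_period = 24,
                      vc_pop = 383, theta_age = 0, age_ref = 31,
                      q_pop = 132, vp_pop = 519, ka = 1.59,
                      mtt = 1.88, n_transit = 6.58, bioavailability_f = 1) {
  th <- list(
    cl_pop = cl_pop, theta_disease = theta_disease,
    theta_circadian = theta_circadian,
    circadian_acrophase = circadian_acrophase,
    circadian_period = circadian_period,
    vc_pop = vc_pop, theta_age = theta_age, age_ref = age_ref,
    q_pop = q_pop, vp_pop = vp_pop, ka = ka, mtt = mtt,
    n_transit = n_transit, bioavailability_f = bioavailability_f
  )
  class(th) <- "theta_set"
  validate_theta(th)
  th
}

validate_theta <- function(th) {
  pos <- c("cl_pop", "vc_pop", "q_pop", "vp_pop", "ka", "mtt",
           "circadian_period", "bioavailability_f")
  for (p in pos) {
    if (!is.numeric(th[[p]]) || length(th[[p]]) != 1L || !is.finite(th[[p]]) ||
        th[[p]] <= 0) {
      abort(sprintf("`%s` must be a single positive finite number.", p))
    }
  }
  if (th$n_transit < 0) abort("`n_transit` must be non-negative.")
  if (abs(th$theta_circadian) >= 1) {
    abort("`theta_circadian` must satisfy |amplitude| < 1 so clearance stays positive.")
  }
  invisible(th)
}

#' Packaged final-model estimates for radotinib
#'
#' Returns the fixed-effect estimates of the final radotinib population model:
#' CL/F 23.0 L/h for a typical CML-CP patient with a +0.646 proportional
#' disease effect for healthy volunteers and a 0.683-amplitude circadian
#' cosine peaking 7 h after first dose; Vc/F 383 L at the reference age of
#' 31 years with slope -0.0129/year; Q/F 132 L/h; Vp/F 519 L; ka 1.59 1/h;
#' MTT 1.88 h; N 6.58 transit compartments.
#'
#' @return A [theta_set()].
#' @export
radotinib_theta <- function() {
  theta_set(
    cl_pop = 23.0, theta_disease = 0.646, theta_circadian = 0.683,
    circadian_acrophase = 7, circadian_period = 24,
    vc_pop = 383, theta_age = -0.0129, age_ref = 31,
    q_pop = 132, vp_pop = 519, ka = 1.59, mtt = 1.88, n_transit = 6.58,
    bioavailability_f = 1
  )
}

#' Random-effect and residual-error specification
#'
#' Standard deviations of the log-normal interindividual (IIV) random effects,
#' the log-normal interoccasion (IOV) effect shared by the central and
#' peripheral volumes, and the proportional residual error. A logical
#' `estimated` flag per component records which variances are estimated versus
#' fixed during model fitting.
#'
#' @param omega_cl,omega_vc,omega_q,omega_vp,omega_ka,omega_mtt,omega_n IIV
#'   standard deviations (log scale) for the corresponding structural
#'   parameters.
#' @param omega_iov IOV standard deviation (log scale), applied per
#'   subject-occasion jointly to Vc/F and Vp/F.
#' @param sigma_prop Proportional residual error standard deviation
#'   (0.20 = 20% CV).
#' @param estimated Named logical vector flagging which components are
#'   estimated; the remainder are held fixed by [fit_foce()].
#' @param iov_shared If `TRUE` (default) one IOV draw per subject-occasion is
#'   shared by Vc/F and Vp/F; if `FALSE` they receive independent draws.
#'
#' @return An object of class `variance_spec`.
#' @seealso [radotinib_variance()] for the packaged defaults.
#' @export
variance_spec <- function(omega_cl = 0, omega_vc = 0, omega_q = 0,
                          omega_vp = 0, omega_ka = 0, omega_mtt = 0,
                          omega_n = 0, omega_iov = 0, sigma_prop = 0,
                          estimated = c(omega_cl = TRUE, omega_iov = TRUE,
                                        sigma_prop = TRUE),
                          iov_shared = TRUE) {
  vs <- list(
    omega_cl = omega_cl, omega_vc = omega_vc, omega_q = omega_q,
    omega_vp = omega_vp, omega_ka = omega_ka, omega_mtt = omega_mtt,
    omega_n = omega_n, omega_iov = omega_iov, sigma_prop = sigma_prop,
    estimated = estimated, iov_shared = isTRUE(iov_shared)
  )
  sds <- unlist(vs[omega_names()])
  if (any(!is.finite(sds)) || any(sds < 0)) {
    abort("All variance-component standard deviations must be finite and >= 0.")
  }
  if (sigma_prop < 0) abort("`sigma_prop` must be >= 0.")
  class(vs) <- "variance_spec"
  vs
}

omega_names <- function() {
  c("omega_cl", "omega_vc", "omega_q", "omega_vp", "omega_ka",
    "omega_mtt", "omega_n", "omega_iov", "sigma_prop")
}

#' Packaged final-model variability estimates for radotinib
#'
#' IIV standard deviation 0.389 on CL/F (estimated); IIV on MTT and N fixed at
#' 0.316 and 0.447 (variances 0.1 and 0.2); IIV on Vc/F, Q/F, Vp/F and ka
#' fixed at 0; IOV standard deviation 0.698 on the volumes (estimated);
#' proportional residual error 20%.
#'
#' @return A [variance_spec()].
#' @export
radotinib_variance <- function() {
  variance_spec(
    omega_cl = 0.389, omega_mtt = 0.316, omega_n = 0.447,
    omega_iov = 0.698, sigma_prop = 0.20
  )
}

#' @export
print.theta_set <- function(x, ...) {
  cat("<theta_set>\n")
  v <- unlist(x)
  for (nm in names(v)) cat(sprintf("  %-20s %s\n", nm, format(v[[nm]])))
  invisible(x)
}

#' @export
print.variance_spec <- function(x, ...) {
  cat("<variance_spec>  (standard deviations)\n")
  for (nm in omega_names()) {
    est <- isTRUE(x$estimated[[nm]])
    cat(sprintf("  %-10s %-8s %s\n", nm, format(x[[nm]]),
                if (est) "estimated" else "fixed"))
  }
  invisible(x)
}

#' Write or read a model profile as YAML
#'
#' Serializes a fixed-effect [theta_set()] and a [variance_spec()] to a single
#' YAML profile file, and reads such a profile back.
#'
#' @param theta A [theta_set()].
#' @param variance A [variance_spec()].
#' @param path File path of the YAML profile.
#' @return `write_model_profile()` returns `path` invisibly;
#'   `read_model_profile()` returns a list with elements `theta` and
#'   `variance`.
#' @export
write_model_profile <- function(theta, variance, path) {
  stopifnot(inherits(theta, "theta_set"), inherits(variance, "variance_spec"))
  obj <- list(
    theta = unclass(theta),
    variance = c(
      lapply(setNames(omega_names(), omega_names()), function(nm) variance[[nm]]),
      list(estimated = as.list(variance$estimated),
           iov_shared = variance$iov_shared)
    )
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_model_profile
#' @export
read_model_profile <- function(path) {
  obj <- yaml::read_yaml(path)
  theta <- do.call(theta_set, obj$theta)
  est <- unlist(obj$variance$estimated)
  var_args <- obj$variance[omega_names()]
  variance <- do.call(variance_spec,
                      c(var_args, list(estimated = est,
                                       iov_shared = obj$variance$iov_shared)))
  list(theta = theta, variance = variance)
}
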