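#' @noRd
#' Split an event table into per-subject structures used by the estimation
#' machinery: dose history, usable observations, occasion segmentation and
#' baseline covariates.
prepare_subjects <- function(data) {
  validate_event_table(data)
  ids <- unique(data$ID)
  lapply(ids, function(id) {
    d <- data[data$ID == id, , drop = FALSE]
    doses <- d[d$EVID == 1, , drop = FALSE]
    obs <- d[d$EVID == 0 & d$MDV == 0 & !is.na(d$DV), , drop = FALSE]
    occs <- sort(unique(d$OCC))
    # occasion k (k > first) begins at the earliest record carrying it
    seg_starts <- c(0, vapply(occs[-1], function(k) min(d$TIME[d$OCC == k]),
                              numeric(1)))
    covs <- d[1, covariate_columns(), drop = FALSE]
    list(id = id, doses = doses, obs = obs, occasions = occs,
         seg_starts = seg_starts, covs = covs)
  })
}

#' @noRd
#' Names of the active (non-degenerate) etas for one subject.
active_etas <- function(subject, variance) {
  nm <- character(0)
  for (p in c("cl", "vc", "q", "vp", "ka", "mtt", "n")) {
    if (variance[[paste0("omega_", p)]] > 0) nm <- c(nm, paste0("eta_", p))
  }
  if (variance$omega_iov > 0) {
    nm <- c(nm, paste0("eta_iov_", subject$occasions))
  }
  nm
}

#' @noRd
#' Prior standard deviation per active eta name.
eta_sds <- function(names, variance) {
  vapply(names, omega_for_eta, numeric(1), spec = variance)
}

#' @noRd
#' Typical parameters of one subject as a plain list (hot-path cache).
typ_for_subject <- function(subject, theta, extra_effects = NULL) {
  as.list(typical_params(subject$covs, theta, extra_effects = extra_effects)[1, ])
}

#' @noRd
#' Build the per-occasion parameter segments for a subject given a named eta
#' vector, and return predicted concentrations at the usable observation
#' times. `typ` is the precomputed typ_for_subject() list; the whole path is
#' plain-numeric for speed (called thousands of times per objective
#' evaluation).
predict_subject <- function(subject, theta, variance, eta, typ,
                            rtol = 1e-6, conc_scale = 1000) {
  tt <- subject$obs$TIME
  if (length(tt) == 0) return(numeric(0))
  g <- function(nm) if (nm %in% names(eta)) eta[[nm]] else 0
  occ <- subject$occasions
  nseg <- length(occ)
  iov <- vapply(occ, function(k) g(paste0("eta_iov_", k)), numeric(1))
  vc_seg <- typ$vc * exp(g("eta_vc") + iov)
  segs <- cbind(
    cl = rep(typ$cl * exp(g("eta_cl")), nseg),
    vc = vc_seg,
    q = rep(typ$q * exp(g("eta_q")), nseg),
    vp = typ$vp * exp(g("eta_vp") + iov),
    ka = rep(typ$ka * exp(g("eta_ka")), nseg),
    mtt = rep(typ$mtt * exp(g("eta_mtt")), nseg),
    n_transit = rep(typ$n_transit * exp(g("eta_n")), nseg),
    f = rep(typ$f, nseg)
  )
  amounts <- .pk_solve_cpp(tt, subject$doses$TIME, subject$doses$AMT,
                           segs, subject$seg_starts,
                           theta$theta_circadian, theta$circadian_acrophase,
                           theta$circadian_period, rtol, 1e-8,
                           c(0, 0, 0, 0))
  amounts[, 3] / vc_seg[seg_at(tt, subject$seg_starts)] * conc_scale
}

# floor on the individual prediction entering the proportional error
# variance, in ng/mL (a fifth of the 5 ng/mL quantification limit). A pure
# proportional model sends the residual variance to zero with the prediction,
# so a steep absorption upswing sampled just after dosing would otherwise
# dominate the likelihood and distort the eta modes.
F_FLOOR <- 1

#' @noRd
#' -2 log p(y | eta): extended-least-squares data term with interaction.
els_term <- function(y, f, sigma, conc_scale = 1000) {
  fb <- pmax(f, F_FLOOR * conc_scale / 1000)
  v <- sigma^2 * fb^2
  sum((y - f)^2 / v + log(v))
}

#' Empirical Bayes (MAP) eta estimation for one subject
#'
#' Minimizes the conditional objective
#' `-2 log p(y | eta) + sum(eta^2 / omega^2)` over the subject's active etas
#' (those with non-zero variance), with the proportional residual variance
#' evaluated at the individual prediction (the FOCE "interaction"). With all
#' IIV/IOV variances zero there is nothing to estimate and the eta vector is
#' empty.
#'
#' @param data Event-table rows of a single subject (an [event_table()]
#'   subset).
#' @param theta A [theta_set()].
#' @param variance A [variance_spec()].
#' @param extra_effects Optional covariate effects (see [typical_params()]).
#' @param eta_start Optional named starting values.
#' @param rtol Integrator relative tolerance used inside the objective.
#' @return A list: `eta` (named vector of MAP etas), `objective` (the
#'   minimized conditional objective), `ipred` (predictions at the MAP etas),
#'   `J` (finite-difference Jacobian of the predictions at the mode),
#'   `converged`.
#' @export
inner_ebe <- function(data, theta, variance, extra_effects = NULL,
                      eta_start = NULL, rtol = 1e-6) {
  subs <- prepare_subjects(data)
  if (length(subs) != 1) abort("`data` must contain exactly one subject.")
  typ <- typ_for_subject(subs[[1]], theta, extra_effects)
  inner_ebe_impl(subs[[1]], theta, variance, typ, eta_start, rtol)
}

inner_ebe_impl <- function(subject, theta, variance, typ,
                           eta_start = NULL, rtol = 1e-6, conc_scale = 1000,
                           need_jacobian = TRUE) {
  nm <- active_etas(subject, variance)
  y <- subject$obs$DV
  sigma <- variance$sigma_prop
  if (length(nm) == 0 || length(y) == 0) {
    f <- predict_subject(subject, theta, variance, numeric(0), typ,
                         rtol, conc_scale)
    obj <- if (length(y)) els_term(y, f, sigma, conc_scale) else 0
    return(list(eta = setNames(numeric(0), character(0)), objective = obj,
                ipred = f, J = NULL, converged = TRUE))
  }
  sds <- eta_sds(nm, variance)
  d <- length(nm)
  floor_c <- F_FLOOR * conc_scale / 1000
  hfun <- function(e, f) {
    els_term(y, f, sigma, conc_scale) + sum(e^2 / sds^2)
  }
  pred <- function(e) {
    predict_subject(subject, theta, variance, setNames(e, nm), typ, rtol,
                    conc_scale)
  }

  eta <- rep(0, d)
  if (!is.null(eta_start)) {
    keep <- intersect(names(eta_start), nm)
    eta[match(keep, nm)] <- pmin(pmax(eta_start[keep], -6 * sds[match(keep, nm)]),
                                 6 * sds[match(keep, nm)])
  }
  f <- pred(eta)
  h <- hfun(eta, f)
  J <- NULL
  converged <- FALSE

  # damped Gauss-Newton on the interaction objective: exact gradient given
  # the finite-difference Jacobian, Gauss-Newton curvature plus the prior
  for (iter in 1:12) {
    J <- eta_jacobian(subject, theta, variance, setNames(eta, nm), typ, rtol,
                      conc_scale)
    fb <- pmax(f, floor_c)
    v <- sigma^2 * fb^2
    r <- y - f
    dv <- ifelse(f > floor_c, 2 * sigma^2 * f, 0)
    u <- -2 * r / v + dv * (1 / v - r^2 / v^2)
    g <- as.numeric(t(J) %*% u) + 2 * eta / sds^2
    H <- 2 * t(J) %*% (J / v) + diag(2 / sds^2, d)
    step <- tryCatch(-solve(H, g), error = function(e) -g / diag(H))
    accepted <- FALSE
    for (damp in c(1, 0.5, 0.25, 0.1, 0.02)) {
      cand <- pmin(pmax(eta + damp * step, -6 * sds), 6 * sds)
      f_cand <- pred(cand)
      h_cand <- hfun(cand, f_cand)
      if (is.finite(h_cand) && h_cand < h) {
        delta <- h - h_cand
        eta <- cand; f <- f_cand; h <- h_cand
        accepted <- TRUE
        break
      }
    }
    if (!accepted) { converged <- TRUE; break }
    if (delta < 1e-6 * (abs(h) + 1) || max(abs(damp * step)) < 1e-6) {
      converged <- TRUE
      break
    }
  }
  if (need_jacobian && (is.null(J) || !converged)) {
    J <- eta_jacobian(subject, theta, variance, setNames(eta, nm), typ, rtol,
                      conc_scale)
  }
  list(eta = setNames(eta, nm), objective = h, ipred = f, J = J,
       converged = converged)
}

#' @noRd
#' Jacobian d f / d eta at eta-hat by central finite differences.
eta_jacobian <- function(subject, theta, variance, eta, typ,
                         rtol, conc_scale = 1000, h = 1e-4) {
  nm <- names(eta)
  n_obs <- nrow(subject$obs)
  J <- matrix(0, n_obs, length(nm), dimnames = list(NULL, nm))
  for (k in seq_along(nm)) {
    up <- eta; up[k] <- up[k] + h
    dn <- eta; dn[k] <- dn[k] - h
    fu <- predict_subject(subject, theta, variance, up, typ, rtol, conc_scale)
    fd <- predict_subject(subject, theta, variance, dn, typ, rtol, conc_scale)
    J[, k] <- (fu - fd) / (2 * h)
  }
  J
}

#' @noRd
#' FOCE-I marginal-likelihood contribution of one subject (Laplace-type, with
#' the Gauss-Newton Hessian at the eta mode), plus the pieces needed by CWRES.
subject_ofv <- function(subject, theta, variance, typ,
                        eta_start = NULL, rtol = 1e-6, conc_scale = 1000,
                        need_jacobian = TRUE) {
  ebe <- inner_ebe_impl(subject, theta, variance, typ, eta_start,
                        rtol, conc_scale, need_jacobian = need_jacobian)
  y <- subject$obs$DV
  f <- ebe$ipred
  if (any(!is.finite(f))) {
    abort(sprintf("Non-finite prediction for subject %s.", format(subject$id)))
  }
  nm <- names(ebe$eta)
  if (length(nm) == 0 || length(y) == 0) {
    return(list(ofv = ebe$objective, eta = ebe$eta, ipred = f, J = NULL,
                converged = ebe$converged))
  }
  sds <- eta_sds(nm, variance)
  J <- ebe$J
  log_det_term <- 0
  if (need_jacobian && !is.null(J)) {
    fb <- pmax(f, F_FLOOR * conc_scale / 1000)
    w <- 1 / (variance$sigma_prop^2 * fb^2)
    M <- diag(sds^2, length(nm)) %*% (t(J) %*% (J * w))
    log_det_term <- determinant(diag(1, length(nm)) + M, logarithm = TRUE)$modulus
  }
  list(ofv = ebe$objective + as.numeric(log_det_term),
       eta = ebe$eta, ipred = f, J = J, converged = ebe$converged)
}

#' FOCE-I objective function value
#'
#' -2 times the approximate marginal log-likelihood of an event table under
#' the model, summed over subjects: each subject's extended-least-squares data
#' term and eta prior are evaluated at the empirical Bayes eta mode, with a
#' Gauss-Newton Laplace correction and the proportional residual variance
#' taken at the individual prediction (interaction). The additive
#' `n log(2 pi)` constant is omitted, following the usual OFV convention.
#'
#' @param data An [event_table()].
#' @param theta A [theta_set()].
#' @param variance A [variance_spec()].
#' @param extra_effects Optional covariate effects (see [typical_params()]).
#' @param rtol Integrator relative tolerance.
#' @param eta_cache Optional environment carrying warm-start etas between
#'   calls (keyed by subject id); updated in place.
#' @return The OFV (numeric scalar) with attribute `"subjects"` holding
#'   per-subject details (eta modes, individual predictions, Jacobians).
#' @export
foce_objective <- function(data, theta, variance, extra_effects = NULL,
                           rtol = 1e-6, eta_cache = NULL) {
  subjects <- prepare_subjects(data)
  foce_objective_impl(subjects, theta, variance, extra_effects, rtol, eta_cache)
}

foce_objective_impl <- function(subjects, theta, variance,
                                extra_effects = NULL, rtol = 1e-6,
                                eta_cache = NULL, conc_scale = 1000,
                                need_jacobian = TRUE) {
  details <- lapply(subjects, function(s) {
    key <- paste0("s", s$id)
    start <- if (!is.null(eta_cache)) eta_cache[[key]] else NULL
    typ <- typ_for_subject(s, theta, extra_effects)
    res <- subject_ofv(s, theta, variance, typ, eta_start = start,
                       rtol = rtol, conc_scale = conc_scale,
                       need_jacobian = need_jacobian)
    if (!is.null(eta_cache)) eta_cache[[key]] <- res$eta
    res
  })
  ofv <- sum(vapply(details, `[[`, numeric(1), "ofv"))
  attr(ofv, "subjects") <- details
  ofv
}

# parameters estimated on the log scale (positivity-constrained)
log_scale_params <- function() {
  c("cl_pop", "vc_pop", "q_pop", "vp_pop", "ka", "mtt", "n_transit",
    "omega_cl", "omega_vc", "omega_q", "omega_vp", "omega_ka", "omega_mtt",
    "omega_n", "omega_iov", "sigma_prop")
}

par_transform <- function(name, value) {
  if (name %in% log_scale_params()) log(value) else value
}
par_back <- function(name, value) {
  if (name %in% log_scale_params()) exp(value) else value
}

#' @noRd
#' Rebuild (theta, variance, extra_effects) from a named vector of free
#' parameter values on the natural scale.
apply_free <- function(theta, variance, extra_effects, values) {
  for (nm in names(values)) {
    if (nm %in% names(theta)) {
      theta[[nm]] <- values[[nm]]
    } else if (nm %in% omega_names()) {
      variance[[nm]] <- values[[nm]]
    } else if (grepl("^beta_", nm)) {
      idx <- which(vapply(extra_effects, function(e) e$name, "") == nm)
      if (length(idx) != 1) abort(sprintf("Unknown effect parameter `%s`.", nm))
      extra_effects[[idx]]$theta <- values[[nm]]
    } else {
      abort(sprintf("Unknown free parameter `%s`.", nm))
    }
  }
  validate_theta(theta)
  list(theta = theta, variance = variance, extra_effects = extra_effects)
}

free_start_values <- function(theta, variance, extra_effects, free) {
  vapply(free, function(nm) {
    if (nm %in% names(theta)) return(theta[[nm]])
    if (nm %in% omega_names()) return(variance[[nm]])
    if (grepl("^beta_", nm)) {
      idx <- which(vapply(extra_effects, function(e) e$name, "") == nm)
      if (length(idx) == 1) return(extra_effects[[idx]]$theta)
    }
    abort(sprintf("Unknown free parameter `%s`.", nm))
  }, numeric(1))
}

#' Fit the population model by FOCE-I
#'
#' Minimizes [foce_objective()] over a chosen set of free parameters.
#' Positivity-constrained parameters (clearances, volumes, rate constants,
#' variance-component standard deviations) are estimated on the log scale;
#' covariate slopes on the natural scale. Empirical Bayes etas are
#' warm-started between objective evaluations. Relative standard errors come
#' from the inverse finite-difference Hessian of the objective at the optimum.
#'
#' @param data An [event_table()].
#' @param theta Initial [theta_set()].
#' @param variance Initial [variance_spec()].
#' @param free Character vector naming the free parameters: any `theta_set`
#'   field, any variance component (`omega_*`, `sigma_prop`), or the `name`
#'   of an entry in `extra_effects`. An empty vector evaluates the objective
#'   at the initial values without optimizing.
#' @param extra_effects Optional covariate effects ([covariate_candidate()]
#'   entries with a `theta` start value).
#' @param rtol Integrator relative tolerance inside the objective.
#' @param compute_rse Whether to compute the finite-difference Hessian for
#'   relative standard errors (skipped for speed when `FALSE`).
#' @param control List: `maxit` (outer iterations), `reltol` (outer relative
#'   convergence tolerance).
#' @return An object of class `radpk_fit`; see [tidy.radpk_fit()] and
#'   [glance.radpk_fit()].
#' @export
fit_foce <- function(data, theta, variance, free = c("cl_pop", "omega_cl",
                                                     "sigma_prop"),
                     extra_effects = NULL, rtol = 1e-5, compute_rse = FALSE,
                     control = list()) {
  ctrl <- modifyList(list(maxit = 400, reltol = 1e-5), control)
  subjects <- prepare_subjects(data)
  if ("theta_disease" %in% free &&
      length(unique(vapply(subjects, function(s) s$covs$CML, numeric(1)))) < 2) {
    warn("`theta_disease` is free but the data contain a single disease level; the effect is not identifiable.")
  }
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L

  objective_at <- function(values) {
    mod <- apply_free(theta, variance, extra_effects, values)
    foce_objective_impl(subjects, mod$theta, mod$variance, mod$extra_effects,
                        rtol = rtol, eta_cache = cache, need_jacobian = TRUE)
  }

  if (length(free) == 0) {
    ofv <- objective_at(setNames(numeric(0), character(0)))
    return(new_radpk_fit(theta, variance, extra_effects, ofv, subjects,
                         rse = NULL, convergence = 0L, n_eval = 1L,
                         rtol = rtol))
  }

  start_nat <- free_start_values(theta, variance, extra_effects, free)
  start_tr <- vapply(free, function(nm) par_transform(nm, start_nat[[nm]]),
                     numeric(1))
  fn <- function(p) {
    n_eval <<- n_eval + 1L
    values <- setNames(vapply(free, function(nm) par_back(nm, p[[match(nm, free)]]),
                              numeric(1)), free)
    as.numeric(tryCatch(objective_at(values), error = function(e) 1e10))
  }

  if (length(free) == 1) {
    o <- optimize(fn, interval = c(start_tr - 2, start_tr + 2), tol = 1e-5)
    par <- setNames(o$minimum, free)
    value <- o$objective
    convergence <- 0L
  } else {
    opt <- optim(start_tr, fn, method = "Nelder-Mead",
                 control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
    par <- setNames(opt$par, free)
    value <- opt$value
    convergence <- opt$convergence
  }

  est <- setNames(vapply(free, function(nm) par_back(nm, par[[nm]]),
                         numeric(1)), free)
  mod <- apply_free(theta, variance, extra_effects, est)
  ofv <- foce_objective_impl(subjects, mod$theta, mod$variance,
                             mod$extra_effects, rtol = rtol, eta_cache = cache)

  rse <- NULL
  if (compute_rse) {
    H <- optimHess(unname(par), fn)
    cov_tr <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov_tr)) {
      se_tr <- sqrt(pmax(diag(cov_tr), 0))
      rse <- tibble(
        parameter = free,
        estimate = unname(est),
        rse_percent = vapply(seq_along(free), function(i) {
          if (free[i] %in% log_scale_params()) 100 * se_tr[i]
          else 100 * se_tr[i] / abs(est[[i]])
        }, numeric(1))
      )
    }
  }

  new_radpk_fit(mod$theta, mod$variance, mod$extra_effects, ofv, subjects,
                rse = rse, convergence = convergence, n_eval = n_eval,
                rtol = rtol)
}

new_radpk_fit <- function(theta, variance, extra_effects, ofv, subjects,
                          rse, convergence, n_eval, rtol) {
  details <- attr(ofv, "subjects")
  etas <- purrr::map_dfr(seq_along(subjects), function(i) {
    e <- details[[i]]$eta
    if (length(e) == 0) return(tibble(ID = subjects[[i]]$id))
    dplyr::bind_cols(tibble(ID = subjects[[i]]$id), as_tibble(as.list(e)))
  })
  structure(list(
    theta = theta, variance = variance, extra_effects = extra_effects,
    ofv = as.numeric(ofv), details = details, subjects = subjects,
    eta_hat = etas, rse = rse, convergence = convergence, n_eval = n_eval,
    rtol = rtol
  ), class = "radpk_fit")
}

#' @export
print.radpk_fit <- function(x, ...) {
  cat(sprintf("<radpk_fit>  OFV = %.3f  (%d subjects, %d objective evaluations)\n",
              x$ofv, length(x$subjects), x$n_eval))
  if (!is.null(x$rse)) print(x$rse)
  invisible(x)
}

#' Conditional weighted residuals
#'
#' FOCE-linearized residuals: for each subject the observation vector is
#' centered on the population-corrected prediction
#' `f(eta_hat) - J eta_hat` and decorrelated by the model-implied covariance
#' `J Omega J' + diag(sigma^2 f(eta_hat)^2)` (lower-Cholesky whitening).
#' Under a correct model CWRES are approximately standard normal.
#'
#' @param data The [event_table()] that was fitted.
#' @param fit A `radpk_fit` (its theta/variance/etas are used).
#' @return A tibble: `ID`, `TIME`, `OCC`, `DV`, `PRED` (population prediction
#'   at eta = 0), `IPRED` (at the eta mode), `CWRES`.
#' @export
cwres <- function(data, fit) {
  stopifnot(inherits(fit, "radpk_fit"))
  gof_table(data, fit)[, c("ID", "TIME", "OCC", "DV", "PRED", "IPRED", "CWRES")]
}

#' Goodness-of-fit table
#'
#' Per-observation population predictions (etas fixed at 0), individual
#' predictions (empirical Bayes etas), residuals and conditional weighted
#' residuals, in a tidy tibble ready for observed-versus-predicted and
#' residual-versus-time displays.
#'
#' @inheritParams cwres
#' @return A tibble with one row per usable observation: `ID`, `TIME`, `OCC`,
#'   `DV`, `PRED`, `IPRED`, `RES`, `IRES`, `CWRES`.
#' @export
gof_table <- function(data, fit) {
  stopifnot(inherits(fit, "radpk_fit"))
  theta <- fit$theta
  variance <- fit$variance
  purrr::map_dfr(seq_along(fit$subjects), function(i) {
    s <- fit$subjects[[i]]
    det <- fit$details[[i]]
    y <- s$obs$DV
    if (length(y) == 0) return(NULL)
    f_ind <- det$ipred
    typ <- typ_for_subject(s, theta, fit$extra_effects)
    f_pop <- predict_subject(s, theta, variance, numeric(0), typ,
                             rtol = fit$rtol)
    eta <- det$eta
    fb <- pmax(f_ind, F_FLOOR)
    v <- variance$sigma_prop^2 * fb^2
    if (length(eta) > 0) {
      J <- det$J
      if (is.null(J)) {
        J <- eta_jacobian(s, theta, variance, eta, typ, fit$rtol)
      }
      sds <- eta_sds(names(eta), variance)
      V <- J %*% diag(sds^2, length(eta)) %*% t(J) + diag(v, length(y))
      r <- y - (f_ind - as.numeric(J %*% eta))
      cw <- tryCatch(
        as.numeric(forwardsolve(t(chol(V)), r)),
        error = function(e) {
          warn(sprintf("Near-singular residual covariance for subject %s; regularized.",
                       format(s$id)))
          as.numeric(forwardsolve(t(chol(V + diag(1e-8 * mean(diag(V)), length(y)))), r))
        }
      )
    } else {
      cw <- (y - f_ind) / sqrt(v)
    }
    tibble(ID = s$id, TIME = s$obs$TIME, OCC = s$obs$OCC, DV = y,
           PRED = f_pop, IPRED = f_ind, RES = y - f_pop, IRES = y - f_ind,
           CWRES = cw)
  })
}
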