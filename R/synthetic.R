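#' Two-cohort study design template
#'
#' The sampling and dosing template of the model-development data: 23 healthy
#' volunteers receiving a single oral 400 mg dose with rich sampling to 48 h,
#' and 24 CML-CP patients receiving 300 mg every 12 h with pre-dose and
#' post-dose sampling on Day 1 (occasion 1, non-steady state) and Day 14
#' (occasion 2, steady state).
#'
#' @param n_hv,n_patient Cohort sizes.
#' @param hv_dose_mg,patient_dose_mg Dose amounts (mg).
#' @param patient_interval_h Patient dosing interval (h).
#' @param hv_times HV sampling times (h post-dose; 0 is the pre-dose sample).
#' @param patient_times_postdose Patient sampling times within a dosing day
#'   (h after the day's first dose; 0 is the pre-dose sample).
#' @param patient_days Sampling days (1-based).
#' @return A list of class `radpk_design`.
#' @export
study_design <- function(n_hv = 23, n_patient = 24,
                         hv_dose_mg = 400, patient_dose_mg = 300,
                         patient_interval_h = 12,
                         hv_times = c(0, 0.5, 1, 2, 3, 4, 5, 6, 8, 10, 12, 18, 24, 32, 48),
                         patient_times_postdose = c(0, 1, 2, 3, 4, 6, 8, 12),
                         patient_days = c(1, 14)) {
  stopifnot(n_hv >= 0, n_patient >= 0, hv_dose_mg > 0, patient_dose_mg > 0)
  structure(list(
    n_hv = n_hv, n_patient = n_patient,
    hv_dose_mg = hv_dose_mg, patient_dose_mg = patient_dose_mg,
    patient_interval_h = patient_interval_h,
    hv_times = sort(hv_times),
    patient_times_postdose = sort(patient_times_postdose),
    patient_days = sort(patient_days)
  ), class = "radpk_design")
}

# rejection sampler for a truncated log-normal, vectorized
rtrunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- exp(rnorm(n, meanlog, sdlog))
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Sample baseline covariates for a cohort
#'
#' Emulates the demographic structure of the model-development cohorts:
#' healthy volunteers are all male with ages spread uniformly over 20-51
#' years; patients are 54% male with a truncated log-normal age distribution
#' (median about 32, range 21-72). Weight, height and laboratory values are
#' drawn from truncated log-normal/normal distributions spanning the observed
#' cohort ranges. Creatinine clearance is drawn directly (no serum creatinine
#' is modelled).
#'
#' @param n Number of individuals.
#' @param cohort `"patient"`, `"hv"`, or `"mixed"` (23:24 HV:patient mix).
#' @param seed Optional integer seed for an isolated RNG scope.
#' @return A tibble with columns `AGE`, `CML`, `SEX` (0 = male, 1 = female),
#'   `WT`, `HT`, `ALT`, `AST`, `CLCR`.
#' @export
virtual_population <- function(n, cohort = c("patient", "hv", "mixed"),
                               seed = NULL) {
  cohort <- match.arg(cohort)
  stopifnot(n >= 1)
  draw <- function() {
    if (cohort == "mixed") {
      n_hv <- round(n * 23 / 47)
      return(dplyr::bind_rows(
        if (n_hv > 0) draw_cohort(n_hv, "hv"),
        if (n - n_hv > 0) draw_cohort(n - n_hv, "patient")
      ))
    }
    draw_cohort(n, cohort)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

draw_cohort <- function(n, cohort) {
  if (cohort == "hv") {
    tibble(
      AGE = sample(20:51, n, replace = TRUE),
      CML = 0,
      SEX = 0,
      WT = rtrunc_lnorm(n, log(71), 0.09, 55.1, 85.2),
      HT = rtrunc_lnorm(n, log(173), 0.025, 166, 186),
      ALT = rtrunc_lnorm(n, log(16), 0.45, 7, 80),
      AST = rtrunc_lnorm(n, log(19), 0.40, 11, 76),
      CLCR = rtrunc_lnorm(n, log(117), 0.12, 72, 139)
    )
  } else {
    tibble(
      AGE = round(rtrunc_lnorm(n, log(32), 0.28, 21, 72)),
      CML = 1,
      SEX = as.integer(runif(n) > 0.54),
      WT = rtrunc_lnorm(n, log(65), 0.14, 47, 96),
      HT = rtrunc_lnorm(n, log(168), 0.03, 155, 178),
      ALT = rtrunc_lnorm(n, log(21), 0.35, 15, 75),
      AST = rtrunc_lnorm(n, log(25), 0.20, 15, 41),
      CLCR = rtrunc_lnorm(n, log(109), 0.20, 74, 200)
    )
  }
}

#' Generate a synthetic two-cohort study
#'
#' Draws covariates and random effects per subject, simulates noise-free
#' concentrations at the design's sampling times with the structural model,
#' applies proportional residual error, and flags/handles below-quantification
#' observations — producing a complete, validated NONMEM-style event table.
#' Patients receive independent IOV draws for Day 1 and Day 14 (the volume
#' parameters switch at the Day-14 pre-dose time); healthy volunteers are a
#' single-occasion cohort. Pre-dose Day-1 samples are true zeros (no prior
#' exposure) and come out flagged below the limit of quantification.
#'
#' @param theta A [theta_set()].
#' @param variance A [variance_spec()].
#' @param design A [study_design()].
#' @param seed Optional integer seed for an isolated RNG scope.
#' @param policy [lloq_policy()] applied to the generated observations.
#' @param rtol Integrator relative tolerance.
#' @return An [event_table()].
#' @export
generate_study <- function(theta = radotinib_theta(),
                           variance = radotinib_variance(),
                           design = study_design(), seed = NULL,
                           policy = lloq_policy(), rtol = 1e-8) {
  stopifnot(inherits(design, "radpk_design"))
  run <- function() {
    rows <- list()
    id <- 0

    if (design$n_hv > 0) {
      covs <- draw_cohort(design$n_hv, "hv")
      etas <- draw_etas(design$n_hv, variance, n_occasions = 1)
      typ <- typical_params(covs, theta)
      ind <- realize_individual(typ, etas, occasion = 1)
      for (i in seq_len(design$n_hv)) {
        id <- id + 1
        tt <- design$hv_times
        pos <- tt[tt > 0]
        prof <- simulate_profile(ind[i, ], theta,
                                 tibble(time = 0, amount = design$hv_dose_mg),
                                 times = pos, rtol = rtol)
        conc <- c(rep(0, sum(tt == 0)), prof$conc)
        dv <- apply_residual_error(conc, variance)
        rows[[length(rows) + 1]] <- dplyr::bind_rows(
          tibble(ID = id, TIME = 0, AMT = 0, EVID = 0, DV = as.numeric(dv[tt == 0]),
                 MDV = 0, OCC = 1),
          tibble(ID = id, TIME = 0, AMT = design$hv_dose_mg, EVID = 1,
                 DV = NA_real_, MDV = 1, OCC = 1),
          tibble(ID = id, TIME = pos, AMT = 0, EVID = 0,
                 DV = as.numeric(dv[tt > 0]), MDV = 0, OCC = 1)
        ) |>
          dplyr::bind_cols(covs[rep(i, sum(tt == 0) + 1 + length(pos)), ])
      }
    }

    if (design$n_patient > 0) {
      covs <- draw_cohort(design$n_patient, "patient")
      etas <- draw_etas(design$n_patient, variance, n_occasions = 2)
      typ <- typical_params(covs, theta)
      ind1 <- realize_individual(typ, etas, occasion = 1)
      ind2 <- realize_individual(typ, etas, occasion = 2)
      tau <- design$patient_interval_h
      for (i in seq_len(design$n_patient)) {
        id <- id + 1
        day_starts <- (design$patient_days - 1) * 24
        occ_of_day <- seq_along(design$patient_days)
        occ2_start <- if (length(day_starts) > 1) day_starts[2] else Inf
        last_obs <- max(day_starts) + max(design$patient_times_postdose)
        dose_times <- seq(0, max(day_starts), by = tau)
        obs <- tidyr::expand_grid(day = seq_along(day_starts),
                                  tpost = design$patient_times_postdose) |>
          mutate(time = day_starts[.data$day] + .data$tpost,
                 occ = occ_of_day[.data$day])
        pos <- obs$time[obs$time > 0]
        seg <- dplyr::bind_rows(ind1[i, ], ind2[i, ])
        amounts <- solve_amounts(pos, dose_times,
                                 rep(design$patient_dose_mg, length(dose_times)),
                                 seg, c(0, occ2_start), theta, rtol = rtol)
        vc_seg <- seg$vc[seg_at(pos, c(0, occ2_start))]
        # obs rows are time-ascending with the single true-zero pre-dose
        # sample first, matching the concatenation below
        conc <- c(rep(0, sum(obs$time == 0)),
                  amounts[, "a_central"] / vc_seg * 1000)
        dv <- apply_residual_error(conc, variance)
        dose_occ <- ifelse(dose_times < occ2_start, 1, 2)
        rec <- dplyr::bind_rows(
          tibble(ID = id, TIME = obs$time, AMT = 0, EVID = 0,
                 DV = as.numeric(dv), MDV = 0, OCC = obs$occ),
          tibble(ID = id, TIME = dose_times,
                 AMT = design$patient_dose_mg, EVID = 1, DV = NA_real_,
                 MDV = 1, OCC = dose_occ)
        )
        # pre-dose samples precede the simultaneous dose record
        rec <- rec[order(rec$TIME, rec$EVID), ]
        rec <- dplyr::bind_cols(rec, covs[rep(i, nrow(rec)), ])
        rows[[length(rows) + 1]] <- rec
      }
    }

    tab <- event_table(dplyr::bind_rows(rows))
    if (is.null(policy)) tab else apply_lloq(tab, policy)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Randomly blank observations (dropout / missingness stress tool)
#'
#' Marks a random subset of observation records missing (`MDV = 1`, `DV`
#' blanked); dose records are never removed. Intended for stress-testing
#' estimation robustness, not for emulating any particular study.
#'
#' @param data An [event_table()].
#' @param rate Per-observation blanking probability in `[0, 1]`.
#' @param seed Optional integer seed for an isolated RNG scope.
#' @return The event table with the selected observations blanked.
#' @export
dropout_and_missingness <- function(data, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  run <- function() {
    hit <- data$EVID == 0 & runif(nrow(data)) < rate
    data$MDV[hit] <- 1
    data$DV[hit] <- NA_real_
    data
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
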