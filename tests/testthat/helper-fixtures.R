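# shared fixtures: everything is generated in code at test time

final_theta <- radotinib_theta()
final_variance <- radotinib_variance()

# variance structure used by the estimation experiments: IIV on clearance
# only, proportional error as published
cl_only_variance <- function(omega_cl = 0.389, sigma_prop = 0.2) {
  variance_spec(omega_cl = omega_cl, sigma_prop = sigma_prop)
}

# a small two-cohort study (single patient sampling day) for fast fit tests
tiny_design <- function(n_hv = 4, n_patient = 4) {
  study_design(n_hv = n_hv, n_patient = n_patient,
               hv_times = c(0, 1, 2, 4, 8, 12, 24, 48),
               patient_days = 1)
}

# one-subject, single-dose event table with observations at given times and
# concentrations; used to build analytic toys
toy_subject <- function(times, dv, dose_mg = 400, cml = 1, age = 31, id = 1) {
  event_table(dplyr::bind_rows(
    tibble::tibble(ID = id, TIME = 0, AMT = dose_mg, EVID = 1, DV = NA_real_,
                   MDV = 1, OCC = 1),
    tibble::tibble(ID = id, TIME = times, AMT = 0, EVID = 0, DV = dv,
                   MDV = 0, OCC = 1)
  ) |>
    dplyr::mutate(AGE = age, CML = cml, SEX = 0, WT = 65, HT = 170,
                  ALT = 20, AST = 20, CLCR = 110))
}

# noise-free concentrations of the typical individual for a single dose
typical_conc <- function(times, theta = final_theta, dose_mg = 400,
                         cml = 1, age = 31) {
  tp <- typical_params(data.frame(age = age, cml = cml), theta)
  simulate_profile(tp, theta, tibble::tibble(time = 0, amount = dose_mg),
                   times = times)$conc
}
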