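test_that("covariate forms evaluate correctly and guard their domains", {
  expect_equal(covariate_function("linear", -0.0129, 31, 31), 1)
  expect_equal(covariate_function("linear", -0.0129, 72, 31), 0.4711)
  expect_equal(383 * covariate_function("linear", -0.0129, 72, 31), 180.4,
               tolerance = 1e-3)
  expect_equal(covariate_function("power", 0, c(40, 90), 65), c(1, 1))
  expect_equal(covariate_function("power", 0.75, 130, 65), 2^0.75)
  expect_equal(covariate_function("exponential", 0.02, 75, 65), exp(0.2))
  expect_equal(covariate_function("proportional", -0.392, 1), 0.608)
  expect_equal(covariate_function("additive", 5, 1), 5)
  expect_error(covariate_function("power", 1, -2, 65), "positive")
  expect_error(covariate_function("spline", 1, 1, 1), "Unknown")
})

test_that("derived covariates follow the Mosteller and Cockcroft-Gault formulas", {
  d <- tibble::tibble(AGE = 40, SEX = c(0, 1), WT = 80, HT = 180, SCR = 1.0)
  out <- derive_covariates(d)
  expect_equal(out$BSA, c(2, 2))
  expect_equal(out$CLCR_CG[1], (140 - 40) * 80 / 72)
  expect_equal(out$CLCR_CG[2], out$CLCR_CG[1] * 0.85)

  # linear in weight
  d2 <- d; d2$WT <- 160
  expect_equal(derive_covariates(d2)$CLCR_CG, 2 * out$CLCR_CG)

  expect_error(derive_covariates(tibble::tibble(HT = 180, WT = 0)), "positive")
  expect_warning(derive_covariates(tibble::tibble(HT = 180, WT = 80, SCR = 1)),
                 "AGE")
})

test_that("stepwise covariate modelling respects its thresholds end to end", {
  th_base <- theta_set(cl_pop = 23, theta_disease = 0, theta_circadian = 0.683,
                       vc_pop = 383, theta_age = 0)
  spec <- cl_only_variance()
  # strong disease effect in the generating model, nothing else
  tab <- generate_study(radotinib_theta(), spec, design = tiny_design(6, 6),
                        seed = 31)

  cands <- list(
    covariate_candidate("cl", "CML", "proportional"),
    covariate_candidate("cl", "WT", "power")
  )
  res <- scm(tab, th_base, spec, cands,
             free_base = c("cl_pop", "omega_cl", "sigma_prop"),
             control = list(maxit = 120))

  tr <- res$trace
  added <- tr[tr$decision == "added", ]
  expect_true(all(added$delta_ofv > 3.84))
  removed <- tr[tr$decision == "removed", ]
  if (nrow(removed) > 0) expect_true(all(-removed$delta_ofv <= 6.63))
  retained <- tr[tr$decision == "retained", ]
  if (nrow(retained) > 0) expect_true(all(-retained$delta_ofv > 6.63))
  # every retained effect earned its keep on the way in
  for (inc in res$included) {
    expect_true(inc$covariate %in% added$covariate)
  }

  # the trace is reproducible: fits are deterministic given data and inits
  res2 <- scm(tab, th_base, spec, cands,
              free_base = c("cl_pop", "omega_cl", "sigma_prop"),
              control = list(maxit = 120))
  expect_equal(res$trace$delta_ofv, res2$trace$delta_ofv, tolerance = 1e-8)

  # an empty candidate list returns the base model untouched
  res0 <- scm(tab, th_base, spec, list(),
              free_base = c("cl_pop", "omega_cl", "sigma_prop"),
              control = list(maxit = 120))
  expect_equal(nrow(res0$trace), 0)
  expect_length(res0$included, 0)
  expect_equal(res0$final_fit$ofv, res0$base_ofv)
})
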