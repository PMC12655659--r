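test_that("dose linearity and the dose/clearance identity hold at steady state", {
  th0 <- theta_set(cl_pop = 23, theta_circadian = 0)
  tp <- typical_params(data.frame(age = 31, cml = 1), th0)

  # without the circadian term, daily AUC at steady state is daily dose / CL
  w <- steady_state_window(tp, th0, 400, 24)
  m <- exposure_metrics(w)
  expect_equal(m$auc_0_24, 400 / 23 * 1000, tolerance = 0.01)

  # doubling the dose doubles every concentration
  th <- final_theta
  w300 <- steady_state_window(tp, th, 300, 24)
  w600 <- steady_state_window(tp, th, 600, 24)
  expect_equal(w600$conc, 2 * w300$conc, tolerance = 1e-6)

  # the window opens on a dose
  expect_equal(attr(w300, "window_start") %% 24, 0)
})

test_that("steady-state trough matches the one-compartment superposition formula", {
  # disconnected peripheral compartment, no circadian term, near-instant
  # absorption: trough follows D exp(-k tau) / (V (1 - exp(-k tau)))
  th1 <- theta_set(cl_pop = 23, theta_circadian = 0, q_pop = 1e-9,
                   ka = 50, mtt = 0.02, n_transit = 1)
  tp <- typical_params(data.frame(age = 31, cml = 1), th1)
  tp$q <- 0
  w <- steady_state_window(tp, th1, 300, 24)
  k <- 23 / 383
  closed <- 300 * exp(-k * 24) / (383 * (1 - exp(-k * 24))) * 1000
  expect_equal(exposure_metrics(w)$ctrough, closed, tolerance = 0.01)
})

test_that("exposure metrics follow from profile geometry and converge with the grid", {
  flat <- structure(tibble::tibble(time = seq(0, 24, 0.5), conc = 50),
                    class = c("radpk_profile", class(tibble::tibble())))
  m <- exposure_metrics(flat, interval_h = 24)
  expect_equal(m$auc_0_24, 24 * 50)
  expect_equal(m$cmax, 50)
  expect_equal(m$ctrough, 50)

  tri <- structure(tibble::tibble(time = c(0, 3, 24), conc = c(0, 100, 0)),
                   class = c("radpk_profile", class(tibble::tibble())))
  m2 <- exposure_metrics(tri, interval_h = 24)
  expect_equal(m2$auc_0_24, 1200)
  expect_equal(m2$tmax, 3)

  short <- structure(tibble::tibble(time = c(0, 12), conc = c(1, 1)),
                     class = c("radpk_profile", class(tibble::tibble())))
  expect_error(exposure_metrics(short, 12), "24 h")

  th <- final_theta
  tp <- typical_params(data.frame(age = 31, cml = 1), th)
  coarse <- exposure_metrics(steady_state_window(tp, th, 300, 12, grid_dt = 0.25))
  fine <- exposure_metrics(steady_state_window(tp, th, 300, 12, grid_dt = 0.05))
  expect_equal(coarse$auc_0_24, fine$auc_0_24, tolerance = 5e-3)
  expect_equal(coarse$cmax, fine$cmax, tolerance = 5e-3)
})

test_that("Monte Carlo exposures are reproducible and degenerate correctly", {
  th <- final_theta
  fixed_cov <- tibble::tibble(AGE = 31, CML = 1, SEX = 0, WT = 65, HT = 168,
                              ALT = 20, AST = 20, CLCR = 110)[rep(1, 5), ]
  none <- variance_spec()
  mc <- monte_carlo_exposures(th, none, 300, 12, n_subjects = 5, seed = 1,
                              covariates = fixed_cov)
  typ <- exposure_metrics(
    steady_state_window(typical_params(fixed_cov[1, ], th), th, 300, 12)
  )
  s <- mc$summary
  expect_equal(s$median[s$metric == "auc_0_24"], typ$auc_0_24, tolerance = 1e-8)
  expect_equal(s$median[s$metric == "cmax"], typ$cmax, tolerance = 1e-8)
  expect_equal(unname(s$q25), unname(s$q75), tolerance = 1e-8)

  mc2 <- monte_carlo_exposures(th, final_variance, 300, 12, n_subjects = 20,
                               seed = 42)
  mc3 <- monte_carlo_exposures(th, final_variance, 300, 12, n_subjects = 20,
                               seed = 42)
  expect_identical(mc2$metrics, mc3$metrics)

  # percentile ordering in every summary row
  expect_true(all(mc2$summary$p05 <= mc2$summary$q25))
  expect_true(all(mc2$summary$q25 <= mc2$summary$median))
  expect_true(all(mc2$summary$median <= mc2$summary$q75))
  expect_true(all(mc2$summary$q75 <= mc2$summary$p95))
  expect_true(all(mc2$metrics$cmax >= mc2$metrics$ctrough))
})
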