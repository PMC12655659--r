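test_that("covariate model reproduces the published typical values", {
  th <- final_theta
  pat <- typical_params(data.frame(age = 31, cml = 1), th)
  expect_equal(pat$cl, 23.0)
  expect_equal(pat$vc, 383)

  hv <- typical_params(data.frame(age = 31, cml = 0), th)
  expect_equal(round(hv$cl, 1), 37.9)

  expect_equal(typical_params(data.frame(age = 72, cml = 1), th)$vc,
               180.4, tolerance = 1e-3)
  expect_equal(typical_params(data.frame(age = 20, cml = 1), th)$vc,
               437.3, tolerance = 1e-3)

  # age far outside the linear model's support drives vc negative
  expect_error(typical_params(data.frame(age = 120, cml = 1), th),
               "age outside")
})

test_that("circadian multiplier peaks at the acrophase and averages to one", {
  th <- final_theta
  expect_equal(circadian_factor(7, th), 1.683)
  expect_equal(circadian_factor(19, th), 0.317)
  # period exactly 24 h
  tt <- seq(0, 240, by = 0.5)
  expect_equal(circadian_factor(tt, th), circadian_factor(tt + 24, th))
  # mean over any full period is 1
  m <- stats::integrate(function(t) circadian_factor(t, th), 3, 27)$value / 24
  expect_equal(m, 1, tolerance = 1e-9)
  # amplitude at or beyond 1 would allow negative clearance
  expect_error(theta_set(cl_pop = 23, theta_circadian = 1), "amplitude")
})

test_that("transit-chain input matches the closed form and conserves dose", {
  p1 <- list(mtt = 1, n_transit = 1, f = 1)
  expect_equal(transit_input_rate(0.5, 100, p1), 100 * 2 * 1 * exp(-1),
               tolerance = 1e-12)
  expect_equal(transit_input_rate(0, 100, p1), 0)

  # mass conservation for the published absorption parameters
  p <- list(mtt = 1.88, n_transit = 6.58, f = 1)
  total <- stats::integrate(function(t) transit_input_rate(t, 400, p),
                            0, 50 * p$mtt, rel.tol = 1e-10)$value
  expect_equal(total, 400, tolerance = 1e-6)
  expect_error(transit_input_rate(1, 100, list(mtt = -1, n_transit = 1, f = 1)),
               "mtt")
})

test_that("compiled integrator agrees with an independent deSolve solution", {
  skip_if_not_installed("deSolve")
  th <- final_theta
  tp <- typical_params(data.frame(age = 45, cml = 1), th)
  doses <- expand_regimen(regimen(300, 12, 5))
  times <- c(0.5, 1, 3, 6, 12, 24, 36, 48, 60)

  prof <- simulate_profile(tp, th, doses, times)

  ref <- deSolve::ode(
    y = c(0, 0, 0, 0), times = c(0, times),
    func = function(t, y, p) ode_rhs(t, y, tp, th, doses),
    parms = NULL, rtol = 1e-10, atol = 1e-10
  )
  ref_conc <- ref[-1, 3] / tp$vc * 1000
  expect_equal(prof$conc, unname(ref_conc), tolerance = 1e-6)
})

test_that("disposition matches the biexponential closed form and conserves mass", {
  # amplitude zero + a bolus straight into the central compartment
  th0 <- theta_set(cl_pop = 23, theta_circadian = 0)
  tp <- typical_params(data.frame(age = 31, cml = 1), th0)
  sp <- secondary_params(tp)
  tt <- c(0.5, 2, 8, 24, 72, 120)
  prof <- simulate_profile(tp, th0, tibble::tibble(time = numeric(0),
                                                   amount = numeric(0)),
                           times = tt, init = c(0, 100, 0))
  A <- 100 / tp$vc * (sp$alpha - sp$k21) / (sp$alpha - sp$beta) * 1000
  B <- 100 / tp$vc * (sp$k21 - sp$beta) / (sp$alpha - sp$beta) * 1000
  expect_equal(prof$conc, A * exp(-sp$alpha * tt) + B * exp(-sp$beta * tt),
               tolerance = 1e-6)

  # oral dose: all states plus eliminated mass account for the full dose
  th <- final_theta
  prof2 <- simulate_profile(typical_params(data.frame(age = 31, cml = 1), th),
                            th, tibble::tibble(time = 0, amount = 400),
                            times = c(12, 48, 150))
  total <- prof2$a_abs + prof2$a_central + prof2$a_peripheral + prof2$a_elim
  expect_equal(total, rep(400, 3), tolerance = 1e-7)

  # zero state, no doses: nothing moves
  prof0 <- simulate_profile(tp, th, tibble::tibble(time = numeric(0),
                                                   amount = numeric(0)),
                            times = c(1, 10))
  expect_equal(prof0$conc, c(0, 0))
})

test_that("secondary parameters reproduce the published half-lives and total volume", {
  th <- final_theta
  pat <- secondary_params(typical_params(data.frame(age = 31, cml = 1), th))
  expect_equal(round(pat$t_half_beta, 1), 28.8)
  expect_equal(pat$v_total, 902)
  expect_gt(pat$alpha, pat$beta)

  hv <- secondary_params(typical_params(data.frame(age = 31, cml = 0), th))
  expect_equal(round(hv$t_half_beta, 1), 18.2)

  # disconnected peripheral compartment: mono-exponential limit
  mono <- secondary_params(tibble::tibble(cl = 23, vc = 383, q = 0, vp = 519))
  expect_equal(mono$t_half_beta, log(2) * 383 / 23, tolerance = 1e-12)
  expect_equal(round(mono$t_half_beta, 2), 11.54)
})

test_that("with no circadian term, single-dose AUC to infinity equals dose over clearance", {
  th0 <- theta_set(cl_pop = 23, theta_circadian = 0)
  tp <- typical_params(data.frame(age = 31, cml = 1), th0)
  t_half <- secondary_params(tp)$t_half_beta
  tt <- seq(0, 10 * t_half, by = 0.25)
  prof <- simulate_profile(tp, th0, tibble::tibble(time = 0, amount = 400), tt)
  auc <- auc_trapezoid(prof$time, prof$conc) +
    prof$conc[length(tt)] / (log(2) / t_half)
  expect_equal(auc, 400 / 23 * 1000, tolerance = 5e-3)
  expect_true(all(prof$conc >= 0))
})
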