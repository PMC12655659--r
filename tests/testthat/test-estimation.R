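test_that("with no random effects the objective reduces to extended least squares", {
  th <- final_theta
  none <- variance_spec(sigma_prop = 0.2)
  tt <- c(1, 4, 12)
  f <- typical_conc(tt)
  tab <- toy_subject(tt, dv = f)

  # y = f: only the log-variance terms remain
  ofv <- foce_objective(tab, th, none)
  expect_equal(as.numeric(ofv), sum(log(0.2^2 * f^2)), tolerance = 1e-6)

  # and a single perturbed observation adds its squared weighted residual
  tab2 <- toy_subject(tt, dv = f * c(1.1, 1, 1))
  ofv2 <- foce_objective(tab2, th, none)
  expect_equal(as.numeric(ofv2 - ofv),
               (0.1 * f[1])^2 / (0.2^2 * f[1]^2), tolerance = 1e-3)

  # empirical Bayes on a no-variance model returns an empty eta vector
  ebe <- inner_ebe(tab, th, none)
  expect_length(ebe$eta, 0)
})

test_that("the eta mode matches a brute-force grid search on a one-eta toy", {
  th <- final_theta
  spec <- cl_only_variance()
  tt <- c(1, 4, 12, 24)
  f_true <- typical_conc(tt)
  # data generated at eta_cl = 0.3, no noise: the MAP eta shrinks toward 0
  f_shift <- {
    tp <- typical_params(data.frame(age = 31, cml = 1), th)
    tp$cl <- tp$cl * exp(0.3)
    simulate_profile(tp, th, tibble::tibble(time = 0, amount = 400), tt)$conc
  }
  tab <- toy_subject(tt, dv = f_shift)
  ebe <- inner_ebe(tab, th, spec)

  # independent oracle: profile the conditional objective on a fine grid,
  # computing predictions through the public simulation surface
  grid <- seq(-0.8, 0.8, by = 1e-3)
  obj <- vapply(grid, function(e) {
    tp <- typical_params(data.frame(age = 31, cml = 1), th)
    tp$cl <- tp$cl * exp(e)
    f <- simulate_profile(tp, th, tibble::tibble(time = 0, amount = 400), tt)$conc
    v <- 0.2^2 * f^2
    sum((f_shift - f)^2 / v + log(v)) + e^2 / 0.389^2
  }, numeric(1))
  eta_grid <- grid[which.min(obj)]
  expect_equal(unname(ebe$eta["eta_cl"]), eta_grid, tolerance = 1e-3)
  expect_gt(eta_grid, 0.1)
  expect_lt(eta_grid, 0.3) # shrinkage

  # an observation right at the typical prediction gives eta about zero
  tab0 <- toy_subject(tt[1], dv = f_true[1])
  expect_lt(abs(inner_ebe(tab0, th, spec)$eta["eta_cl"]), 5e-3)
})

test_that("FOCE-I agrees with adaptive-quadrature marginal likelihood on one-eta toys", {
  th <- final_theta
  tt <- c(1, 4, 12)
  for (case in list(list(eta = 0.25, omega = 0.389, sigma = 0.2),
                    list(eta = -0.4, omega = 0.6, sigma = 0.15))) {
    spec <- cl_only_variance(omega_cl = case$omega, sigma_prop = case$sigma)
    tp <- typical_params(data.frame(age = 31, cml = 1), th)
    tp$cl <- tp$cl * exp(case$eta)
    y <- simulate_profile(tp, th, tibble::tibble(time = 0, amount = 400),
                          tt)$conc * (1 + c(0.05, -0.12, 0.08))
    tab <- toy_subject(tt, dv = y)

    ofv_foce <- as.numeric(foce_objective(tab, th, spec))

    # oracle: integrate the conditional likelihood against the eta prior;
    # the n log(2 pi) constant cancels by construction
    integrand <- function(e) {
      vapply(e, function(ei) {
        tpe <- typical_params(data.frame(age = 31, cml = 1), th)
        tpe$cl <- tpe$cl * exp(ei)
        f <- simulate_profile(tpe, th, tibble::tibble(time = 0, amount = 400),
                              tt)$conc
        v <- case$sigma^2 * f^2
        exp(-0.5 * sum((y - f)^2 / v + log(v))) * dnorm(ei, 0, case$omega)
      }, numeric(1))
    }
    ofv_exact <- -2 * log(stats::integrate(integrand, -3, 3,
                                           rel.tol = 1e-9)$value)
    expect_equal(ofv_foce, ofv_exact, tolerance = 0.02 * abs(ofv_exact))
  }
})

test_that("objective bookkeeping: fixed fits, subject-order invariance, local minimum", {
  th <- final_theta
  spec <- cl_only_variance()
  tab <- generate_study(th, spec, design = tiny_design(), seed = 21)

  # all parameters fixed: the fit is a single objective evaluation
  fit <- fit_foce(tab, th, spec, free = character(0))
  expect_equal(fit$ofv, as.numeric(foce_objective(tab, th, spec, rtol = 1e-5)),
               tolerance = 1e-6)
  expect_equal(fit$n_eval, 1L)

  # OFV does not depend on subject ordering
  ids <- unique(tab$ID)
  shuffled <- event_table(dplyr::bind_rows(
    lapply(rev(ids), function(i) tab[tab$ID == i, ])
  ))
  expect_equal(as.numeric(foce_objective(shuffled, th, spec)),
               as.numeric(foce_objective(tab, th, spec)), tolerance = 1e-6)

  # on noise-free data generated at the initial values, the initial OFV is a
  # local minimum over single-parameter perturbations
  quiet <- variance_spec(sigma_prop = 1e-3)
  clean <- generate_study(th, variance_spec(), design = tiny_design(), seed = 3)
  ofv0 <- as.numeric(foce_objective(clean, th, quiet))
  for (fac in c(0.9, 1.1)) {
    th_p <- th
    th_p$cl_pop <- th$cl_pop * fac
    expect_gt(as.numeric(foce_objective(clean, th_p, quiet)), ofv0)
  }
})

test_that("CWRES vanish on noise-free typical data and shrink residual structure", {
  th <- final_theta
  quiet <- variance_spec(sigma_prop = 0.05)
  clean <- generate_study(th, variance_spec(), design = tiny_design(), seed = 9)
  fit <- fit_foce(clean, th, quiet, free = character(0))
  cw <- cwres(clean, fit)
  expect_equal(nrow(cw), sum(clean$EVID == 0 & clean$MDV == 0))
  expect_lt(max(abs(cw$CWRES)), 1e-3)
  expect_equal(cw$IPRED, cw$DV, tolerance = 1e-5)

  # population predictions use eta = 0: they match a direct typical-value
  # simulation for one subject
  g <- gof_table(clean, fit)
  one <- clean[clean$ID == 1 & clean$EVID == 0 & clean$MDV == 0, ]
  direct <- typical_conc(one$TIME, cml = one$CML[1], age = one$AGE[1],
                         dose_mg = 400)
  expect_equal(g$PRED[g$ID == 1], direct, tolerance = 1e-5)
})
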