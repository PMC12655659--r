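test_that("eta draws honor the variance spec and the seed contract", {
  degenerate <- variance_spec()
  e0 <- draw_etas(50, degenerate, n_occasions = 2, seed = 1)
  expect_true(all(as.matrix(e0[, -1]) == 0))

  spec <- final_variance
  e1 <- draw_etas(10000, spec, n_occasions = 2, seed = 7)
  expect_equal(sd(e1$eta_cl), 0.389, tolerance = 0.02)
  expect_equal(sd(e1$eta_mtt), 0.316, tolerance = 0.02)
  expect_equal(sd(e1$eta_iov_2), 0.698, tolerance = 0.02)
  expect_equal(sd(e1$eta_vc), 0)

  e2 <- draw_etas(10000, spec, n_occasions = 2, seed = 7)
  expect_identical(e1, e2)

  # IOV is drawn independently per occasion
  expect_lt(abs(cor(e1$eta_iov_1, e1$eta_iov_2)), 0.05)
})

test_that("packaged variability estimates square to the fixed variances", {
  spec <- final_variance
  expect_equal(spec$omega_mtt^2, 0.1, tolerance = 2e-3)
  expect_equal(spec$omega_n^2, 0.2, tolerance = 2e-3)
  expect_false(isTRUE(spec$estimated["omega_mtt"]))
  expect_true(isTRUE(spec$estimated[["omega_cl"]]))
})

test_that("individual realization applies the log-normal links", {
  th <- final_theta
  typ <- typical_params(data.frame(age = c(31, 40), cml = c(1, 0)), th)
  zero <- draw_etas(2, variance_spec(), n_occasions = 1)
  expect_equal(realize_individual(typ, zero, 1), typ)

  etas <- zero
  etas$eta_cl <- c(log(2), 0)
  ind <- realize_individual(typ, etas, 1)
  expect_equal(ind$cl, typ$cl * c(2, 1))
  expect_equal(ind$vc, typ$vc)

  # an IOV draw moves vc and vp together, occasion by occasion
  spec <- final_variance
  e2 <- draw_etas(1, spec, n_occasions = 2, seed = 3)
  d1 <- realize_individual(typ[1, ], e2, 1)
  d2 <- realize_individual(typ[1, ], e2, 2)
  expect_equal(d1$vc / typ$vc[1], d1$vp / typ$vp[1])
  expect_false(isTRUE(all.equal(d1$vc, d2$vc)))

  # median of the realized clearance stays at the typical value
  many <- draw_etas(40000, spec, n_occasions = 1, seed = 11)
  big <- realize_individual(typ[rep(1, 40000), ], many, 1)
  expect_equal(median(big$cl) / typ$cl[1], 1, tolerance = 0.02)
})

test_that("proportional residual error has the stated coefficient of variation", {
  spec <- final_variance
  y <- apply_residual_error(rep(1000, 40000), spec, seed = 5)
  expect_equal(sd(y) / mean(y), 0.20, tolerance = 0.02)
  expect_equal(mean(y), 1000, tolerance = 5)

  none <- variance_spec()
  expect_equal(apply_residual_error(c(0, 10, 500), none), c(0, 10, 500),
               ignore_attr = TRUE)
  # zero concentration never acquires noise
  expect_equal(unique(as.numeric(apply_residual_error(rep(0, 100), spec))), 0)
})

test_that("eta log prior matches the normal density and integrates to one", {
  spec <- variance_spec(omega_cl = 1)
  expect_equal(eta_log_density(c(eta_cl = 0), spec), -0.5 * log(2 * pi))
  expect_equal(eta_log_density(c(eta_cl = 0.7), spec),
               eta_log_density(c(eta_cl = -0.7), spec))

  spec2 <- variance_spec(omega_cl = 0.389, omega_mtt = 0.316)
  total <- stats::integrate(function(x) {
    vapply(x, function(xi) exp(eta_log_density(c(eta_cl = xi), spec2)),
           numeric(1))
  }, -Inf, Inf)$value
  expect_equal(total, 1, tolerance = 1e-6)

  # a zero-variance component cannot carry a non-zero eta
  expect_identical(eta_log_density(c(eta_vc = 0.1), spec2), -Inf)
  expect_equal(eta_log_density(c(eta_vc = 0), spec2), 0)
})
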