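test_that("VPC bands collapse and degenerate as the simulation model dictates", {
  th <- final_theta
  tab <- generate_study(th, cl_only_variance(), design = tiny_design(),
                        seed = 41)

  # a single replicate: the band medians are that replicate's percentiles
  v1 <- vpc(tab, th, cl_only_variance(), n_sim = 1, seed = 2)
  expect_equal(v1$bands$sim_p50_med, v1$bands$sim_p50_lo)
  expect_equal(v1$bands$sim_p50_med, v1$bands$sim_p50_hi)

  # a zero-variance model gives identical replicates (zero-width confidence
  # bands), and with homogeneous covariates every percentile coincides
  v0 <- vpc(tab, th, variance_spec(), n_sim = 5, seed = 2)
  expect_equal(v0$bands$sim_p05_lo, v0$bands$sim_p05_hi, tolerance = 1e-10)
  expect_equal(v0$bands$sim_p50_lo, v0$bands$sim_p50_hi, tolerance = 1e-10)

  homog <- generate_study(th, variance_spec(), design = tiny_design(4, 0),
                          seed = 42)
  homog$AGE <- 30
  vh <- vpc(event_table(homog), th, variance_spec(), n_sim = 3, seed = 2)
  expect_equal(vh$bands$sim_p05_med, vh$bands$sim_p95_med, tolerance = 1e-10)

  # band ordering and coverage bounds always hold
  v <- vpc(tab, th, cl_only_variance(), n_sim = 40, seed = 3)
  expect_true(all(v$bands$sim_p05_med <= v$bands$sim_p50_med))
  expect_true(all(v$bands$sim_p50_med <= v$bands$sim_p95_med))
  expect_gte(v$coverage, 0)
  expect_lte(v$coverage, 1)
})

test_that("bootstrap preserves cohort sizes, is seeded, and degenerates to zero width", {
  th <- final_theta
  spec <- cl_only_variance()
  tab <- generate_study(th, spec, design = tiny_design(4, 5), seed = 51)

  b <- bootstrap_fit(tab, th, spec, n_boot = 3, seed = 8, free = "cl_pop",
                     control = list(maxit = 60))
  cml_of <- tab |>
    dplyr::distinct(ID, CML)
  for (ids in b$resampled_ids) {
    expect_length(ids, 9)
    expect_equal(sum(cml_of$CML[match(ids, cml_of$ID)] == 0), 4)
    expect_equal(sum(cml_of$CML[match(ids, cml_of$ID)] == 1), 5)
  }

  b2 <- bootstrap_fit(tab, th, spec, n_boot = 3, seed = 8, free = "cl_pop",
                      control = list(maxit = 60))
  expect_identical(b$resampled_ids, b2$resampled_ids)
  expect_equal(b$estimates, b2$estimates)

  # all-identical subjects: every resample is the same dataset
  one <- tab[tab$ID == tab$ID[1], ]
  clones <- event_table(dplyr::bind_rows(lapply(1:3, function(i) {
    d <- one; d$ID <- i; d
  })))
  b3 <- bootstrap_fit(clones, th, spec, n_boot = 3, seed = 1, free = "cl_pop",
                      control = list(maxit = 60))
  expect_equal(b3$summary$ci_lo, b3$summary$ci_hi, tolerance = 1e-8)
})

test_that("the goodness-of-fit table separates population and individual predictions", {
  th <- final_theta
  spec <- cl_only_variance()
  tab <- generate_study(th, spec, design = tiny_design(3, 3), seed = 61)
  fit <- fit_foce(tab, th, spec, free = character(0))
  g <- gof_table(tab, fit)
  expect_equal(nrow(g), sum(tab$EVID == 0 & tab$MDV == 0))
  # individual predictions absorb the subject's eta, population ones do not
  err_pop <- mean(abs(g$DV - g$PRED) / pmax(g$PRED, 1))
  err_ind <- mean(abs(g$DV - g$IPRED) / pmax(g$IPRED, 1))
  expect_lt(err_ind, err_pop)
})
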