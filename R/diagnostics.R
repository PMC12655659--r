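#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the observed design (same subjects, doses,
#' sampling times, covariates and occasion structure; etas, IOV and residual
#' error redrawn each replicate), then compares observed concentration
#' percentiles with the simulated percentile bands, stratified by occasion
#' and binned at the nominal sampling times. Also reports the fraction of
#' observations falling inside the simulated 90% prediction interval
#' (pooled 5th-95th percentiles per bin).
#'
#' @param data An [event_table()] with observation records.
#' @param theta A [theta_set()].
#' @param variance A [variance_spec()].
#' @param n_sim Number of simulated replicates.
#' @param seed Optional integer seed for an isolated RNG scope.
#' @param probs Percentiles tracked (default 5/50/95).
#' @param rtol Integrator relative tolerance.
#' @return A list of class `radpk_vpc`: `bands` (per occasion x time:
#'   observed percentiles, simulated medians of each percentile with 95%
#'   confidence bands, pooled prediction-interval bounds), `coverage`
#'   (fraction of observations inside the 90% PI), `n_sim`.
#' @export
vpc <- function(data, theta, variance, n_sim = 1000, seed = NULL,
                probs = c(0.05, 0.5, 0.95), rtol = 1e-6) {
  subjects <- prepare_subjects(data)
  n_obs <- vapply(subjects, function(s) nrow(s$obs), integer(1))
  if (sum(n_obs) == 0) abort("`data` has no usable observations.")

  design <- purrr::map_dfr(subjects, function(s) {
    tibble(ID = s$id, TIME = s$obs$TIME, OCC = s$obs$OCC, DV = s$obs$DV)
  })

  typs <- lapply(subjects, typ_for_subject, theta = theta)
  run <- function() {
    sims <- purrr::map_dfr(seq_len(n_sim), function(r) {
      dv <- unlist(lapply(seq_along(subjects), function(i) {
        s <- subjects[[i]]
        if (nrow(s$obs) == 0) return(numeric(0))
        etas <- draw_etas(1, variance, n_occasions = max(s$occasions))
        eta <- unlist(etas[1, setdiff(names(etas), "subject")])
        f <- predict_subject(s, theta, variance, eta, typs[[i]], rtol = rtol)
        suppressWarnings(as.numeric(apply_residual_error(pmax(f, 0), variance)))
      }))
      tibble(replicate = r, ID = design$ID, TIME = design$TIME,
             OCC = design$OCC, sim = dv)
    })
    sims
  }
  sims <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  obs_bands <- design |>
    group_by(.data$OCC, .data$TIME) |>
    summarise(
      obs_p05 = unname(quantile(.data$DV, probs[1])),
      obs_p50 = unname(quantile(.data$DV, probs[2])),
      obs_p95 = unname(quantile(.data$DV, probs[3])),
      n_obs = dplyr::n(), .groups = "drop"
    )

  rep_pct <- sims |>
    group_by(.data$replicate, .data$OCC, .data$TIME) |>
    summarise(
      p05 = unname(quantile(.data$sim, probs[1])),
      p50 = unname(quantile(.data$sim, probs[2])),
      p95 = unname(quantile(.data$sim, probs[3])),
      .groups = "drop"
    )
  sim_bands <- rep_pct |>
    group_by(.data$OCC, .data$TIME) |>
    summarise(
      dplyr::across(c("p05", "p50", "p95"),
                    list(med = median,
                         lo = ~ unname(quantile(.x, 0.025)),
                         hi = ~ unname(quantile(.x, 0.975))),
                    .names = "sim_{.col}_{.fn}"),
      .groups = "drop"
    )
  pi_bounds <- sims |>
    group_by(.data$OCC, .data$TIME) |>
    summarise(pi_lo = unname(quantile(.data$sim, probs[1])),
              pi_hi = unname(quantile(.data$sim, probs[3])), .groups = "drop")

  bands <- obs_bands |>
    left_join(sim_bands, by = c("OCC", "TIME")) |>
    left_join(pi_bounds, by = c("OCC", "TIME"))

  inside <- design |>
    left_join(pi_bounds, by = c("OCC", "TIME")) |>
    mutate(inside = .data$DV >= .data$pi_lo & .data$DV <= .data$pi_hi)

  structure(list(bands = bands, coverage = mean(inside$inside),
                 observed = design, n_sim = n_sim),
            class = "radpk_vpc")
}

#' @export
print.radpk_vpc <- function(x, ...) {
  cat(sprintf("<radpk_vpc>  %d simulated replicates; %.1f%% of observations inside the 90%% PI\n",
              x$n_sim, 100 * x$coverage))
  invisible(x)
}

#' @export
tidy.radpk_vpc <- function(x, ...) x$bands

#' Nonparametric bootstrap of the model fit
#'
#' Resamples subjects with replacement — within disease-status strata, so
#' every replicate keeps the original number of healthy volunteers and
#' patients — refits the model on each replicate (warm-started at the
#' original estimates), and summarizes the replicate estimates as medians
#' with percentile 95% confidence intervals. Replicates whose fit fails are
#' excluded and counted; more than 20% failures raises a warning.
#'
#' @param data An [event_table()].
#' @param theta,variance Starting model ([theta_set()], [variance_spec()]),
#'   typically the final estimates.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed for an isolated RNG scope.
#' @param stratify Resample within CML strata (recommended).
#' @param free,extra_effects,rtol,control Passed to [fit_foce()].
#' @return A list of class `radpk_boot`: `estimates` (tibble of per-replicate
#'   parameter estimates), `summary` (median and 95% CI per parameter),
#'   `n_failed`, `resampled_ids` (list of the id multisets used).
#' @export
bootstrap_fit <- function(data, theta, variance, n_boot = 1000, seed = NULL,
                          stratify = TRUE,
                          free = c("cl_pop", "omega_cl", "sigma_prop"),
                          extra_effects = NULL, rtol = 1e-5, control = list()) {
  subj <- as_tibble(data) |>
    group_by(.data$ID) |>
    slice(1) |>
    ungroup()
  run <- function() {
    out <- vector("list", n_boot)
    id_sets <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      ids <- if (stratify) {
        unlist(lapply(split(subj$ID, subj$CML), function(g) {
          sample(g, length(g), replace = TRUE)
        }), use.names = FALSE)
      } else {
        sample(subj$ID, nrow(subj), replace = TRUE)
      }
      id_sets[[b]] <- ids
      rep_data <- purrr::map_dfr(seq_along(ids), function(j) {
        d <- data[data$ID == ids[j], , drop = FALSE]
        d$ID <- j
        d
      })
      fit <- tryCatch(
        fit_foce(event_table(rep_data), theta, variance, free = free,
                 extra_effects = extra_effects, rtol = rtol, control = control),
        error = function(e) NULL
      )
      if (!is.null(fit)) {
        est <- free_start_values(fit$theta, fit$variance, fit$extra_effects, free)
        out[[b]] <- dplyr::bind_cols(tibble(replicate = b),
                                     as_tibble(as.list(est)))
      }
    }
    list(estimates = dplyr::bind_rows(out), ids = id_sets)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  n_failed <- n_boot - nrow(res$estimates)
  if (n_failed > 0.2 * n_boot) {
    warn(sprintf("%d of %d bootstrap replicates failed to fit.", n_failed, n_boot))
  }
  est_long <- res$estimates |>
    tidyr::pivot_longer(-"replicate", names_to = "parameter",
                        values_to = "estimate")
  summary <- est_long |>
    group_by(.data$parameter) |>
    summarise(median = median(.data$estimate),
              ci_lo = unname(quantile(.data$estimate, 0.025)),
              ci_hi = unname(quantile(.data$estimate, 0.975)),
              n = dplyr::n(), .groups = "drop")
  structure(list(estimates = res$estimates, summary = summary,
                 n_failed = n_failed, resampled_ids = res$ids),
            class = "radpk_boot")
}

#' @export
print.radpk_boot <- function(x, ...) {
  cat(sprintf("<radpk_boot>  %d successful replicate(s), %d failed\n",
              nrow(x$estimates), x$n_failed))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.radpk_boot <- function(x, ...) x$summary
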