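#' Tidy a fitted population model
#'
#' One row per model parameter with its value, whether it was estimated, and
#' (when available) the relative standard error.
#'
#' @param x A `radpk_fit`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `estimate`, `type`, `fixed`,
#'   and `rse_percent`.
#' @export
tidy.radpk_fit <- function(x, ...) {
  th <- x$theta
  vs <- x$variance
  free <- if (!is.null(x$rse)) x$rse$parameter else character(0)
  rows <- dplyr::bind_rows(
    purrr::map_dfr(setdiff(names(th), NULL), function(nm) {
      tibble(parameter = nm, estimate = th[[nm]], type = "theta")
    }),
    purrr::map_dfr(omega_names(), function(nm) {
      tibble(parameter = nm, estimate = vs[[nm]], type = "variance")
    }),
    purrr::map_dfr(x$extra_effects, function(e) {
      tibble(parameter = e$name, estimate = e$theta, type = "covariate_effect")
    })
  )
  if (!is.null(x$rse)) {
    rows <- left_join(rows, x$rse[, c("parameter", "rse_percent")],
                      by = "parameter")
  } else {
    rows$rse_percent <- NA_real_
  }
  rows
}

#' Model-level summary of a fit
#'
#' @param x A `radpk_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `ofv`, `n_subjects`, `n_obs`, `convergence`,
#'   `n_eval`.
#' @export
glance.radpk_fit <- function(x, ...) {
  tibble(
    ofv = x$ofv,
    n_subjects = length(x$subjects),
    n_obs = sum(vapply(x$subjects, function(s) nrow(s$obs), integer(1))),
    convergence = x$convergence,
    n_eval = x$n_eval
  )
}
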