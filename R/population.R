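#' Draw subject-level random effects
#'
#' Independent zero-mean normal draws on the log scale: one IIV eta per
#' structural parameter per subject, and one IOV eta per subject-occasion
#' (shared by Vc/F and Vp/F unless the spec says otherwise). Components with a
#' zero standard deviation are exactly 0.
#'
#' @param n_subjects Number of subjects.
#' @param spec A [variance_spec()].
#' @param n_occasions Number of occasions per subject (IOV etas drawn per
#'   occasion).
#' @param seed Optional integer seed; when given, draws are made in an
#'   isolated RNG scope so the global stream is untouched.
#' @return A tibble with one row per subject: `subject`, `eta_cl`, `eta_vc`,
#'   `eta_q`, `eta_vp`, `eta_ka`, `eta_mtt`, `eta_n`, and `eta_iov_1` ..
#'   `eta_iov_<n_occasions>` (plus `eta_iov_vp_*` when `iov_shared` is
#'   `FALSE`).
#' @export
draw_etas <- function(n_subjects, spec, n_occasions = 1, seed = NULL) {
  stopifnot(inherits(spec, "variance_spec"))
  draw <- function() {
    out <- tibble(subject = seq_len(n_subjects))
    for (p in c("cl", "vc", "q", "vp", "ka", "mtt", "n")) {
      sd <- spec[[paste0("omega_", p)]]
      out[[paste0("eta_", p)]] <-
        if (sd > 0) rnorm(n_subjects, 0, sd) else rep(0, n_subjects)
    }
    for (k in seq_len(n_occasions)) {
      out[[paste0("eta_iov_", k)]] <-
        if (spec$omega_iov > 0) rnorm(n_subjects, 0, spec$omega_iov) else rep(0, n_subjects)
      if (!spec$iov_shared) {
        out[[paste0("eta_iov_vp_", k)]] <-
          if (spec$omega_iov > 0) rnorm(n_subjects, 0, spec$omega_iov) else rep(0, n_subjects)
      }
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Realize individual parameters from typical values and etas
#'
#' Applies the log-normal random-effect links of the model: `cl`, `mtt` and
#' `n_transit` are multiplied by `exp(eta)`; `vc` and `vp` by the occasion's
#' IOV multiplier `exp(eta_iov_<occasion>)`; `q`, `ka` and `f` carry no
#' random effect in the final model (their etas, if drawn, are applied the
#' same way and are 0 under the packaged spec).
#'
#' @param typical Tibble of typical parameters ([typical_params()] output),
#'   one row per subject.
#' @param etas Tibble from [draw_etas()] with the same number of rows.
#' @param occasion Occasion id (scalar or one per subject) selecting the IOV
#'   column.
#' @return A tibble of realized individual parameters, same columns as
#'   `typical`.
#' @export
realize_individual <- function(typical, etas, occasion = 1) {
  typical <- as_tibble(typical)
  etas <- as_tibble(etas)
  if (nrow(typical) != nrow(etas)) {
    abort("`typical` and `etas` must have the same number of rows.")
  }
  occasion <- rep_len(occasion, nrow(typical))
  out <- typical
  out$cl <- typical$cl * exp(etas$eta_cl)
  out$q <- typical$q * exp(etas$eta_q)
  out$ka <- typical$ka * exp(etas$eta_ka)
  out$mtt <- typical$mtt * exp(etas$eta_mtt)
  out$n_transit <- typical$n_transit * exp(etas$eta_n)
  iov_vc <- iov_eta(etas, occasion, "eta_iov_")
  iov_vp <- if (any(grepl("^eta_iov_vp_", names(etas)))) {
    iov_eta(etas, occasion, "eta_iov_vp_")
  } else {
    iov_vc
  }
  out$vc <- typical$vc * exp(etas$eta_vc + iov_vc)
  out$vp <- typical$vp * exp(etas$eta_vp + iov_vp)
  out
}

iov_eta <- function(etas, occasion, prefix) {
  vapply(seq_along(occasion), function(i) {
    col <- paste0(prefix, occasion[i])
    if (!col %in% names(etas)) {
      abort(sprintf("No IOV eta column `%s`: draw etas with enough occasions.", col))
    }
    etas[[col]][i]
  }, numeric(1))
}

#' Apply proportional residual error
#'
#' Observed concentration `y = c * (1 + eps)` with
#' `eps ~ Normal(0, sigma_prop^2)`. Draws that would produce a negative
#' concentration are truncated at 0; the returned vector carries a
#' `"truncated"` attribute flagging them, and a warning is raised when any
#' truncation happens.
#'
#' @param true_conc Noise-free concentration(s), ng/mL (>= 0).
#' @param spec A [variance_spec()] (only `sigma_prop` is used).
#' @param seed Optional integer seed for an isolated RNG scope.
#' @return Numeric vector of observed concentrations with attribute
#'   `"truncated"`.
#' @export
apply_residual_error <- function(true_conc, spec, seed = NULL) {
  stopifnot(inherits(spec, "variance_spec"))
  if (any(true_conc < 0)) abort("`true_conc` must be >= 0.")
  draw <- function() {
    eps <- rnorm(length(true_conc), 0, spec$sigma_prop)
    y <- true_conc * (1 + eps)
    trunc <- y < 0
    if (any(trunc)) {
      warn(sprintf("%d simulated concentration(s) were negative and truncated at 0.",
                   sum(trunc)))
      y[trunc] <- 0
    }
    attr(y, "truncated") <- trunc
    y
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Log prior density of a set of etas
#'
#' Sum of independent normal log-densities with the standard deviations of a
#' [variance_spec()]; the quantity entering the FOCE inner (empirical Bayes)
#' objective. A zero-variance component evaluated at a non-zero eta has
#' density zero, hence `-Inf`.
#'
#' @param etas Named numeric vector (or one-row data frame) of etas; names
#'   follow [draw_etas()] (`eta_cl`, `eta_mtt`, `eta_n`, `eta_iov_1`, ...).
#' @param spec A [variance_spec()].
#' @return A single numeric log-density.
#' @export
eta_log_density <- function(etas, spec) {
  stopifnot(inherits(spec, "variance_spec"))
  if (is.data.frame(etas)) {
    etas <- unlist(etas[1, setdiff(names(etas), "subject"), drop = FALSE])
  }
  total <- 0
  for (nm in names(etas)) {
    sd <- omega_for_eta(nm, spec)
    if (sd == 0) {
      if (etas[[nm]] != 0) return(-Inf)
    } else {
      total <- total + dnorm(etas[[nm]], 0, sd, log = TRUE)
    }
  }
  total
}

omega_for_eta <- function(name, spec) {
  if (grepl("^eta_iov", name)) return(spec$omega_iov)
  par <- sub("^eta_", "", name)
  sd <- spec[[paste0("omega_", par)]]
  if (is.null(sd)) abort(sprintf("Unknown eta component `%s`.", name))
  sd
}
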