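#' Parameter-covariate relationship forms
#'
#' The standard functional forms for covariate effects on a structural
#' parameter: continuous covariates centered at a reference value enter as
#' `linear` (`1 + theta * (x - ref)`), `power` (`(x / ref)^theta`) or
#' `exponential` (`exp(theta * (x - ref))`) multipliers; categorical
#' indicators as `proportional` (`1 + theta * z`) multipliers or `additive`
#' (`theta * z`) shifts.
#'
#' @param form One of `"linear"`, `"power"`, `"exponential"`,
#'   `"proportional"`, `"additive"`.
#' @param theta Effect coefficient.
#' @param x Covariate value(s) (indicator values for categorical forms).
#' @param center Reference value for continuous forms (commonly the dataset
#'   median); ignored for categorical forms.
#' @return Multiplier (or addend for `"additive"`) vector.
#' @examples
#' covariate_function("linear", -0.0129, 72, 31)  # 0.4711
#' @export
covariate_function <- function(form, theta, x, center = NA) {
  switch(form,
    linear = 1 + theta * (x - center),
    power = {
      if (any(x <= 0) || is.na(center) || center <= 0) {
        abort("Power form needs positive covariate values and a positive center.")
      }
      (x / center)^theta
    },
    exponential = exp(theta * (x - center)),
    proportional = 1 + theta * x,
    additive = theta * x,
    abort(sprintf("Unknown covariate form `%s`.", form))
  )
}

#' Candidate parameter-covariate relationship
#'
#' Describes one testable covariate effect for stepwise covariate modelling:
#' which structural parameter it modifies, which covariate drives it, its
#' functional form, and the centering value for continuous forms.
#'
#' @param parameter Target parameter: `"cl"`, `"vc"` or `"vp"`.
#' @param covariate Covariate column name (event-table dialect, e.g. `"WT"`,
#'   `"CML"`, `"SEX"`).
#' @param form See [covariate_function()]; `linear`/`power`/`exponential`
#'   for continuous covariates, `proportional`/`additive` for categorical.
#' @param center Centering value (continuous forms). `NA` lets [scm()] use
#'   the dataset median.
#' @param theta Starting coefficient (0 = no effect).
#' @return A list of class `radpk_candidate` with a unique `name` used as the
#'   free-parameter label.
#' @export
covariate_candidate <- function(parameter = c("cl", "vc", "vp"), covariate,
                                form = c("linear", "power", "exponential",
                                         "proportional", "additive"),
                                center = NA, theta = 0) {
  parameter <- match.arg(parameter)
  form <- match.arg(form)
  structure(list(parameter = parameter, covariate = covariate, form = form,
                 center = center, theta = theta,
                 name = sprintf("beta_%s_%s", parameter, tolower(covariate))),
            class = "radpk_candidate")
}

#' Derived covariates: body surface area and creatinine clearance
#'
#' Adds `BSA` (Mosteller: `sqrt(height_cm * weight_kg / 3600)`, m^2) and,
#' when a serum creatinine column `SCR` (mg/dL) is present, `CLCR_CG`
#' (Cockcroft-Gault: `(140 - age) * weight / (72 * SCR)`, times 0.85 for
#' females, mL/min). Rows with missing inputs yield `NA` for the derived
#' value.
#'
#' @param data A data frame with `HT`, `WT` (and for Cockcroft-Gault `AGE`,
#'   `SEX`, `SCR`) columns, case-insensitive.
#' @return The input with `BSA` (and `CLCR_CG` when computable) appended.
#' @export
derive_covariates <- function(data) {
  data <- as_tibble(data)
  lookup <- setNames(names(data), tolower(names(data)))
  get <- function(nm) if (nm %in% names(lookup)) data[[lookup[[nm]]]] else NULL
  ht <- get("ht"); wt <- get("wt")
  if (is.null(ht) || is.null(wt)) {
    abort("`data` must contain height (`HT`) and weight (`WT`) columns.")
  }
  if (any(stats::na.omit(ht) <= 0) || any(stats::na.omit(wt) <= 0)) {
    abort("Height and weight must be positive.")
  }
  data$BSA <- sqrt(ht * wt / 3600)
  scr <- get("scr")
  if (!is.null(scr)) {
    age <- get("age"); sex <- get("sex")
    if (is.null(age) || is.null(sex)) {
      warn("Cockcroft-Gault needs `AGE` and `SEX`; `CLCR_CG` not derived.")
    } else {
      data$CLCR_CG <- (140 - age) * wt / (72 * scr) * ifelse(sex == 1, 0.85, 1)
    }
  }
  data
}

#' Stepwise covariate modelling
#'
#' Greedy forward addition followed by backward elimination over a candidate
#' list, refitting the model for every tested candidate. A candidate enters
#' when it gives the largest objective-function drop among those exceeding
#' `forward_dofv` (3.84, chi-square 0.05 with 1 df); after forward selection,
#' included effects are removed one at a time, dropping any whose removal
#' raises the objective by no more than `backward_dofv` (6.63, chi-square
#' 0.01), weakest first. Candidates collinear with an already included
#' covariate (absolute correlation above `collinearity_max` across subjects)
#' are skipped with a note in the trace. Failed candidate fits are skipped
#' likewise.
#'
#' @param data An [event_table()].
#' @param theta Base-model [theta_set()] (typically without the covariate
#'   effects under test).
#' @param variance Base-model [variance_spec()].
#' @param candidates List of [covariate_candidate()] objects.
#' @param free_base Free parameters of the base model, passed to
#'   [fit_foce()]; each tested model adds the candidate coefficients.
#' @param forward_dofv,backward_dofv Inclusion / retention thresholds on the
#'   objective-function change.
#' @param collinearity_max Correlation guard threshold.
#' @param rtol,control Passed to [fit_foce()].
#' @return A list of class `radpk_scm`: `final_fit`, `included` (candidate
#'   list), `trace` (tibble of every decision), `base_ofv`.
#' @export
scm <- function(data, theta, variance, candidates,
                free_base = c("cl_pop", "omega_cl", "sigma_prop"),
                forward_dofv = 3.84, backward_dofv = 6.63,
                collinearity_max = 0.9, rtol = 1e-5, control = list()) {
  subj_covs <- as_tibble(data) |>
    group_by(.data$ID) |>
    slice(1) |>
    ungroup()
  candidates <- lapply(candidates, function(cand) {
    if (cand$form %in% c("linear", "power", "exponential") && is.na(cand$center)) {
      cand$center <- median(subj_covs[[cand$covariate]], na.rm = TRUE)
    }
    cand
  })

  trace <- list()
  note <- function(phase, step, cand, ofv_ref, ofv_new, decision) {
    trace[[length(trace) + 1]] <<- tibble(
      step = step, phase = phase,
      parameter = cand$parameter, covariate = cand$covariate, form = cand$form,
      ofv_ref = ofv_ref, ofv_new = ofv_new,
      delta_ofv = ofv_ref - ofv_new, decision = decision
    )
  }

  fit_with <- function(effects, extra_free = character(0)) {
    fit_foce(data, theta, variance,
             free = c(free_base, vapply(effects, `[[`, "", "name"), extra_free),
             extra_effects = effects, rtol = rtol, control = control)
  }

  base_fit <- fit_foce(data, theta, variance, free = free_base, rtol = rtol,
                       control = control)
  base_ofv <- base_fit$ofv
  included <- list()
  current_fit <- base_fit
  remaining <- candidates
  step <- 0

  # forward addition
  repeat {
    step <- step + 1
    results <- lapply(remaining, function(cand) {
      for (inc in included) {
        if (cand$covariate != inc$covariate) {
          r <- suppressWarnings(
            stats::cor(subj_covs[[cand$covariate]], subj_covs[[inc$covariate]])
          )
          if (is.finite(r) && abs(r) > collinearity_max) {
            note("forward", step, cand, current_fit$ofv, NA_real_,
                 sprintf("skipped: |cor| with %s > %.1f", inc$covariate,
                         collinearity_max))
            return(NULL)
          }
        }
      }
      f <- tryCatch(fit_with(c(included, list(cand))), error = function(e) NULL)
      if (is.null(f)) {
        note("forward", step, cand, current_fit$ofv, NA_real_, "skipped: fit failed")
        return(NULL)
      }
      list(cand = cand, fit = f)
    })
    results <- purrr::compact(results)
    if (length(results) == 0) break
    dofv <- vapply(results, function(r) current_fit$ofv - r$fit$ofv, numeric(1))
    best <- which.max(dofv)
    for (i in seq_along(results)) {
      note("forward", step, results[[i]]$cand, current_fit$ofv,
           results[[i]]$fit$ofv,
           if (i == best && dofv[i] > forward_dofv) "added"
           else if (dofv[i] > forward_dofv) "candidate (not best)"
           else "not significant")
    }
    if (dofv[best] <= forward_dofv) break
    added <- results[[best]]$cand
    added$theta <- results[[best]]$fit$extra_effects[[
      which(vapply(results[[best]]$fit$extra_effects, `[[`, "", "name") == added$name)
    ]]$theta
    included <- c(included, list(added))
    current_fit <- results[[best]]$fit
    remaining <- purrr::discard(remaining, function(cand) cand$name == added$name)
    if (length(remaining) == 0) break
  }

  # backward elimination, weakest effect first
  repeat {
    if (length(included) == 0) break
    step <- step + 1
    drops <- lapply(seq_along(included), function(i) {
      kept <- included[-i]
      f <- tryCatch(
        if (length(kept) == 0) {
          base_fit # removing the only effect recovers the base model
        } else {
          fit_with(kept)
        },
        error = function(e) NULL
      )
      list(cand = included[[i]], fit = f)
    })
    rise <- vapply(drops, function(d) {
      if (is.null(d$fit)) Inf else d$fit$ofv - current_fit$ofv
    }, numeric(1))
    weakest <- which.min(rise)
    for (i in seq_along(drops)) {
      note("backward", step, drops[[i]]$cand, current_fit$ofv,
           if (is.null(drops[[i]]$fit)) NA_real_ else drops[[i]]$fit$ofv,
           if (i == weakest && rise[i] <= backward_dofv) "removed"
           else if (rise[i] > backward_dofv) "retained"
           else "removable (not weakest)")
    }
    if (rise[weakest] > backward_dofv) break
    current_fit <- drops[[weakest]]$fit
    included <- included[-weakest]
  }

  structure(list(final_fit = current_fit, included = included,
                 trace = dplyr::bind_rows(trace), base_ofv = base_ofv),
            class = "radpk_scm")
}

#' @export
print.radpk_scm <- function(x, ...) {
  cat(sprintf("<radpk_scm>  base OFV %.2f -> final OFV %.2f; %d covariate effect(s) retained\n",
              x$base_ofv, x$final_fit$ofv, length(x$included)))
  for (inc in x$included) {
    cat(sprintf("  %s on %s (%s), coefficient %.4g\n",
                inc$covariate, inc$parameter, inc$form, inc$theta))
  }
  invisible(x)
}

#' @export
tidy.radpk_scm <- function(x, ...) x$trace
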