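#' NONMEM-style event tables
#'
#' An event table is a tibble of per-subject dose and observation records in
#' the conventional NONMEM column dialect:
#'
#' * `ID` subject identifier
#' * `TIME` hours since the subject's first dose (also the time entering the
#'   circadian clearance term)
#' * `AMT` dose amount in mg (0 for observations)
#' * `EVID` event type: 1 = dose, 0 = observation
#' * `DV` observed concentration in ng/mL (missing for doses)
#' * `MDV` missing-DV flag (1 for doses and unusable observations)
#' * `OCC` occasion: 1 = Day 1 (non-steady state), 2 = Day 14 (steady state)
#' * `BLQ` below-quantification flag
#' * covariates: `AGE` (years), `CML` (0 = healthy volunteer, 1 = CML-CP
#'   patient), `SEX` (0 = male, 1 = female), `WT` (kg), `HT` (cm), `ALT`,
#'   `AST` (IU/L), `CLCR` (mL/min)
#'
#' `event_table()` validates a data frame and stamps the class;
#' `read_event_table()` / `write_event_table()` move tables between CSV files
#' (missing values written as `.`), applying a below-quantification policy on
#' the way in.
#'
#' @param data A data frame with the columns above (`BLQ` and covariates
#'   optional on input; missing ones are filled with `NA`/0).
#' @return A tibble of class `radpk_event_table`.
#' @export
event_table <- function(data) {
  data <- as_tibble(data)
  req <- c("ID", "TIME", "AMT", "EVID", "DV", "MDV", "OCC")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Event table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"BLQ" %in% names(data)) data$BLQ <- 0
  for (cv in covariate_columns()) if (!cv %in% names(data)) data[[cv]] <- NA_real_
  data <- data[, c(req, "BLQ", covariate_columns())]
  validate_event_table(data)
  class(data) <- c("radpk_event_table", class(data))
  data
}

covariate_columns <- function() {
  c("AGE", "CML", "SEX", "WT", "HT", "ALT", "AST", "CLCR")
}

validate_event_table <- function(data) {
  bad_time <- which(!is.finite(data$TIME) | data$TIME < 0)
  if (length(bad_time) > 0) {
    abort(sprintf("Row %d: TIME must be a non-negative number (got %s).",
                  bad_time[1], format(data$TIME[bad_time[1]])))
  }
  bad_evid <- which(!data$EVID %in% c(0, 1))
  if (length(bad_evid) > 0) {
    abort(sprintf("Row %d: unknown EVID %s (expected 0 = observation, 1 = dose).",
                  bad_evid[1], format(data$EVID[bad_evid[1]])))
  }
  bad_dose <- which(data$EVID == 1 & (!is.finite(data$AMT) | data$AMT <= 0))
  if (length(bad_dose) > 0) {
    abort(sprintf("Row %d: dose records must have AMT > 0.", bad_dose[1]))
  }
  bad_dose_dv <- which(data$EVID == 1 & !is.na(data$DV) & data$DV != 0)
  if (length(bad_dose_dv) > 0) {
    abort(sprintf("Row %d: dose records must not carry a DV.", bad_dose_dv[1]))
  }
  bad_obs <- which(data$EVID == 0 & data$AMT != 0)
  if (length(bad_obs) > 0) {
    abort(sprintf("Row %d: observation records must have AMT = 0.", bad_obs[1]))
  }
  dec <- data |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$ID) |>
    filter(c(FALSE, diff(.data$TIME) < 0)) |>
    ungroup()
  if (nrow(dec) > 0) {
    abort(sprintf("Row %d: TIME must be non-decreasing within subject %s.",
                  dec$.row[1], format(dec$ID[1])))
  }
  invisible(data)
}

#' Below-quantification (BLQ) handling policy
#'
#' The bioanalytical lower limit of quantification for radotinib is 5 ng/mL.
#' Observations below it are either discarded (`method = "discard"`, the M1
#' convention: the record is kept but flagged `MDV = 1` so it never enters a
#' likelihood) or imputed at half the limit (`method = "fix_at_half"`).
#'
#' @param lloq Lower limit of quantification in ng/mL.
#' @param method One of `"discard"` or `"fix_at_half"`.
#' @return An object of class `lloq_policy`.
#' @export
lloq_policy <- function(lloq = 5, method = c("discard", "fix_at_half")) {
  method <- match.arg(method)
  if (!is.numeric(lloq) || length(lloq) != 1L || lloq <= 0) {
    abort("`lloq` must be a single positive number.")
  }
  structure(list(lloq = lloq, method = method), class = "lloq_policy")
}

#' Apply a BLQ policy to an event table
#'
#' Flags observation records with `DV` below the limit of quantification and
#' either marks them missing or imputes half the limit. Dose records are never
#' touched.
#'
#' @param data An [event_table()].
#' @param policy An [lloq_policy()].
#' @return The event table with `BLQ`, `MDV` (and for `fix_at_half`, `DV`)
#'   updated.
#' @export
apply_lloq <- function(data, policy = lloq_policy()) {
  stopifnot(inherits(policy, "lloq_policy"))
  is_blq <- data$EVID == 0 & !is.na(data$DV) & data$DV < policy$lloq
  data$BLQ <- as.integer(is_blq)
  if (policy$method == "discard") {
    data$MDV[is_blq] <- 1
  } else {
    data$DV[is_blq] <- policy$lloq / 2
  }
  data
}

#' @rdname event_table
#' @param path CSV file path.
#' @param policy An [lloq_policy()] applied after reading
#'   (`NULL` to skip BLQ handling).
#' @export
read_event_table <- function(path, policy = lloq_policy()) {
  data <- readr::read_csv(path, na = c(".", "NA", ""),
                          show_col_types = FALSE, progress = FALSE)
  tab <- event_table(data)
  if (!is.null(policy)) tab <- apply_lloq(tab, policy)
  tab
}

#' @rdname event_table
#' @param x An [event_table()] to write.
#' @export
write_event_table <- function(x, path) {
  validate_event_table(x)
  readr::write_csv(as_tibble(x), path, na = ".", progress = FALSE)
  invisible(path)
}

#' Dosing regimens
#'
#' A regimen is a fixed dose repeated at a fixed interval:
#' `n_doses` administrations of `dose_mg` starting at `first_dose_time`.
#' `expand_regimen()` turns it into explicit dose events.
#'
#' @param dose_mg Dose amount per administration (mg).
#' @param interval_h Dosing interval (h).
#' @param n_doses Number of administrations.
#' @param first_dose_time Time of the first dose (h, default 0).
#' @return `regimen()` returns a `radpk_regimen`; `expand_regimen()` a tibble
#'   with columns `time` and `amount`.
#' @examples
#' expand_regimen(regimen(300, 12, 4))
#' @export
regimen <- function(dose_mg, interval_h, n_doses, first_dose_time = 0) {
  if (!is.numeric(dose_mg) || dose_mg <= 0) abort("`dose_mg` must be > 0.")
  if (!is.numeric(interval_h) || interval_h <= 0) abort("`interval_h` must be > 0.")
  n_doses <- as.integer(n_doses)
  if (is.na(n_doses) || n_doses < 1L) abort("`n_doses` must be an integer >= 1.")
  if (first_dose_time < 0) abort("`first_dose_time` must be >= 0.")
  structure(list(dose_mg = dose_mg, interval_h = interval_h,
                 n_doses = n_doses, first_dose_time = first_dose_time),
            class = "radpk_regimen")
}

#' @rdname regimen
#' @param x A `radpk_regimen`.
#' @export
expand_regimen <- function(x) {
  stopifnot(inherits(x, "radpk_regimen"))
  tibble(
    time = x$first_dose_time + (seq_len(x$n_doses) - 1) * x$interval_h,
    amount = rep(x$dose_mg, x$n_doses)
  )
}
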