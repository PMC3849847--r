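#' Does an admission record carry a diabetes code?
#'
#' True when the principal diagnosis or any secondary diagnosis field
#' matches the diabetes code set under the record's own ICD version
#' (ICD-9 250, ICD-10 E10--E14) -- i.e. any of the 21 diagnosis fields.
#'
#' @param admissions Admissions tibble.
#' @return Logical vector, one element per record.
#' @export
admission_has_diabetes <- function(admissions) {
  principal <- is_diabetes_code(
    admissions$principal_diagnosis, admissions$icd_version
  )
  sec <- split_codes(admissions$secondary_diagnoses)
  ver <- admissions$icd_version
  secondary <- vapply(
    seq_along(sec),
    function(i) any(is_diabetes_code(sec[[i]], ver[i])),
    logical(1)
  )
  principal | secondary
}

#' The standard lookback windows
#'
#' Index admission only, then 1, 2, 5, 10 and 15 years of prior history.
#' @return Character vector of window labels.
#' @export
lookback_windows <- function() c("index", "1", "2", "5", "10", "15")

#' Ascertain administrative diabetes status over lookback windows
#'
#' For each cohort row and lookback window, administrative status is
#' positive if the index admission carries a diabetes code, or (for a
#' `w`-year window) any prior admission with admission date in
#' `[index_date - w years, index_date)` does. Window boundaries use
#' calendar-year arithmetic (same month/day `w` years earlier, 29 February
#' mapping to 28 February); each prior record is matched under its own ICD
#' version, so histories spanning the ICD-9/ICD-10 cutover are handled
#' version-appropriately. Status is non-decreasing across nested windows
#' by construction.
#'
#' @param cohort Cohort tibble from [build_cohort()] (needs `person_id`,
#'   `era`, `index_admission_id`, `index_date`).
#' @param admissions Admissions tibble containing each cohort person's
#'   history, including the index admission itself.
#' @param windows Character vector of window labels: `"index"` and/or
#'   whole numbers of years, strictly increasing (default
#'   [lookback_windows()]).
#' @return Long tibble: `person_id`, `era`, `window` (factor in window
#'   order), `administrative_diabetes`.
#' @export
ascertain <- function(cohort, admissions, windows = lookback_windows()) {
  windows <- validate_windows(windows)
  flagged <- admissions |>
    mutate(has_dm = admission_has_diabetes(admissions)) |>
    select("person_id", "admission_id", "admission_date", "has_dm")

  base <- cohort |>
    select("person_id", "era", "index_admission_id", "index_date")

  hist <- base |>
    inner_join(flagged, by = "person_id", relationship = "many-to-many")
  late <- hist$admission_id != hist$index_admission_id &
    hist$admission_date >= hist$index_date
  if (any(late & hist$has_dm)) {
    warning(
      sum(late & hist$has_dm),
      " diabetes-coded admission(s) dated on/after the index were ignored",
      call. = FALSE
    )
  }

  # per row: index status, and years-back of the most recent coded prior
  summ <- hist |>
    filter(!late) |>
    group_by(.data$person_id, .data$era) |>
    summarise(
      index_dm = any(.data$has_dm & .data$admission_id == .data$index_admission_id),
      last_dm_prior_date = if (any(.data$has_dm &
        .data$admission_id != .data$index_admission_id)) {
        max(.data$admission_date[.data$has_dm &
          .data$admission_id != .data$index_admission_id])
      } else {
        as.Date(NA)
      },
      .groups = "drop"
    )
  base <- base |> left_join(summ, by = c("person_id", "era"))

  out <- purrr::map(windows, function(w) {
    status <- if (w == "index") {
      base$index_dm
    } else {
      lower <- subtract_years(base$index_date, as.integer(w))
      base$index_dm |
        (!is.na(base$last_dm_prior_date) & base$last_dm_prior_date >= lower)
    }
    tibble(
      person_id = base$person_id,
      era = base$era,
      window = w,
      administrative_diabetes = status
    )
  }) |>
    dplyr::bind_rows()
  out$window <- factor(out$window, levels = windows)
  out
}

validate_windows <- function(windows) {
  windows <- as.character(windows)
  yrs <- suppressWarnings(as.integer(windows[windows != "index"]))
  if (anyNA(yrs) || any(diff(yrs) <= 0) ||
    anyDuplicated(windows) > 0 || length(windows) == 0) {
    stop(
      '`windows` must be "index" and/or strictly increasing whole years',
      call. = FALSE
    )
  }
  windows
}

#' History-based covariates for the index admission
#'
#' `prior_90day`: any admission (for any cause) with admission date in the
#' 90 days before the index. `first_ever_chd`: no admission with a CHD
#' *principal* diagnosis in the 15 years before the index (consistent with
#' index selection, which is principal-diagnosis based).
#'
#' @inheritParams ascertain
#' @return Tibble `person_id`, `era`, `prior_90day`, `first_ever_chd`.
#' @export
derive_history_covariates <- function(cohort, admissions) {
  base <- cohort |>
    select("person_id", "era", "index_admission_id", "index_date")
  hist <- base |>
    inner_join(
      admissions |>
        select(
          "person_id", "admission_id", "admission_date",
          "principal_diagnosis", "icd_version"
        ),
      by = "person_id", relationship = "many-to-many"
    ) |>
    filter(
      .data$admission_id != .data$index_admission_id,
      .data$admission_date < .data$index_date
    )
  summ <- hist |>
    group_by(.data$person_id, .data$era) |>
    summarise(
      prior_90day = any(.data$admission_date >= .data$index_date - 90),
      prior_chd_15y = any(
        .data$admission_date >= subtract_years(.data$index_date, 15) &
          is_chd_code(.data$principal_diagnosis, .data$icd_version)
      ),
      .groups = "drop"
    )
  base |>
    left_join(summ, by = c("person_id", "era")) |>
    transmute(
      person_id = .data$person_id,
      era = .data$era,
      prior_90day = dplyr::coalesce(.data$prior_90day, FALSE),
      first_ever_chd = !dplyr::coalesce(.data$prior_chd_15y, FALSE)
    )
}
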