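#' Select index CHD admissions for one era
#'
#' For every person with at least one admission in the era window whose
#' *principal* diagnosis is CHD (ICD-9 410--414 / ICD-10 I20--I25, matched
#' under the record's own ICD version), returns the earliest such
#' admission; ties on the same day are broken by lowest `admission_id`.
#' Persons with CHD only in secondary fields, or no in-window CHD
#' admission, are excluded.
#'
#' @param admissions Admissions tibble (see [generate_linked_data()] for
#'   the schema).
#' @param era_window Length-2 `Date` (or parseable character) vector; both
#'   endpoints inclusive.
#' @param era Label recorded on the output rows (e.g. `"ICD9"`).
#' @return Tibble with one row per person: `person_id`, `era`,
#'   `index_admission_id`, `index_date`.
#' @export
select_index_admissions <- function(admissions, era_window, era = "era") {
  era_window <- as.Date(era_window)
  admissions |>
    filter(
      .data$admission_date >= era_window[1],
      .data$admission_date <= era_window[2],
      is_chd_code(.data$principal_diagnosis, .data$icd_version)
    ) |>
    arrange(.data$person_id, .data$admission_date, .data$admission_id) |>
    distinct(.data$person_id, .keep_all = TRUE) |>
    transmute(
      person_id = .data$person_id,
      era = era,
      index_admission_id = .data$admission_id,
      index_date = .data$admission_date
    )
}

#' Derive Indigenous status from a person's record history
#'
#' Indigenous identification is under-recorded in hospital discharge data,
#' so a person is classified Indigenous when at least 25% of all their
#' admission records carry the Indigenous flag (boundary inclusive).
#'
#' @param admissions Admissions tibble covering each person's full
#'   available history.
#' @param threshold Minimum flagged fraction (default 0.25).
#' @return Tibble `person_id`, `indigenous_derived`. Persons are keyed by
#'   their records; a person absent from `admissions` has no row.
#' @export
derive_indigenous <- function(admissions, threshold = 0.25) {
  if (nrow(admissions) == 0) {
    stop("cannot derive Indigenous status from an empty history", call. = FALSE)
  }
  admissions |>
    group_by(.data$person_id) |>
    summarise(
      indigenous_derived = mean(.data$indigenous_flag) >= threshold,
      .groups = "drop"
    )
}

#' Classify reference diabetes status from a medical-record entry
#'
#' A patient is reference-positive if diabetes was documented as present
#' in the medical notes *or* diabetes drug treatment was identified.
#' Patients whose status was "not recorded" with no diabetes drugs are
#' classified in the no-diabetes group, and flagged so a sensitivity
#' analysis can drop them.
#'
#' @param medical_records Tibble with `diabetes_documented`
#'   (`present`/`absent`/`not_recorded`) and `diabetes_drug_treatment`
#'   (logical) columns.
#' @return The input with `reference_diabetes` and `not_recorded_flag`
#'   logical columns appended.
#' @export
classify_reference_diabetes <- function(medical_records) {
  doc <- medical_records$diabetes_documented
  bad <- !doc %in% c("present", "absent", "not_recorded")
  if (any(bad)) {
    stop(
      "invalid `diabetes_documented` value(s): ",
      paste(unique(doc[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  drug <- as.logical(medical_records$diabetes_drug_treatment)
  medical_records |>
    mutate(
      reference_diabetes = doc == "present" | drug,
      not_recorded_flag = doc == "not_recorded" & !drug
    )
}

#' Build the analysis cohort across eras
#'
#' Runs index selection per era, applies the era's age-eligibility filter,
#' derives Indigenous status from the person's full record history, and
#' joins the medical-record reference classification. Index admissions
#' without a reviewable medical-record entry are dropped (the count is
#' reported via `message()`), mirroring admissions whose notes could not
#' be reviewed.
#'
#' @param admissions Admissions tibble.
#' @param medical_records Medical-record tibble (see
#'   [generate_linked_data()]).
#' @param era_windows Named list of era date windows, as in [sim_config()].
#' @param age_bounds Named list (per era) of inclusive `c(min, max)` age
#'   eligibility at the index admission; `NULL` entries disable the
#'   filter. Defaults follow the two sampling frames: 35--79 in the ICD-9
#'   era and 25--79 in the ICD-10 era.
#' @return Cohort tibble keyed by (`person_id`, `era`): index admission
#'   reference and date, `indigenous_derived`, `reference_diabetes`,
#'   `not_recorded_flag`, plus index covariate columns (`age`, `sex`, ...).
#' @export
build_cohort <- function(admissions, medical_records,
                         era_windows = list(
                           ICD9 = c("1998-01-01", "1998-12-31"),
                           ICD10 = c("2002-01-01", "2004-12-31")
                         ),
                         age_bounds = list(
                           ICD9 = c(35, 79),
                           ICD10 = c(25, 79)
                         )) {
  indig <- derive_indigenous(admissions)
  mr <- classify_reference_diabetes(medical_records)

  cohort <- purrr::imap(era_windows, function(win, era) {
    idx <- select_index_admissions(admissions, win, era)
    idx <- idx |>
      inner_join(
        admissions |> select(-"person_id", -"admission_date"),
        by = c(index_admission_id = "admission_id")
      )
    bounds <- age_bounds[[era]]
    if (!is.null(bounds) && "age" %in% names(idx)) {
      idx <- filter(idx, .data$age >= bounds[1], .data$age <= bounds[2])
    }
    idx
  }) |>
    dplyr::bind_rows()

  n_before <- nrow(cohort)
  cohort <- cohort |>
    inner_join(
      mr |> select("index_admission_id", "reference_diabetes", "not_recorded_flag"),
      by = "index_admission_id"
    )
  dropped <- n_before - nrow(cohort)
  if (dropped > 0) {
    message(dropped, " index admission(s) without a medical-record entry excluded")
  }
  cohort |>
    left_join(indig, by = "person_id") |>
    arrange(.data$era, .data$person_id)
}
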