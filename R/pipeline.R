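#' Write / read the pipeline's delimited tables
#'
#' Tables are CSV with a header row, dates as ISO-8601 (`YYYY-MM-DD`) and
#' missing values as empty strings.
#'
#' @param tables Named list of tibbles.
#' @param dir Output directory (created if needed).
#' @return `write_linked_tables()` returns the paths invisibly;
#'   `read_linked_tables()` a named list of tibbles.
#' @export
write_linked_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::imap_chr(tables, function(tab, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(tab, path, na = "")
    path
  })
  invisible(paths)
}

#' @rdname write_linked_tables
#' @param names Table names to read (file base names).
#' @export
read_linked_tables <- function(dir, names = c("admissions", "medical_records")) {
  out <- lapply(names, function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) stop("missing input table: ", path, call. = FALSE)
    readr::read_csv(path, show_col_types = FALSE, na = "", progress = FALSE)
  })
  setNames(out, names)
}

#' Run the full validation pipeline
#'
#' Orchestrates simulate (or load) -> cohort -> ascertain -> concordance
#' -> predictors, writing every artifact as a delimited table plus a JSON
#' run manifest with row-count bookkeeping at each stage. Concordance is
#' produced per era and, within eras whose cohort contains both groups,
#' stratified by derived Indigenous status; eras are also compared
#' measure-by-measure at each window.
#'
#' @param sim A [sim_config()] object, or `NULL` to read `admissions` /
#'   `medical_records` tables from `input_dir`.
#' @param input_dir Directory holding `admissions.csv` and
#'   `medical_records.csv` when `sim` is `NULL`.
#' @param out_dir Output directory for result tables and the manifest;
#'   `NULL` skips writing.
#' @param windows Lookback windows (see [ascertain()]).
#' @param era_windows,age_bounds Passed to [build_cohort()]; defaults are
#'   taken from `sim` when it is supplied.
#' @param drop_not_recorded Sensitivity-analysis switch: drop reference
#'   rows whose medical-record diabetes status was "not recorded".
#' @param entry_p Univariable entry threshold for the multivariable
#'   misclassification models (0.05, or 0.1 for the sensitivity variant).
#' @param strata Extra cohort columns to stratify concordance by, in
#'   addition to `era` (default adds `indigenous_derived` where both
#'   levels are present).
#' @return Invisible list: `cohort`, `ascertainment`, `concordance`,
#'   `era_comparison`, `predictors` (screening + models), `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(sim = sim_config(
#'   n_patients_per_era = c(ICD9 = 200, ICD10 = 300), seed = 42
#' ))
#' head(res$concordance)
#' }
run_pipeline <- function(sim = sim_config(), input_dir = NULL, out_dir = NULL,
                         windows = lookback_windows(),
                         era_windows = NULL, age_bounds = NULL,
                         drop_not_recorded = FALSE, entry_p = 0.05,
                         strata = "indigenous_derived") {
  manifest <- list(
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("lookback")),
    windows = windows,
    drop_not_recorded = drop_not_recorded,
    entry_p = entry_p
  )

  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    dat <- generate_linked_data(sim)
    manifest$seed <- sim$seed
    era_windows <- era_windows %||% sim$era_windows
    age_bounds <- age_bounds %||%
      sim$covariate_params$age_range[names(sim$era_windows)]
  } else {
    if (is.null(input_dir)) {
      stop("supply either `sim` or `input_dir`", call. = FALSE)
    }
    dat <- read_linked_tables(input_dir)
    dat$admissions$admission_date <- as.Date(dat$admissions$admission_date)
    dat$admissions$separation_date <- as.Date(dat$admissions$separation_date)
    if (is.null(era_windows)) {
      stop("`era_windows` is required when loading tables", call. = FALSE)
    }
  }
  manifest$n_admissions <- nrow(dat$admissions)
  manifest$n_medical_records <- nrow(dat$medical_records)

  dropped_mr <- 0
  withCallingHandlers(
    cohort <- build_cohort(dat$admissions, dat$medical_records,
      era_windows = era_windows,
      age_bounds = age_bounds %||%
        setNames(vector("list", length(era_windows)), names(era_windows))
    ),
    message = function(m) {
      n <- suppressWarnings(as.integer(sub("^(\\d+) .*", "\\1",
        conditionMessage(m))))
      if (!is.na(n)) dropped_mr <<- n
      invokeRestart("muffleMessage")
    }
  )
  manifest$n_cohort <- nrow(cohort)
  manifest$n_index_without_medical_record <- dropped_mr
  manifest$n_not_recorded <- sum(cohort$not_recorded_flag)
  if (drop_not_recorded) {
    cohort <- filter(cohort, !.data$not_recorded_flag)
    manifest$n_cohort_after_drop <- nrow(cohort)
  }

  ascertainment <- ascertain(cohort, dat$admissions, windows)

  conc <- concordance_by_stratum(cohort, ascertainment, strata = "era")
  strata <- setdiff(strata, "era")
  for (s in strata) {
    if (s %in% names(cohort) && length(unique(cohort[[s]])) > 1) {
      conc <- dplyr::bind_rows(
        conc,
        concordance_by_stratum(cohort, ascertainment,
          strata = c("era", s)
        )
      )
    }
  }

  eras <- unique(cohort$era)
  era_comparison <- NULL
  if (length(eras) == 2) {
    era_comparison <- purrr::map(windows, function(w) {
      tabs <- lapply(eras, function(e) {
        d <- ascertainment |>
          filter(.data$window == w, .data$era == e) |>
          inner_join(cohort |> select("person_id", "era", "reference_diabetes"),
            by = c("person_id", "era")
          )
        build_two_by_two(d$reference_diabetes, d$administrative_diabetes)
      })
      compare_measures(tabs[[1]], tabs[[2]]) |>
        mutate(window = w, era_a = eras[1], era_b = eras[2], .before = 1)
    }) |>
      dplyr::bind_rows()
  }

  covariates <- label_outcomes(cohort, ascertainment, dat$admissions)
  predictors <- predictor_report(covariates, entry_p = entry_p)

  manifest$n_false_negative <- sum(covariates$outcome_fn, na.rm = TRUE)
  manifest$n_false_positive <- sum(covariates$outcome_fp, na.rm = TRUE)
  manifest$models_fitted <- names(predictors$models)

  result <- list(
    cohort = cohort,
    ascertainment = ascertainment,
    concordance = conc,
    era_comparison = era_comparison,
    predictors = predictors,
    covariates = covariates,
    manifest = manifest
  )

  if (!is.null(out_dir)) {
    tables <- list(
      cohort = cohort,
      ascertainment = ascertainment,
      concordance = round_report(conc),
      predictor_screening = predictors$screening
    )
    if (!is.null(era_comparison)) tables$era_comparison <- era_comparison
    model_rows <- purrr::imap(predictors$models, function(m, key) {
      m$estimates |>
        mutate(model = key, n = m$n, converged = m$converged, .before = 1)
    })
    if (length(model_rows)) {
      tables$predictor_models <- dplyr::bind_rows(model_rows)
    }
    if (!is.null(sim)) {
      tables$admissions <- dat$admissions
      tables$medical_records <- dat$medical_records
      tables$truth <- dat$truth
    }
    write_linked_tables(tables, out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  invisible(result)
}

# presentation rounding: percentages to 1 decimal, half away from zero
round_report <- function(conc) {
  conc |>
    mutate(across(
      any_of(c(
        "observed_agreement", "kappa", "sensitivity", "specificity",
        "ppv", "npv", "under_over"
      )),
      ~ round_half_away(.x, 1)
    ))
}
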