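#' Configuration for the linked-data simulator
#'
#' Builds and validates the parameter set for [generate_linked_data()]. The
#' defaults emulate a two-era validation study of diabetes coding in
#' hospital discharge data for coronary heart disease (CHD) patients: an
#' ICD-9 sampling era (calendar 1998, n = 1685) and an ICD-10 era
#' (2002--2004, n = 2258), with the statewide coding cutover on
#' 1999-07-01 so that a person's multi-year admission history spans both
#' ICD versions. Indigenous status is over-represented in the later era
#' and under-recorded at the record level, diabetes prevalence differs by
#' era and Indigenous status, and the per-admission probability that a
#' true diabetic's record carries a diabetes code differs by the ICD
#' version in force when the record was coded.
#'
#' @param n_patients_per_era Named integer vector, persons sampled per era.
#' @param era_windows Named list of length-2 `Date` (or parseable
#'   character) vectors giving each era's index-admission sampling window.
#'   Windows must not overlap.
#' @param icd10_cutover Date from which records are coded in ICD-10.
#' @param history_years Years of pre-index admission history to simulate
#'   (at least the longest lookback window you intend to use; default 15).
#' @param prev_diabetes Named list (per era) of length-2 probability
#'   vectors `c(non_indigenous =, indigenous =)`: true diabetes prevalence.
#' @param p_code_diabetes Probabilities named `"9"` and `"10"`: chance a
#'   true diabetic's admission carries a diabetes code, by the ICD version
#'   of the record.
#' @param q_miscode Probabilities named `"9"` and `"10"`: chance a
#'   non-diabetic's admission carries a diabetes code.
#' @param admission_rate Expected non-index admissions per person-year.
#' @param admission_rate_ratio_diabetes Multiplier on `admission_rate` for
#'   true diabetics (they are hospitalized more often).
#' @param prop_indigenous Named probability per era of being truly
#'   Indigenous.
#' @param p_record_indigenous Per-record probability that a truly
#'   Indigenous person's admission is flagged Indigenous (under-recording
#'   when < 1); non-Indigenous records are never flagged.
#' @param p_doc_present Probability a true diabetic's medical record
#'   documents diabetes as present (1 = medical record is truth).
#' @param p_drug_given_diabetic Probability a true diabetic has diabetes
#'   drug treatment identifiable in the record.
#' @param p_not_recorded Probability a non-diabetic's reference entry is
#'   "not recorded" rather than "absent".
#' @param p_prior_chd Probability a prior (non-index) admission carries a
#'   CHD principal diagnosis; such admissions are only generated outside
#'   the era sampling windows so the intended index admission is always
#'   the first in-window CHD admission.
#' @param covariate_params List of distribution parameters for length of
#'   stay, age, sex, admission type, hospital type/location, transfers,
#'   in-hospital death and secondary-diagnosis counts; see
#'   [default_covariate_params()].
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   output tables exactly.
#' @return A validated list of class `sim_config`.
#' @seealso [generate_linked_data()]
#' @export
sim_config <- function(n_patients_per_era = c(ICD9 = 1685, ICD10 = 2258),
                       era_windows = list(
                         ICD9 = c("1998-01-01", "1998-12-31"),
                         ICD10 = c("2002-01-01", "2004-12-31")
                       ),
                       icd10_cutover = "1999-07-01",
                       history_years = 15,
                       prev_diabetes = list(
                         ICD9 = c(non_indigenous = 0.225, indigenous = 0.560),
                         ICD10 = c(non_indigenous = 0.285, indigenous = 0.562)
                       ),
                       p_code_diabetes = c("9" = 0.9, "10" = 0.8),
                       q_miscode = c("9" = 0.013, "10" = 0.018),
                       admission_rate = 0.4,
                       admission_rate_ratio_diabetes = 1.5,
                       prop_indigenous = c(ICD9 = 0.015, ICD10 = 0.232),
                       p_record_indigenous = 0.7,
                       p_doc_present = 1,
                       p_drug_given_diabetic = 0.6,
                       p_not_recorded = 0.025,
                       p_prior_chd = 0.1,
                       covariate_params = default_covariate_params(),
                       seed = 1L) {
  eras <- names(era_windows)
  if (is.null(eras) || any(!nzchar(eras))) {
    stop("`era_windows` must be a named list of date intervals", call. = FALSE)
  }
  era_windows <- lapply(era_windows, function(w) {
    w <- as.Date(w)
    if (length(w) != 2 || anyNA(w) || w[2] < w[1]) {
      stop("each era window must be two ordered dates", call. = FALSE)
    }
    w
  })
  if (length(eras) > 1) {
    ivl <- do.call(rbind, era_windows)
    ord <- order(ivl[, 1])
    if (any(ivl[ord, 1][-1] <= ivl[ord, 2][-length(eras)])) {
      stop("era windows must be disjoint", call. = FALSE)
    }
  }
  n_patients_per_era <- setNames(
    as.integer(rep_len(n_patients_per_era, length(eras))),
    eras
  )
  if (any(n_patients_per_era < 1)) {
    stop("`n_patients_per_era` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(history_years) || history_years <= 0) {
    stop("`history_years` must be positive", call. = FALSE)
  }
  for (e in eras) {
    stopifnot_prob(prev_diabetes[[e]], paste0("prev_diabetes$", e))
    if (!all(c("non_indigenous", "indigenous") %in% names(prev_diabetes[[e]]))) {
      stop("`prev_diabetes` needs non_indigenous and indigenous entries",
        call. = FALSE
      )
    }
  }
  p_code_diabetes <- version_probs(p_code_diabetes, "p_code_diabetes")
  q_miscode <- version_probs(q_miscode, "q_miscode")
  prop_indigenous <- setNames(rep_len(prop_indigenous, length(eras)), eras)
  stopifnot_prob(prop_indigenous, "prop_indigenous")
  stopifnot_prob(p_record_indigenous, "p_record_indigenous")
  stopifnot_prob(p_doc_present, "p_doc_present")
  stopifnot_prob(p_drug_given_diabetic, "p_drug_given_diabetic")
  stopifnot_prob(p_not_recorded, "p_not_recorded")
  stopifnot_prob(p_prior_chd, "p_prior_chd")
  if (admission_rate < 0 || admission_rate_ratio_diabetes < 0) {
    stop("admission rates must be non-negative", call. = FALSE)
  }
  structure(
    list(
      n_patients_per_era = n_patients_per_era,
      era_windows = era_windows,
      icd10_cutover = as.Date(icd10_cutover),
      history_years = history_years,
      prev_diabetes = prev_diabetes,
      p_code_diabetes = p_code_diabetes,
      q_miscode = q_miscode,
      admission_rate = admission_rate,
      admission_rate_ratio_diabetes = admission_rate_ratio_diabetes,
      prop_indigenous = prop_indigenous,
      p_record_indigenous = p_record_indigenous,
      p_doc_present = p_doc_present,
      p_drug_given_diabetic = p_drug_given_diabetic,
      p_not_recorded = p_not_recorded,
      p_prior_chd = p_prior_chd,
      covariate_params = utils::modifyList(
        default_covariate_params(), covariate_params
      ),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# probabilities keyed by ICD version ("9"/"10"); scalars are recycled
version_probs <- function(p, what) {
  if (length(p) == 1 && is.null(names(p))) p <- c("9" = unname(p), "10" = unname(p))
  if (!all(c("9", "10") %in% names(p))) {
    stop(sprintf('`%s` must be named with versions "9" and "10"', what),
      call. = FALSE
    )
  }
  stopifnot_prob(p, what)
  p[c("9", "10")]
}

#' Default covariate distributions for the simulator
#'
#' Length of stay is `1 + NegBin(size, mu)` days; age at index is normal
#' (era-specific mean/sd) clamped to the era's eligibility range;
#' remaining covariates are Bernoulli. Secondary-diagnosis counts are
#' Poisson by ICD version (capped so a record never exceeds 20 secondary
#' fields). Values mirror the marginal structure of a late-1990s/early-2000s
#' CHD inpatient sample.
#'
#' @return Named list of parameters, overridable through the
#'   `covariate_params` argument of [sim_config()].
#' @export
default_covariate_params <- function() {
  list(
    los_mu = 3, los_size = 2,
    age_mean = c(ICD9 = 64.1, ICD10 = 61.1),
    age_sd = c(ICD9 = 10.8, ICD10 = 12.3),
    age_range = list(ICD9 = c(35, 79), ICD10 = c(25, 79)),
    p_male = 0.68,
    p_elective = 0.107,
    p_rural = c(ICD9 = 0.013, ICD10 = 0.328),
    p_private = c(ICD9 = 0.258, ICD10 = 0.171),
    p_transfer_in = 0.08,
    p_transfer_out = 0.08,
    p_died = 0.04,
    mean_secondary = c("9" = 4.5, "10" = 3.5),
    dx_group_probs = c(MI = 0.49, UA = 0.45, other_CHD = 0.06)
  )
}

#' Read a simulator configuration from a YAML or JSON file
#'
#' Any field omitted from the file keeps its [sim_config()] default.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- lapply(raw, relist_named)
  do.call(sim_config, raw)
}

# YAML maps come back as lists; collapse scalar-valued maps to named
# vectors, recursing so era-keyed sub-maps survive round-tripping
relist_named <- function(x) {
  if (is.list(x) && length(x)) {
    if (all(vapply(x, function(e) is.atomic(e) && length(e) == 1, logical(1))) &&
      !is.null(names(x))) {
      return(unlist(x))
    }
    return(lapply(x, relist_named))
  }
  x
}
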