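# Era-version ICD code pools used by the generator. Diabetes and CHD pools
# are the code sets the ascertainment and cohort modules match on; filler
# pools are common cardiovascular/medical codes outside both sets (several
# map to Charlson conditions so comorbidity scoring is exercised).
code_pools <- list(
  "9" = list(
    mi = c("41001", "41011", "41091", "4109"),
    ua = c("4111"),
    other_chd = c("4139", "41401", "412", "4130"),
    diabetes = c("25000", "25001", "25002", "25010", "25040", "25060"),
    principal_filler = c("486", "5990", "5409", "4280", "56212", "78039"),
    secondary_filler = c(
      "4019", "2724", "42731", "4280", "496", "5859",
      "2859", "311", "53081", "486"
    )
  ),
  "10" = list(
    mi = c("I210", "I214", "I219", "I220"),
    ua = c("I200"),
    other_chd = c("I209", "I208", "I251", "I259"),
    diabetes = c("E119", "E1165", "E112", "E149", "E109", "E1122"),
    principal_filler = c("J189", "N390", "K358", "I500", "K573", "R55"),
    secondary_filler = c(
      "I10", "E780", "I48", "I500", "J449", "N189",
      "D649", "F329", "K219", "J189"
    )
  )
)

#' Generate linked admission histories with a medical-record reference
#'
#' Simulates, per sampling era, a cohort of persons each anchored by one
#' index CHD admission inside the era window, a Poisson history of prior
#' admissions over the preceding `history_years`, per-admission diabetes
#' coding with version-specific sensitivity (and a small miscoding rate in
#' non-diabetics), record-level under-recording of Indigenous status, and
#' one medical-record reference entry per index admission. Records are
#' coded in ICD-9 or ICD-10 according to their own admission date relative
#' to the cutover, so a long history spans both versions.
#'
#' @param config A [sim_config()] object.
#' @return A list of three tibbles:
#' \describe{
#'   \item{admissions}{one row per hospital separation: `person_id`,
#'     `admission_id`, `admission_date`, `separation_date`, `icd_version`,
#'     `principal_diagnosis`, `secondary_diagnoses` (semicolon-delimited,
#'     at most 20), `admission_type`, `hospital_type`, `hospital_location`,
#'     `transfer_in`, `transfer_out`, `died_in_hospital`,
#'     `indigenous_flag`, `age`, `sex`.}
#'   \item{medical_records}{one reference-standard row per index
#'     admission: `person_id`, `index_admission_id`, `diabetes_documented`
#'     (`present`/`absent`/`not_recorded`), `diabetes_drug_treatment`.}
#'   \item{truth}{latent state per person-era: `person_id`, `era`,
#'     `index_admission_id`, `true_diabetes`, `true_indigenous`.}
#' }
#' @export
#' @examples
#' cfg <- sim_config(n_patients_per_era = c(ICD9 = 50, ICD10 = 80), seed = 7)
#' dat <- generate_linked_data(cfg)
#' dplyr::count(dat$admissions, icd_version)
generate_linked_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$history_years < 15) {
    warning("history_years < 15: 15-year lookback windows will be truncated",
      call. = FALSE
    )
  }
  withr::with_seed(config$seed, {
    parts <- lapply(names(config$era_windows), simulate_era, config = config)
  })
  list(
    admissions = dplyr::bind_rows(lapply(parts, `[[`, "admissions")) |>
      arrange(.data$person_id, .data$admission_date, .data$admission_id),
    medical_records = dplyr::bind_rows(lapply(parts, `[[`, "medical_records")),
    truth = dplyr::bind_rows(lapply(parts, `[[`, "truth"))
  )
}

simulate_era <- function(era, config) {
  n <- config$n_patients_per_era[[era]]
  cp <- config$covariate_params
  win <- config$era_windows[[era]]
  person_id <- sprintf("%s-%06d", era, seq_len(n))

  true_indigenous <- runif(n) < config$prop_indigenous[[era]]
  prev <- config$prev_diabetes[[era]]
  true_diabetes <- runif(n) <
    ifelse(true_indigenous, prev[["indigenous"]], prev[["non_indigenous"]])

  index_date <- win[1] +
    floor(runif(n) * (as.numeric(win[2] - win[1]) + 1))
  age_lim <- cp$age_range[[era]]
  age_index <- pmin(pmax(
    round(rnorm(n, cp$age_mean[[era]], cp$age_sd[[era]])),
    age_lim[1]
  ), age_lim[2])
  sex <- ifelse(runif(n) < cp$p_male, "male", "female")

  # prior admissions: homogeneous Poisson over the history window, with a
  # higher rate for true diabetics
  rate <- config$admission_rate *
    ifelse(true_diabetes, config$admission_rate_ratio_diabetes, 1)
  k_prior <- rpois(n, rate * config$history_years)
  idx <- rep(seq_len(n), k_prior)
  offset_days <- floor(runif(length(idx)) * config$history_years * 365.25) + 1
  prior_date <- index_date[idx] - offset_days

  adm <- tibble(
    person_id = c(person_id, person_id[idx]),
    is_index = rep(c(TRUE, FALSE), c(n, length(idx))),
    admission_date = c(index_date, prior_date),
    age = c(age_index, pmax(age_index[idx] - offset_days %/% 365, 0L)),
    sex = c(sex, sex[idx]),
    true_diabetes = c(true_diabetes, true_diabetes[idx]),
    true_indigenous = c(true_indigenous, true_indigenous[idx])
  )
  m <- nrow(adm)
  adm$admission_id <- sprintf("%s-A%07d", era, seq_len(m))
  adm$icd_version <- ifelse(adm$admission_date >= config$icd10_cutover, 10L, 9L)

  los <- 1L + rnbinom(m, size = cp$los_size, mu = cp$los_mu)
  adm$separation_date <- adm$admission_date + los
  adm$admission_type <- ifelse(runif(m) < cp$p_elective, "elective", "emergency")
  adm$hospital_location <- ifelse(runif(m) < cp$p_rural[[era]],
    "rural", "metropolitan"
  )
  adm$hospital_type <- ifelse(runif(m) < cp$p_private[[era]],
    "private", "public"
  )
  adm$transfer_in <- runif(m) < cp$p_transfer_in
  adm$transfer_out <- runif(m) < cp$p_transfer_out
  adm$died_in_hospital <- adm$is_index & runif(m) < cp$p_died
  adm$indigenous_flag <- adm$true_indigenous &
    runif(m) < config$p_record_indigenous

  adm$principal_diagnosis <- draw_principal(adm, era, config)
  adm$secondary_diagnoses <- draw_secondaries(adm, config)

  index_ids <- adm$admission_id[adm$is_index]
  documented <- ifelse(
    true_diabetes,
    ifelse(runif(n) < config$p_doc_present, "present", "absent"),
    ifelse(runif(n) < config$p_not_recorded, "not_recorded", "absent")
  )
  drug <- true_diabetes & runif(n) < config$p_drug_given_diabetic

  list(
    admissions = adm[, c(
      "person_id", "admission_id", "admission_date", "separation_date",
      "icd_version", "principal_diagnosis", "secondary_diagnoses",
      "admission_type", "hospital_type", "hospital_location",
      "transfer_in", "transfer_out", "died_in_hospital",
      "indigenous_flag", "age", "sex"
    )],
    medical_records = tibble(
      person_id = person_id,
      index_admission_id = index_ids,
      diabetes_documented = documented,
      diabetes_drug_treatment = drug
    ),
    truth = tibble(
      person_id = person_id,
      era = era,
      index_admission_id = index_ids,
      true_diabetes = true_diabetes,
      true_indigenous = true_indigenous
    )
  )
}

# Principal diagnosis: the index admission gets a CHD code of its record
# version (MI/UA/other mix); priors get a CHD code with probability
# p_prior_chd only when dated outside every era sampling window (so the
# intended index stays the first in-window CHD admission), else a filler.
draw_principal <- function(adm, era, config) {
  m <- nrow(adm)
  cp <- config$covariate_params
  ver <- as.character(adm$icd_version)
  out <- character(m)

  grp <- sample(names(cp$dx_group_probs), m,
    replace = TRUE, prob = cp$dx_group_probs
  )
  in_window <- Reduce(`|`, lapply(config$era_windows, function(w) {
    adm$admission_date >= w[1] & adm$admission_date <= w[2]
  }))
  chd_prior <- !adm$is_index & !in_window & runif(m) < config$p_prior_chd
  for (v in c("9", "10")) {
    pool <- code_pools[[v]]
    sel <- ver == v & (adm$is_index | chd_prior)
    if (any(sel)) {
      pools <- list(
        MI = pool$mi, UA = pool$ua, other_CHD = pool$other_chd
      )[grp[sel]]
      out[sel] <- vapply(pools, function(p) p[sample.int(length(p), 1)],
        character(1)
      )
    }
    filler <- ver == v & !adm$is_index & !chd_prior
    out[filler] <- sample(pool$principal_filler, sum(filler), replace = TRUE)
  }
  out
}

# Secondary diagnoses: Poisson count of filler codes (capped at 19), plus a
# diabetes code with the version-specific coding probability, inserted at a
# uniformly chosen position so it can occupy any of the 21 fields' slots.
draw_secondaries <- function(adm, config) {
  m <- nrow(adm)
  ver <- as.character(adm$icd_version)
  k <- pmin(rpois(m, config$covariate_params$mean_secondary[ver]), 19L)
  codes <- vector("list", m)
  for (v in c("9", "10")) {
    sel <- which(ver == v)
    if (!length(sel)) next
    total <- sum(k[sel])
    draws <- sample(code_pools[[v]]$secondary_filler, total, replace = TRUE)
    codes[sel] <- split(draws, factor(rep(seq_along(sel), k[sel]),
      levels = seq_along(sel)
    ))
  }
  p_dm <- ifelse(adm$true_diabetes,
    config$p_code_diabetes[ver], config$q_miscode[ver]
  )
  carries <- runif(m) < p_dm
  dm_code <- character(m)
  for (v in c("9", "10")) {
    sel <- carries & ver == v
    dm_code[sel] <- sample(code_pools[[v]]$diabetes, sum(sel), replace = TRUE)
  }
  for (i in which(carries)) {
    pos <- sample.int(k[i] + 1L, 1L)
    codes[[i]] <- append(codes[[i]], dm_code[i], after = pos - 1L)
  }
  join_codes(codes)
}

#' Closed-form lookback ascertainment sensitivity
#'
#' Under independent per-admission coding with probability `p_code`, a
#' person whose lookback window contains the index admission plus `k`
#' prior admissions is detected with probability `1 - (1 - p_code)^(k+1)`.
#' Averaging over a distribution of prior-admission counts gives the
#' expected ascertainment sensitivity
#' `sum_k pmf(k) * (1 - (1 - p_code)^(k + 1))` -- the analytic oracle for
#' the simulator's lookback mechanism.
#'
#' @param p_code Per-admission coding probability in `[0, 1]`.
#' @param pmf Numeric vector of probabilities for `k = 0, 1, 2, ...` prior
#'   admissions in the window; must sum to 1 within `1e-9`.
#' @return The expected sensitivity, a single probability.
#' @export
#' @examples
#' expected_lookback_sensitivity(0.7, dpois(0:50, 4) / sum(dpois(0:50, 4)))
expected_lookback_sensitivity <- function(p_code, pmf) {
  if (!is.numeric(p_code) || length(p_code) != 1 ||
    p_code < 0 || p_code > 1) {
    stop("`p_code` must be a single probability in [0, 1]", call. = FALSE)
  }
  if (abs(sum(pmf) - 1) > 1e-9) {
    stop("`pmf` must sum to 1 within 1e-9", call. = FALSE)
  }
  sum(pmf * (1 - (1 - p_code)^(seq_along(pmf))))
}
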