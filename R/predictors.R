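#' Label false-negative / false-positive outcomes and covariates
#'
#' Builds the covariate table for modelling misclassification on the
#' index admission. `outcome_fn` (a reference-positive patient with no
#' diabetes code on the index admission) is defined only among
#' reference-positives; `outcome_fp` only among reference-negatives; each
#' is `NA` elsewhere. Covariates are banded as in validation practice:
#' length of stay 1--2 / 3--5 / >=6 days, age 25--50 / 51--65 / 66--79,
#' Charlson index (excluding diabetes) 0 / 1--4 / >=5, comorbidity count
#' (non-diabetes secondary fields) 0--3 / 4--7 / >=8. Reference levels of
#' each factor are the ones conventionally reported as baseline
#' (emergency admission, no in-hospital death, >=6-day stay, other CHD,
#' >=8 comorbidities, Charlson >=5).
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @param ascertainment Long tibble from [ascertain()]; must contain the
#'   `"index"` window.
#' @param admissions Admissions tibble (for history covariates).
#' @return Tibble, one row per cohort row: outcomes plus factor covariates
#'   `los_band`, `age_band`, `sex`, `admission_type`,
#'   `indigenous_derived`, `charlson_band`, `comorbidity_band`,
#'   `prior_90day`, `hospital_location`, `hospital_type`,
#'   `transfer_in_or_out`, `died_in_hospital`, `principal_dx_group`,
#'   `first_ever_chd`.
#' @export
label_outcomes <- function(cohort, ascertainment, admissions) {
  index_status <- ascertainment |>
    filter(.data$window == "index") |>
    select("person_id", "era", admin_index = "administrative_diabetes")
  if (nrow(index_status) == 0) {
    stop('`ascertainment` must include the "index" window', call. = FALSE)
  }
  histcov <- derive_history_covariates(cohort, admissions)

  sec <- split_codes(cohort$secondary_diagnoses)
  ver <- cohort$icd_version
  charlson <- vapply(
    seq_len(nrow(cohort)),
    function(i) {
      charlson_index(
        c(cohort$principal_diagnosis[i], sec[[i]]),
        ver[i],
        exclude_diabetes = TRUE
      )
    },
    integer(1)
  )
  n_comorb <- vapply(
    seq_len(nrow(cohort)),
    function(i) sum(!is_diabetes_code(sec[[i]], ver[i])),
    integer(1)
  )
  los <- pmax(as.integer(cohort$separation_date - cohort$index_date), 1L)

  cohort |>
    inner_join(index_status, by = c("person_id", "era")) |>
    left_join(histcov, by = c("person_id", "era")) |>
    transmute(
      person_id = .data$person_id,
      era = .data$era,
      reference_diabetes = .data$reference_diabetes,
      administrative_diabetes = .data$admin_index,
      outcome_fn = ifelse(.data$reference_diabetes,
        !.data$admin_index, NA
      ),
      outcome_fp = ifelse(!.data$reference_diabetes,
        .data$admin_index, NA
      ),
      los_band = cut(los,
        breaks = c(0, 2, 5, Inf), labels = c("1-2", "3-5", ">=6")
      ) |> stats::relevel(ref = ">=6"),
      age_band = cut(.data$age,
        breaks = c(-Inf, 50, 65, Inf), labels = c("25-50", "51-65", "66-79")
      ),
      sex = factor(.data$sex),
      admission_type = factor(.data$admission_type,
        levels = c("emergency", "elective")
      ),
      indigenous_derived = .data$indigenous_derived,
      charlson_band = cut(charlson,
        breaks = c(-Inf, 0, 4, Inf), labels = c("0", "1-4", ">=5")
      ) |> stats::relevel(ref = ">=5"),
      comorbidity_band = cut(n_comorb,
        breaks = c(-Inf, 3, 7, Inf), labels = c("0-3", "4-7", ">=8")
      ) |> stats::relevel(ref = ">=8"),
      prior_90day = .data$prior_90day,
      hospital_location = factor(.data$hospital_location,
        levels = c("metropolitan", "rural")
      ),
      hospital_type = factor(.data$hospital_type,
        levels = c("public", "private")
      ),
      transfer_in_or_out = .data$transfer_in | .data$transfer_out,
      died_in_hospital = .data$died_in_hospital,
      principal_dx_group = principal_dx_group(
        .data$principal_diagnosis, .data$icd_version
      ) |> stats::relevel(ref = "other_CHD"),
      first_ever_chd = .data$first_ever_chd
    )
}

#' Default candidate predictors of misclassification
#' @return Character vector of covariate column names in
#'   [label_outcomes()] output.
#' @export
predictor_variables <- function() {
  c(
    "los_band", "age_band", "sex", "admission_type", "indigenous_derived",
    "charlson_band", "comorbidity_band", "prior_90day",
    "hospital_location", "hospital_type", "transfer_in_or_out",
    "died_in_hospital", "principal_dx_group", "first_ever_chd"
  )
}

#' Univariable screening of misclassification predictors
#'
#' For each candidate variable, tests association with the outcome on the
#' variable x outcome contingency table using the Pearson chi-square test,
#' falling back to Fisher's exact test when any expected cell count is
#' below 5. Rows with a missing outcome (patients in whom the outcome is
#' undefined) or missing variable are dropped per test; variables with
#' fewer than two observed levels are skipped with a message.
#'
#' @param rows Covariate tibble from [label_outcomes()].
#' @param outcome Name of the outcome column (`"outcome_fn"` or
#'   `"outcome_fp"`).
#' @param variables Character vector of covariate columns (default
#'   [predictor_variables()]).
#' @param alpha Significance threshold recorded in the output (default
#'   0.05).
#' @return Tibble `variable`, `method`, `statistic`, `df`, `p_value`,
#'   `significant`.
#' @export
univariable_screen <- function(rows, outcome = "outcome_fn",
                               variables = predictor_variables(),
                               alpha = 0.05) {
  out <- purrr::map(variables, function(v) {
    d <- rows[!is.na(rows[[outcome]]) & !is.na(rows[[v]]), c(v, outcome)]
    x <- if (is.factor(d[[v]])) droplevels(d[[v]]) else factor(d[[v]])
    y <- factor(d[[outcome]], levels = c(FALSE, TRUE))
    if (nlevels(x) < 2 || length(unique(d[[outcome]])) < 2) {
      message("skipping ", v, ": fewer than two observed levels")
      return(NULL)
    }
    tab <- table(x, y)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- fisher.test(tab)
      tibble(
        variable = v, method = "fisher_exact", statistic = NA_real_,
        df = NA_real_, p_value = ft$p.value
      )
    } else {
      ct <- chisq.test(tab, correct = FALSE)
      tibble(
        variable = v, method = "pearson_chisq",
        statistic = unname(ct$statistic),
        df = unname(ct$parameter), p_value = ct$p.value
      )
    }
  })
  empty <- tibble(
    variable = character(), method = character(), statistic = numeric(),
    df = numeric(), p_value = numeric()
  )
  dplyr::bind_rows(c(list(empty), out)) |>
    mutate(significant = .data$p_value < alpha)
}

#' Multivariable logistic model of misclassification
#'
#' Fits a maximum-likelihood logistic regression of the outcome on the
#' selected variables (indicator contrasts against each factor's
#' reference level) and reports odds ratios with Wald 95% confidence
#' intervals. Non-convergence or separation (detected via glm's
#' convergence flag or exploding standard errors) is flagged in the
#' result, never silently dropped.
#'
#' @inheritParams univariable_screen
#' @param variables Variables to enter (typically the univariably
#'   significant ones; see `entry_p` of [predictor_report()] for the
#'   p < 0.1 sensitivity-entry variant).
#' @return List with `estimates` (tibble `term`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`), `n` (rows used), `converged`, `era` attribute
#'   columns left to the caller, and the underlying `fit`.
#' @export
fit_multivariable <- function(rows, outcome = "outcome_fn",
                              variables = predictor_variables()) {
  d <- rows[!is.na(rows[[outcome]]), c(variables, outcome), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0) stop("no complete rows to fit on", call. = FALSE)
  d[[outcome]] <- as.integer(d[[outcome]])
  fml <- stats::as.formula(
    paste(outcome, "~", paste(variables, collapse = " + "))
  )
  fit <- suppressWarnings(glm(fml,
    data = d, family = binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)
  ))
  est <- coef(summary(fit))
  keep <- rownames(est) != "(Intercept)"
  se <- est[keep, "Std. Error"]
  beta <- est[keep, "Estimate"]
  z <- qnorm(0.975)
  converged <- isTRUE(fit$converged) && all(is.finite(se)) && all(se < 10)
  if (!converged) {
    warning("logistic model did not converge cleanly (possible separation)",
      call. = FALSE
    )
  }
  list(
    estimates = tibble(
      term = rownames(est)[keep],
      odds_ratio = exp(beta),
      ci_low = exp(beta - z * se),
      ci_high = exp(beta + z * se),
      p_value = est[keep, "Pr(>|z|)"]
    ),
    n = nrow(d),
    converged = converged,
    fit = fit
  )
}

#' Era-stratified misclassification predictor report
#'
#' Runs the full predictor workflow separately per era: univariable
#' screening of every candidate variable against false negatives (and
#' false positives), then -- only where at least one variable screens in --
#' a multivariable logistic model of the significant variables. No
#' multivariable model is fitted for an outcome with no significant
#' univariable association (as is typical for false positives, which are
#' rare).
#'
#' @param covariates Output of [label_outcomes()].
#' @param entry_p Univariable p-value threshold for entry into the
#'   multivariable model: 0.05 by default, 0.1 for the sensitivity
#'   variant.
#' @param variables Candidate variables.
#' @return List with `screening` (tibble over era x outcome x variable)
#'   and `models` (list keyed `era.outcome` of [fit_multivariable()]
#'   results).
#' @export
predictor_report <- function(covariates, entry_p = 0.05,
                             variables = predictor_variables()) {
  eras <- unique(covariates$era)
  screening <- list()
  models <- list()
  for (era in eras) {
    d <- filter(covariates, .data$era == !!era)
    for (outcome in c("outcome_fn", "outcome_fp")) {
      sc <- univariable_screen(d, outcome, variables) |>
        mutate(era = era, outcome = outcome, .before = 1)
      screening[[paste(era, outcome, sep = ".")]] <- sc
      selected <- sc$variable[sc$p_value < entry_p]
      if (length(selected) > 0) {
        models[[paste(era, outcome, sep = ".")]] <-
          fit_multivariable(d, outcome, selected)
      }
    }
  }
  list(screening = dplyr::bind_rows(screening), models = models)
}
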