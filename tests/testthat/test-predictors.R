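test_that("Charlson index scores mapped conditions with original weights", {
  expect_equal(charlson_index(character(0), 10), 0L)
  expect_equal(charlson_index(c("I10", "K219"), 10), 0L) # unmapped codes
  # CHF (1) + any malignancy (2) = 3, both versions
  expect_equal(charlson_index(c("I500", "C50"), 10), 3L)
  expect_equal(charlson_index(c("4280", "1749"), 9), 3L)
  # punctuation/sub-code tolerant
  expect_equal(charlson_index("i50.0", 10), 1L)
  expect_error(charlson_index("I500", 11), "9 or 10")
})

test_that("diabetes contributes nothing when excluded, its weight otherwise", {
  expect_equal(charlson_index(c("E1122", "E119"), 10, exclude_diabetes = TRUE), 0L)
  expect_equal(charlson_index("E119", 10, exclude_diabetes = FALSE), 1L)
  expect_equal(charlson_index("E1122", 10, exclude_diabetes = FALSE), 2L)
  expect_equal(charlson_index("25000", 9, exclude_diabetes = TRUE), 0L)
  expect_equal(charlson_index("25041", 9, exclude_diabetes = FALSE), 2L)
})

test_that("condition hierarchies count only the most severe form", {
  # complicated supersedes uncomplicated diabetes
  expect_equal(
    charlson_index(c("E119", "E1122"), 10, exclude_diabetes = FALSE), 2L
  )
  # severe liver supersedes mild
  expect_equal(charlson_index(c("K70", "K721"), 10), 3L)
  # metastatic supersedes any malignancy
  expect_equal(charlson_index(c("C50", "C78"), 10), 6L)
})

test_that("Charlson is monotone non-decreasing under code-set inclusion", {
  pool <- c(
    "I500", "J449", "N189", "C50", "C78", "K70", "K721", "B20",
    "G81", "M05", "I10", "E780", "486"
  )
  withr::with_seed(99, {
    for (i in 1:50) {
      codes <- sample(pool, sample.int(length(pool), 1))
      extra <- sample(pool, 1)
      expect_gte(
        charlson_index(c(codes, extra), 10),
        charlson_index(codes, 10)
      )
    }
  })
})

test_that("the shipped condition map is well-formed", {
  map <- charlson_map()
  expect_setequal(unique(map$icd_version), c(9L, 10L))
  expect_equal(anyDuplicated(map[, c("condition", "icd_version", "prefix")]), 0L)
  expect_true(all(map$weight %in% c(1, 2, 3, 6)))
  expect_equal(length(unique(map$condition)), 17)
})

test_that("outcomes are defined only in their reference group", {
  adm <- dplyr::bind_rows(
    make_admission("p1", "a1", "2003-03-01", principal = "I214"), # FN
    make_admission("p2", "a2", "2003-03-01",
      principal = "I214", secondary = "E119"
    ), # TP
    make_admission("p3", "a3", "2003-03-01",
      principal = "I214", secondary = "E119"
    ), # FP
    make_admission("p4", "a4", "2003-03-01", principal = "I214") # TN
  )
  mr <- dplyr::bind_rows(
    make_medical_record("p1", "a1", "present"),
    make_medical_record("p2", "a2", "present"),
    make_medical_record("p3", "a3", "absent"),
    make_medical_record("p4", "a4", "absent")
  )
  cohort <- build_cohort(adm, mr,
    era_windows = list(ICD10 = c("2002-01-01", "2004-12-31")),
    age_bounds = NULL
  )
  asc <- ascertain(cohort, adm, windows = "index")
  cov <- label_outcomes(cohort, asc, adm)
  cov <- cov[match(c("p1", "p2", "p3", "p4"), cov$person_id), ]
  expect_equal(cov$outcome_fn, c(TRUE, FALSE, NA, NA))
  expect_equal(cov$outcome_fp, c(NA, NA, TRUE, FALSE))
})

test_that("covariate bands partition their domains with the reported baselines", {
  sim <- small_sim(seed = 55)
  cohort <- build_cohort(sim$dat$admissions, sim$dat$medical_records,
    era_windows = sim$cfg$era_windows, age_bounds = NULL
  )
  asc <- ascertain(cohort, sim$dat$admissions, windows = "index")
  cov <- label_outcomes(cohort, asc, sim$dat$admissions)
  expect_equal(levels(cov$los_band), c(">=6", "1-2", "3-5"))
  expect_equal(levels(cov$age_band), c("25-50", "51-65", "66-79"))
  expect_equal(levels(cov$comorbidity_band), c(">=8", "0-3", "4-7"))
  expect_equal(levels(cov$charlson_band), c(">=5", "0", "1-4"))
  expect_equal(levels(cov$admission_type), c("emergency", "elective"))
  expect_equal(levels(cov$principal_dx_group), c("other_CHD", "MI", "UA"))
  expect_false(anyNA(cov$los_band))
  expect_false(anyNA(cov$age_band))
  expect_false(anyNA(cov$comorbidity_band))
})

test_that("univariable screening matches a textbook chi-square and takes the Fisher branch", {
  # elective-admission false-negative pattern: 12/47 elective vs 22/332
  # emergency FN among reference-positives -- strongly associated either
  # way, and with one expected cell at 4.2 the small-cell rule kicks in
  rows <- tibble::tibble(
    outcome_fn = rep(c(TRUE, FALSE, TRUE, FALSE), c(12, 35, 22, 310)),
    admission_type = factor(
      rep(c("elective", "elective", "emergency", "emergency"),
        c(12, 35, 22, 310)
      ),
      levels = c("emergency", "elective")
    )
  )
  res <- univariable_screen(rows, "outcome_fn", "admission_type")
  expect_equal(res$method, "fisher_exact")
  expect_true(res$significant)
  tab <- matrix(c(22, 310, 12, 35), 2, byrow = TRUE)
  # the chi-square evidence itself is strong too (textbook oracle)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_lt(pchisq(sum((tab - e)^2 / e), 1, lower.tail = FALSE), 0.05)

  # all expected cells >= 5: Pearson branch, against the textbook formula
  rows_big <- tibble::tibble(
    outcome_fn = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 100, 40, 300)),
    grp = factor(rep(c("a", "a", "b", "b"), c(30, 100, 40, 300)))
  )
  res_big <- univariable_screen(rows_big, "outcome_fn", "grp")
  tab_big <- matrix(c(100, 30, 300, 40), 2, byrow = TRUE)
  e_big <- outer(rowSums(tab_big), colSums(tab_big)) / sum(tab_big)
  stat <- sum((tab_big - e_big)^2 / e_big)
  expect_equal(res_big$method, "pearson_chisq")
  expect_equal(res_big$statistic, stat, tolerance = 1e-10)
  expect_equal(res_big$p_value, pchisq(stat, 1, lower.tail = FALSE))

  # small expected cell -> Fisher's exact, against the hypergeometric oracle
  rows2 <- tibble::tibble(
    outcome_fn = rep(c(TRUE, FALSE, TRUE, FALSE), c(3, 4, 2, 40)),
    rare = factor(rep(c("yes", "yes", "no", "no"), c(3, 4, 2, 40)))
  )
  res2 <- univariable_screen(rows2, "outcome_fn", "rare")
  expect_equal(res2$method, "fisher_exact")
  tab2 <- table(rows2$rare, factor(rows2$outcome_fn, c(FALSE, TRUE)))
  expect_equal(res2$p_value, fisher.test(tab2)$p.value)

  # degenerate single-level variable is skipped
  rows3 <- tibble::tibble(outcome_fn = c(TRUE, FALSE), constant = factor("x"))
  expect_message(
    res3 <- univariable_screen(rows3, "outcome_fn", "constant"),
    "fewer than two"
  )
  expect_equal(nrow(res3), 0)
})

test_that("a perfectly balanced table is non-significant", {
  rows <- tibble::tibble(
    outcome_fn = rep(c(TRUE, FALSE, TRUE, FALSE), each = 25),
    grp = factor(rep(c("a", "a", "b", "b"), each = 25))
  )
  res <- univariable_screen(rows, "outcome_fn", "grp")
  expect_equal(res$p_value, 1)
})

test_that("single-covariate logistic OR equals the cross-product ratio", {
  rows <- tibble::tibble(
    outcome_fn = rep(c(TRUE, FALSE, TRUE, FALSE), c(12, 35, 22, 310)),
    elective = rep(c(TRUE, TRUE, FALSE, FALSE), c(12, 35, 22, 310))
  )
  fit <- fit_multivariable(rows, "outcome_fn", "elective")
  or_closed <- (12 * 310) / (35 * 22)
  expect_equal(fit$estimates$odds_ratio, or_closed, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$n, 379)
})

test_that("a null model's confidence intervals cover 1", {
  withr::with_seed(404, {
    rows <- tibble::tibble(
      outcome_fn = runif(800) < 0.2,
      x1 = runif(800) < 0.5,
      x2 = factor(sample(c("a", "b", "c"), 800, replace = TRUE))
    )
    fit <- fit_multivariable(rows, "outcome_fn", c("x1", "x2"))
    expect_true(all(fit$estimates$ci_low < 1 & fit$estimates$ci_high > 1))
  })
})

test_that("separation is flagged, not silently reported", {
  rows <- tibble::tibble(
    outcome_fn = rep(c(TRUE, FALSE), each = 20),
    x = rep(c(TRUE, FALSE), each = 20)
  )
  expect_warning(fit <- fit_multivariable(rows, "outcome_fn", "x"), "converge")
  expect_false(fit$converged)
})

test_that("no multivariable model is fitted when nothing screens in", {
  withr::with_seed(505, {
    cov <- tibble::tibble(
      era = "ICD10",
      outcome_fn = NA, # no reference-positives: FN model impossible
      outcome_fp = runif(400) < 0.02,
      grp = factor(sample(c("a", "b"), 400, replace = TRUE))
    )
    rep <- suppressMessages(
      predictor_report(cov, variables = "grp")
    )
    expect_equal(length(rep$models), 0)
    fp_rows <- rep$screening[rep$screening$outcome == "outcome_fp", ]
    expect_true(all(!fp_rows$significant))
  })
})

test_that("parameters are recovered when the generating model is logistic", {
  # outcome generated with OR = 3 for one binary covariate
  withr::with_seed(606, {
    n <- 1500
    x <- runif(n) < 0.3
    p <- stats::plogis(stats::qlogis(0.10) + log(3) * x)
    rows <- tibble::tibble(outcome_fn = runif(n) < p, x = x)
    fit <- fit_multivariable(rows, "outcome_fn", "x")
    expect_true(fit$estimates$ci_low < 3 & fit$estimates$ci_high > 3)
  })
})
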