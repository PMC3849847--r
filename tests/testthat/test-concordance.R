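test_that("build_two_by_two cross-classifies paired vectors", {
  t <- build_two_by_two(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unlist(t[c("tp", "fp", "fn", "tn")]), c(tp = 1, fp = 1, fn = 1, tn = 1))
  t2 <- build_two_by_two(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(t2$fn + t2$fp, 0)
  expect_error(build_two_by_two(c(TRUE), c(TRUE, FALSE)), "length")
  expect_error(two_by_two(-1, 0, 0, 5), "non-negative")
  expect_error(two_by_two(0, 0, 0, 0), "at least one")
})

test_that("a fixture built to carry known margins reproduces its table", {
  # 2258 paired rows with tp=643, fp=27, fn=146, tn=1442
  ref <- rep(c(TRUE, TRUE, FALSE, FALSE), c(643, 146, 27, 1442))
  tst <- rep(c(TRUE, FALSE, TRUE, FALSE), c(643, 146, 27, 1442))
  ord <- withr::with_seed(1, sample.int(2258))
  t <- build_two_by_two(ref[ord], tst[ord])
  expect_equal(
    unlist(t[c("tp", "fp", "fn", "tn")]),
    c(tp = 643, fp = 27, fn = 146, tn = 1442)
  )
})

test_that("perfect agreement gives 100% observed agreement and kappa", {
  m <- concordance_measures(two_by_two(40, 0, 0, 120))
  expect_equal(m$observed_agreement, 100)
  expect_equal(m$kappa, 100)
  expect_equal(m$under_over, 0)
})

test_that("measures with empty denominators are NA-flagged, not zero", {
  m <- concordance_measures(two_by_two(0, 0, 0, 10)) # no reference-positives
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
  expect_true(is.na(m$under_over))
  expect_equal(m$specificity, 100)
  # all-one-cell table: chance agreement is 1, kappa undefined
  expect_true(is.na(concordance_measures(two_by_two(0, 0, 0, 7))$kappa))
})

test_that("kappa agrees with an independent brute-force computation", {
  brute_kappa <- function(tp, fp, fn, tn) {
    n <- tp + fp + fn + tn
    po <- (tp + tn) / n
    p_test_pos <- (tp + fp) / n
    p_ref_pos <- (tp + fn) / n
    pe <- p_test_pos * p_ref_pos + (1 - p_test_pos) * (1 - p_ref_pos)
    (po - pe) / (1 - pe)
  }
  withr::with_seed(303, {
    for (i in 1:200) {
      cells <- rpois(4, lambda = sample(c(2, 10, 80), 1)) + c(1, 0, 0, 1)
      m <- concordance_measures(two_by_two(cells[1], cells[2], cells[3], cells[4]))
      want <- 100 * brute_kappa(cells[1], cells[2], cells[3], cells[4])
      if (is.finite(want)) expect_equal(m$kappa, want, tolerance = 1e-12)
    }
  })
})

test_that("under/over-estimation equals its test-vs-reference-positive identity", {
  expect_equal(round_half_away(under_over_estimation(81.5, 96.0)), -15.1)
  expect_equal(under_over_estimation(50, 50), 0)
  expect_equal(round_half_away(under_over_estimation(92.6, 91.9)), 0.8)
  expect_true(is.na(under_over_estimation(50, 0)))
  # algebraic identity: (sens/ppv - 1)*100 == (test-pos/ref-pos - 1)*100
  withr::with_seed(304, {
    for (i in 1:100) {
      cells <- rpois(4, 20) + 1
      t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
      m <- concordance_measures(t)
      direct <- ((t$tp + t$fp) / (t$tp + t$fn) - 1) * 100
      expect_equal(m$under_over, direct, tolerance = 1e-10)
      alt <- 100 * (t$fp - t$fn) / (t$tp + t$fn)
      expect_equal(m$under_over, alt, tolerance = 1e-10)
    }
  })
})

test_that("McNemar: large-sample statistic, exact fallback and degenerate case", {
  # fn=146, fp=27: (146-27)^2/173, p from the chi-square tail
  mc <- mcnemar_test(two_by_two(643, 27, 146, 1442))
  expect_equal(mc$statistic, (146 - 27)^2 / 173, tolerance = 1e-12)
  expect_equal(mc$statistic, 81.86, tolerance = 1e-4)
  expect_lt(mc$p_value, 1e-15)
  expect_equal(mc$p_value, pchisq((146 - 27)^2 / 173, 1, lower.tail = FALSE))
  # symmetric discordance
  mc2 <- mcnemar_test(two_by_two(10, 30, 30, 10))
  expect_equal(mc2$statistic, 0)
  expect_equal(mc2$p_value, 1)
  # no discordant pairs
  mc3 <- mcnemar_test(two_by_two(5, 0, 0, 5))
  expect_equal(mc3$p_value, 1)
  # exact binomial fallback: 10 of 12 discordant, brute-force two-sided sum
  mc4 <- mcnemar_test(two_by_two(50, 2, 10, 50))
  expect_equal(mc4$method, "mcnemar_exact")
  k <- 0:12
  probs <- choose(12, k) * 0.5^12
  brute_p <- sum(probs[probs <= probs[11] + 1e-12])
  expect_equal(mc4$p_value, brute_p, tolerance = 1e-12)
})

test_that("chi-square used for measure comparison matches the textbook formula", {
  pearson <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  withr::with_seed(305, {
    for (i in 1:200) {
      tab <- matrix(rpois(4, sample(c(5, 30, 200), 1)) + 1, 2)
      got <- suppressWarnings(chisq.test(tab, correct = FALSE))
      expect_equal(unname(got$statistic), pearson(tab), tolerance = 1e-10)
      expect_equal(
        got$p.value, pchisq(pearson(tab), 1, lower.tail = FALSE),
        tolerance = 1e-12
      )
    }
  })
})

test_that("between-sample comparison flags the sensitivity drop between eras", {
  t9 <- two_by_two(346, 17, 34, 1288)
  t10 <- two_by_two(643, 27, 146, 1442)
  cmp <- compare_measures(t9, t10)
  sens <- cmp[cmp$measure == "sensitivity", ]
  expect_lt(sens$p_value, 0.0001)
  expect_equal(round_half_away(sens$value_a), 91.1)
  expect_equal(round_half_away(sens$value_b), 81.5)
  npv <- cmp[cmp$measure == "npv", ]
  expect_lt(npv$p_value, 0.0001)
  # identical tables: every comparison is null
  same <- compare_measures(t9, t9)
  expect_true(all(same$p_value == 1))
  expect_true(all(same$statistic == 0, na.rm = TRUE))
})

test_that("the log-ratio z-test holds its nominal size under the null", {
  # two samples from identical parameters; reject rate at alpha=0.05
  withr::with_seed(306, {
    n <- 600
    p <- c(tp = 0.25, fp = 0.05, fn = 0.08, tn = 0.62)
    rejections <- vapply(seq_len(500), function(i) {
      ca <- as.vector(stats::rmultinom(1, n, p))
      cb <- as.vector(stats::rmultinom(1, n, p))
      ta <- two_by_two(ca[1], ca[2], ca[3], ca[4])
      tb <- two_by_two(cb[1], cb[2], cb[3], cb[4])
      uo <- compare_measures(ta, tb)
      uo$p_value[uo$measure == "under_over"] < 0.05
    }, logical(1))
    rate <- mean(rejections)
    expect_gt(rate, 0.02)
    expect_lt(rate, 0.09)
  })
})

test_that("the bootstrap cross-check agrees with the z-test on a clear difference", {
  t9 <- two_by_two(346, 17, 34, 1288)
  t10 <- two_by_two(643, 27, 146, 1442)
  bs <- bootstrap_under_over_diff(t9, t10, n_boot = 500, seed = 7)
  expect_equal(
    bs$diff,
    concordance_measures(t9)$under_over - concordance_measures(t10)$under_over
  )
  # observed difference ~ +10.7pp; interval excludes zero, like the z-test
  expect_gt(bs$ci_low, 0)
  expect_lt(bs$p_value, 0.05)
  expect_identical(
    bootstrap_under_over_diff(t9, t10, n_boot = 200, seed = 3),
    bootstrap_under_over_diff(t9, t10, n_boot = 200, seed = 3)
  )
})

test_that("stratified concordance reproduces a known fixture table", {
  ref <- rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 10, 5, 55))
  tst <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 5, 55))
  cohort <- tibble::tibble(
    person_id = sprintf("p%03d", 1:100), era = "ICD10",
    reference_diabetes = ref, not_recorded_flag = FALSE
  )
  asc <- tibble::tibble(
    person_id = cohort$person_id, era = "ICD10",
    window = factor("index", levels = "index"),
    administrative_diabetes = tst
  )
  conc <- concordance_by_stratum(cohort, asc)
  expect_equal(conc$tp, 30)
  expect_equal(conc$fn, 10)
  expect_equal(conc$sensitivity, 75)
  expect_equal(conc$specificity, 100 * 55 / 60)
  expect_equal(conc$mcnemar_p, mcnemar_test(two_by_two(30, 5, 10, 55))$p_value)
})
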