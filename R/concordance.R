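#' Build a 2x2 concordance table
#'
#' Cross-classifies a paired test classification (administrative status)
#' against the reference standard (medical record): `tp` = both positive,
#' `fn` = reference-positive only, `fp` = test-positive only, `tn` = both
#' negative.
#'
#' @param reference,test Equal-length logical vectors (pairwise complete).
#' @return A `two_by_two` object: named list `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' build_two_by_two(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
build_two_by_two <- function(reference, test) {
  if (length(reference) != length(test)) {
    stop("`reference` and `test` must have the same length", call. = FALSE)
  }
  reference <- as.logical(reference)
  test <- as.logical(test)
  if (anyNA(reference) || anyNA(test)) {
    stop("`reference` and `test` must not contain NA", call. = FALSE)
  }
  two_by_two(
    tp = sum(reference & test),
    fp = sum(!reference & test),
    fn = sum(reference & !test),
    tn = sum(!reference & !test)
  )
}

#' @rdname build_two_by_two
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) < 1) stop("table must contain at least one pair", call. = FALSE)
  structure(
    as.list(setNames(as.integer(cells), names(cells))),
    class = "two_by_two"
  )
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn),
    nrow = 2,
    dimnames = list(test = c("+", "-"), reference = c("+", "-"))
  )
  cat("2x2 concordance table (n =", sum(unlist(x)), ")\n")
  print(m)
  invisible(x)
}

n_pairs <- function(t) t$tp + t$fp + t$fn + t$tn

#' Concordance measures for a 2x2 table
#'
#' Computes the standard validation measures of administrative data
#' against a reference standard, each expressed as a percentage:
#' observed agreement `(tp+tn)/n`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, positive and negative predictive values, Cohen's kappa
#' `(p_o - p_e)/(1 - p_e)` with the usual marginal chance agreement
#' `p_e = [(tp+fp)(tp+fn) + (fn+tn)(fp+tn)]/n^2`, and the net
#' under/over-estimation statistic `(sensitivity/PPV - 1) x 100` (negative
#' values: administrative data undercount reference-positive cases).
#' A measure whose denominator is zero (or `p_e = 1` for kappa) is
#' returned as `NA` rather than 0.
#'
#' @param t A `two_by_two` table.
#' @return One-row tibble: `n`, `tp`, `fp`, `fn`, `tn`,
#'   `observed_agreement`, `kappa`, `sensitivity`, `specificity`, `ppv`,
#'   `npv` (percentages, unrounded) and `under_over` (signed percentage).
#'   Round for presentation with [round_half_away()].
#' @export
#' @examples
#' concordance_measures(two_by_two(643, 27, 146, 1442))
concordance_measures <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  n <- n_pairs(t)
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- ratio(t$tp, t$tp + t$fn)
  spec <- ratio(t$tn, t$tn + t$fp)
  ppv <- ratio(t$tp, t$tp + t$fp)
  npv <- ratio(t$tn, t$tn + t$fn)
  oa <- ratio(t$tp + t$tn, n)
  p_e <- ((t$tp + t$fp) * (t$tp + t$fn) + (t$fn + t$tn) * (t$fp + t$tn)) / n^2
  kappa <- if (abs(1 - p_e) > .Machine$double.eps^0.5) {
    100 * (oa / 100 - p_e) / (1 - p_e)
  } else {
    NA_real_
  }
  tibble(
    n = n, tp = t$tp, fp = t$fp, fn = t$fn, tn = t$tn,
    observed_agreement = oa, kappa = kappa,
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    under_over = under_over_estimation(sens, ppv)
  )
}

#' Net under/over-estimation of prevalence
#'
#' `(sensitivity / PPV - 1) x 100`: the relative difference between the
#' number of test-positives and reference-positives. Negative values mean
#' the administrative source undercounts true cases (under-estimation);
#' positive values mean over-estimation.
#'
#' @param sensitivity,ppv Percentages (or proportions, as long as both are
#'   on the same scale); `ppv` must be positive.
#' @return Signed percentage.
#' @export
#' @examples
#' under_over_estimation(81.5, 96.0) # about -15.1
under_over_estimation <- function(sensitivity, ppv) {
  ifelse(is.na(sensitivity) | is.na(ppv) | ppv <= 0,
    NA_real_,
    (sensitivity / ppv - 1) * 100
  )
}

#' McNemar's test for paired prevalence difference
#'
#' Tests whether the administrative and reference classifications disagree
#' symmetrically, i.e. whether the two sources give the same prevalence.
#' Uses the large-sample statistic `(fn - fp)^2 / (fn + fp)` (1 df, no
#' continuity correction) when the number of discordant pairs is at least
#' `exact_threshold`, and the exact two-sided binomial test on the
#' discordant pairs otherwise. With no discordant pairs the statistic is 0
#' and `p = 1`.
#'
#' @param t A `two_by_two` table.
#' @param exact_threshold Discordant-pair count below which the exact
#'   binomial test is used (default 25).
#' @return Tibble `method`, `statistic`, `df`, `p_value`.
#' @export
mcnemar_test <- function(t, exact_threshold = 25) {
  stopifnot(inherits(t, "two_by_two"))
  d <- t$fn + t$fp
  if (d == 0) {
    return(tibble(
      method = "mcnemar_chisq", statistic = 0,
      df = 1, p_value = 1
    ))
  }
  if (d < exact_threshold) {
    p <- binom.test(t$fn, d, p = 0.5)$p.value
    return(tibble(
      method = "mcnemar_exact", statistic = NA_real_,
      df = NA_real_, p_value = p
    ))
  }
  stat <- (t$fn - t$fp)^2 / d
  tibble(
    method = "mcnemar_chisq", statistic = stat, df = 1,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE)
  )
}

# variance of log(test-positives/reference-positives) treating the four
# cells as multinomial; sens/ppv = (tp+fp)/(tp+fn), so the delta method
# gives var = 1/A + 1/B - 2*tp/(A*B) with A = tp+fp, B = tp+fn.
log_ratio_variance <- function(t) {
  a <- t$tp + t$fp
  b <- t$tp + t$fn
  if (a == 0 || b == 0) {
    return(NA_real_)
  }
  1 / a + 1 / b - 2 * t$tp / (a * b)
}

#' Compare concordance measures between two independent samples
#'
#' Rate measures (sensitivity, specificity, PPV, NPV, observed agreement)
#' are compared with a Pearson chi-square (no continuity correction) on
#' the measure's own numerator/denominator 2x2 across the samples -- e.g.
#' sensitivity compares `tp` vs `fn` of each sample. The
#' under/over-estimation statistic, a ratio of sensitivity to PPV, is
#' compared with a two-sample z-test on `log(sensitivity/PPV)` with
#' delta-method variances treating each sample's cells as multinomial;
#' [bootstrap_under_over_diff()] offers a resampling cross-check.
#'
#' @param table_a,table_b `two_by_two` tables from the two samples.
#' @return Tibble with one row per measure: `measure`, `value_a`,
#'   `value_b` (unrounded percentages), `method`, `statistic`, `df`,
#'   `p_value`. Measures with a zero denominator in either sample are
#'   skipped with a message.
#' @export
compare_measures <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "two_by_two"), inherits(table_b, "two_by_two"))
  ma <- concordance_measures(table_a)
  mb <- concordance_measures(table_b)

  pairs <- list(
    sensitivity = function(t) c(t$tp, t$fn),
    specificity = function(t) c(t$tn, t$fp),
    ppv = function(t) c(t$tp, t$fp),
    npv = function(t) c(t$tn, t$fn),
    observed_agreement = function(t) c(t$tp + t$tn, t$fp + t$fn)
  )
  rows <- purrr::imap(pairs, function(cells, measure) {
    tab <- rbind(cells(table_a), cells(table_b))
    if (any(rowSums(tab) == 0)) {
      message("skipping ", measure, ": zero denominator")
      return(NULL)
    }
    if (identical(tab[1, ], tab[2, ]) && any(colSums(tab) == 0)) {
      # degenerate identical margins: no information, agreement is exact
      return(tibble(
        measure = measure, value_a = ma[[measure]], value_b = mb[[measure]],
        method = "pearson_chisq", statistic = 0, df = 1, p_value = 1
      ))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble(
      measure = measure, value_a = ma[[measure]], value_b = mb[[measure]],
      method = "pearson_chisq",
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p_value = if (is.nan(ct$p.value)) 1 else ct$p.value
    )
  })

  va <- log_ratio_variance(table_a)
  vb <- log_ratio_variance(table_b)
  uo <- if (is.na(va) || is.na(vb)) {
    message("skipping under_over: zero denominator")
    NULL
  } else {
    ra <- log((table_a$tp + table_a$fp) / (table_a$tp + table_a$fn))
    rb <- log((table_b$tp + table_b$fp) / (table_b$tp + table_b$fn))
    z <- if (va + vb == 0) 0 else (ra - rb) / sqrt(va + vb)
    tibble(
      measure = "under_over",
      value_a = ma$under_over, value_b = mb$under_over,
      method = "z_log_ratio", statistic = z, df = NA_real_,
      p_value = 2 * pnorm(-abs(z))
    )
  }
  dplyr::bind_rows(c(rows, list(uo)))
}

#' Bootstrap comparison of under/over-estimation between samples
#'
#' Percentile-bootstrap cross-check for the delta-method z-test in
#' [compare_measures()]: resamples each sample's cell counts
#' multinomially, recomputes the difference in under/over-estimation, and
#' returns the percentile confidence interval and a two-sided p-value from
#' the bootstrap distribution's tail crossing zero.
#'
#' @inheritParams compare_measures
#' @param n_boot Number of resamples (default 2000).
#' @param seed Integer seed for reproducibility.
#' @param conf_level Confidence level for the percentile interval.
#' @return Tibble `diff` (observed `a - b` difference, percentage points),
#'   `ci_low`, `ci_high`, `p_value`, `n_boot`.
#' @export
bootstrap_under_over_diff <- function(table_a, table_b, n_boot = 2000,
                                      seed = 1L, conf_level = 0.95) {
  stopifnot(inherits(table_a, "two_by_two"), inherits(table_b, "two_by_two"))
  uo <- function(t) {
    m <- concordance_measures(t)
    m$under_over
  }
  resample <- function(t) {
    counts <- unlist(t)
    stats::rmultinom(1, sum(counts), counts / sum(counts))[, 1]
  }
  obs <- uo(table_a) - uo(table_b)
  diffs <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ca <- resample(table_a)
      cb <- resample(table_b)
      ta <- two_by_two(ca[1], ca[2], ca[3], ca[4])
      tb <- two_by_two(cb[1], cb[2], cb[3], cb[4])
      uo(ta) - uo(tb)
    }, numeric(1))
  })
  diffs <- diffs[is.finite(diffs)]
  alpha <- 1 - conf_level
  ci <- stats::quantile(diffs, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  tibble(
    diff = obs, ci_low = ci[1], ci_high = ci[2],
    p_value = min(p, 1), n_boot = length(diffs)
  )
}

#' Concordance results per stratum and lookback window
#'
#' Joins the cohort's reference classification to the long ascertainment
#' table and computes, for each stratum x window cell, the full set of
#' concordance measures plus McNemar's paired test of the prevalence
#' difference -- the tidy analogue of a published
#' stratum-by-lookback-window concordance table.
#'
#' @param cohort Cohort tibble (needs `person_id`, `era`,
#'   `reference_diabetes`; plus any stratification columns).
#' @param ascertainment Long tibble from [ascertain()].
#' @param strata Character vector of cohort columns to stratify by
#'   (default `"era"`; use e.g. `c("era", "indigenous_derived")`).
#' @param drop_not_recorded If `TRUE`, rows flagged `not_recorded_flag`
#'   are removed first (sensitivity analysis).
#' @return Tibble: stratum columns, `window`, cell counts, all measures
#'   (unrounded percentages), `mcnemar_statistic`, `mcnemar_p`.
#' @export
concordance_by_stratum <- function(cohort, ascertainment, strata = "era",
                                   drop_not_recorded = FALSE) {
  if (drop_not_recorded) {
    cohort <- filter(cohort, !.data$not_recorded_flag)
  }
  joined <- ascertainment |>
    inner_join(
      cohort |> select(all_of(unique(c("person_id", "era", strata,
        "reference_diabetes")))),
      by = c("person_id", "era")
    )
  joined |>
    group_by(across(all_of(c(strata, "window")))) |>
    group_modify(function(d, key) {
      t <- build_two_by_two(d$reference_diabetes, d$administrative_diabetes)
      mc <- mcnemar_test(t)
      concordance_measures(t) |>
        mutate(
          mcnemar_statistic = mc$statistic,
          mcnemar_p = mc$p_value
        )
    }) |>
    ungroup()
}
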