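#' Death indicator per report
#'
#' A report is a death when its outcome codes contain \code{DE}. Other
#' serious outcomes (life-threatening \code{LT}, hospitalization \code{HO},
#' ...) do not count as deaths.
#'
#' @param cohort an \code{"ncdia_cohort"} (or any case-report data.frame with
#'   an \code{outcomes} column of ";"-packed codes).
#' @return logical vector.
#' @export
flag_deaths <- function(cohort) {
  vapply(split_multi(cohort$outcomes), function(oc) {
    !all(is.na(oc)) && "DE" %in% oc
  }, logical(1))
}

# Clopper-Pearson exact binomial interval from beta quantiles.
clopper_pearson <- function(x, n, conf = 0.95) {
  al <- (1 - conf) / 2
  lo <- ifelse(x == 0, 0, stats::qbeta(al, x, n - x + 1))
  hi <- ifelse(x == n, 1, stats::qbeta(1 - al, x + 1, n - x))
  cbind(lo = lo, hi = hi)
}

#' Mortality summary from death / non-death counts
#'
#' The fixture-friendly core: rates and exact (Clopper-Pearson) binomial
#' confidence intervals computed directly from counts, so pre-aggregated
#' published tables can be analyzed without raw reports.
#'
#' @param deaths,non_deaths integer vectors per stratum.
#' @param label stratum labels.
#' @param conf confidence level (default 0.95).
#' @return data.frame of class \code{"mortality_summary"} with \code{label},
#'   \code{deaths}, \code{non_deaths}, \code{total}, \code{rate} (fraction),
#'   \code{ci_low}, \code{ci_high}.
#' @export
mortality_summary <- function(deaths, non_deaths, label, conf = 0.95) {
  stopifnot(all(deaths >= 0), all(non_deaths >= 0))
  n <- deaths + non_deaths
  ci <- clopper_pearson(deaths, n, conf)
  out <- data.frame(label = as.character(label), deaths = as.integer(deaths),
                    non_deaths = as.integer(non_deaths), total = as.integer(n),
                    rate = ifelse(n > 0, deaths / n, NA_real_),
                    ci_low = ifelse(n > 0, ci[, "lo"], NA_real_),
                    ci_high = ifelse(n > 0, ci[, "hi"], NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("mortality_summary", class(out))
  out
}

#' Default study-period bins
#'
#' Four intervals over the 2004–2024Q1 window: 2004–2010, 2011–2015,
#' 2016–2020, 2021–2024.
#'
#' @return data.frame with \code{label}, \code{start_year}, \code{end_year}.
#' @export
default_period_bins <- function() {
  data.frame(label = c("2004-2010", "2011-2015", "2016-2020", "2021-2024"),
             start_year = c(2004L, 2011L, 2016L, 2021L),
             end_year = c(2010L, 2015L, 2020L, 2024L),
             stringsAsFactors = FALSE)
}

#' Per-period mortality rates
#'
#' Bins target cases by the year of their FDA receipt date (the versioning
#' clock of the reporting system) and computes death rates with exact
#' binomial CIs per bin. Cases outside every bin are collected in an
#' \code{out-of-window} bucket.
#'
#' @param cohort an \code{"ncdia_cohort"}; only case rows are used.
#' @param bins data.frame as from \code{\link{default_period_bins}}.
#' @param conf confidence level.
#' @return a \code{"mortality_summary"} data.frame, one row per bin (plus the
#'   out-of-window bucket when nonempty).
#' @export
period_rates <- function(cohort, bins = default_period_bins(), conf = 0.95) {
  cases <- cohort[cohort$is_case, , drop = FALSE]
  death <- flag_deaths(cases)
  yr <- as.integer(format(cases$fda_dt, "%Y"))
  lab <- rep(NA_character_, nrow(cases))
  for (i in seq_len(nrow(bins)))
    lab[!is.na(yr) & yr >= bins$start_year[i] & yr <= bins$end_year[i]] <- bins$label[i]
  lab[is.na(lab)] <- "out-of-window"
  lev <- c(bins$label, if (any(lab == "out-of-window")) "out-of-window")
  f <- factor(lab, levels = lev)
  d <- tapply(death, f, sum, default = 0L)
  n <- tapply(rep(1L, length(death)), f, sum, default = 0L)
  mortality_summary(as.integer(d), as.integer(n - d), lev, conf)
}

#' Omnibus chi-square test across period bins
#'
#' Pearson chi-square on the k x 2 death/non-death table, k-1 degrees of
#' freedom, no continuity correction (standard for df > 1). Bins with zero
#' totals are dropped; a flag is raised when any expected cell is below 1.
#'
#' @param summary a \code{"mortality_summary"}.
#' @return list with \code{statistic}, \code{df}, \code{p},
#'   \code{low_expected} flag.
#' @export
omnibus_period_test <- function(summary) {
  s <- summary[summary$total > 0, , drop = FALSE]
  if (nrow(s) < 2L) stop("omnibus test needs at least two nonempty bins")
  m <- cbind(s$deaths, s$non_deaths)
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, low_expected = any(ct$expected < 1))
}

#' Pairwise period chi-square tests with Bonferroni correction
#'
#' Each pair of bins is compared with a 2 x 2 Pearson chi-square using the
#' Yates continuity correction; raw p-values are multiplied by the number of
#' pairs. Both the capped (at 1) and uncapped products are reported — some
#' published tables print the raw product, which can exceed 1.
#'
#' @param summary a \code{"mortality_summary"}.
#' @return data.frame with \code{period1}, \code{period2}, \code{statistic},
#'   \code{p_raw}, \code{p_adj}, \code{p_adj_uncapped}.
#' @export
pairwise_period_tests <- function(summary) {
  s <- summary[summary$total > 0 & summary$label != "out-of-window", , drop = FALSE]
  if (nrow(s) < 2L) stop("pairwise tests need at least two nonempty bins")
  pairs <- utils::combn(nrow(s), 2)
  npairs <- ncol(pairs)
  res <- lapply(seq_len(npairs), function(i) {
    i1 <- pairs[1, i]; i2 <- pairs[2, i]
    m <- rbind(c(s$deaths[i1], s$non_deaths[i1]),
               c(s$deaths[i2], s$non_deaths[i2]))
    ct <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    data.frame(period1 = s$label[i1], period2 = s$label[i2],
               statistic = unname(ct$statistic), p_raw = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p_raw * npairs)
  out$p_adj_uncapped <- out$p_raw * npairs
  out
}

#' Gender chi-square for death versus non-death cases
#'
#' 2 x 2 Pearson chi-square with Yates continuity correction on
#' (death, non-death) x (female, male) counts; unknown-sex reports are
#' excluded from the test.
#'
#' @param f_death,m_death,f_alive,m_alive counts.
#' @return list with \code{statistic}, \code{p}.
#' @export
gender_death_test <- function(f_death, m_death, f_alive, m_alive) {
  m <- rbind(c(f_death, f_alive), c(m_death, m_alive))
  ct <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Gender balance of target-case reporting
#'
#' One-degree-of-freedom goodness-of-fit chi-square of the observed
#' (female, male) report counts against a 50:50 split, unknown sex excluded,
#' no continuity correction.
#'
#' @param n_female,n_male counts.
#' @return list with \code{statistic}, \code{p}.
#' @export
gender_balance_test <- function(n_female, n_male) {
  stopifnot(n_female > 0, n_male > 0)
  ct <- stats::chisq.test(c(n_female, n_male), p = c(0.5, 0.5), correct = FALSE)
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Death versus non-death comparison battery
#'
#' Gender 2 x 2 chi-square (Yates, unknown sex excluded), Mann-Whitney
#' comparison of age, and Mann-Whitney comparison of time to onset between
#' death and non-death target cases. Missing ages/onsets are counted
#' separately, not imputed.
#'
#' @param cohort an \code{"ncdia_cohort"}.
#' @param onsets optional data.frame from \code{\link{compute_onsets}}; when
#'   supplied the onset comparison is run on it (joined by report id).
#' @return list: \code{gender} (counts + test), \code{age} (medians + test),
#'   \code{onset} (medians + test, or NULL without \code{onsets}).
#' @export
death_vs_nondeath_comparisons <- function(cohort, onsets = NULL) {
  cases <- cohort[cohort$is_case, , drop = FALSE]
  death <- flag_deaths(cases)
  cnt <- function(sx, dd) sum(cases$sex == sx & death == dd)
  gender <- list(counts = c(f_death = cnt("F", TRUE), m_death = cnt("M", TRUE),
                            f_alive = cnt("F", FALSE), m_alive = cnt("M", FALSE),
                            unk_death = cnt("UNK", TRUE), unk_alive = cnt("UNK", FALSE)))
  gender$test <- gender_death_test(gender$counts["f_death"], gender$counts["m_death"],
                                   gender$counts["f_alive"], gender$counts["m_alive"])
  age_d <- cases$age_years[death & !is.na(cases$age_years)]
  age_a <- cases$age_years[!death & !is.na(cases$age_years)]
  age <- list(median_death = stats::median(age_d),
              median_nondeath = stats::median(age_a),
              missing_death = sum(death & is.na(cases$age_years)),
              missing_nondeath = sum(!death & is.na(cases$age_years)),
              test = mann_whitney(age_d, age_a))
  onset_cmp <- NULL
  if (!is.null(onsets)) {
    od <- death[match(onsets$primaryid, cases$primaryid)]
    x <- onsets$onset_days[od]; y <- onsets$onset_days[!od]
    onset_cmp <- list(median_death = stats::median(x),
                      median_nondeath = stats::median(y),
                      missing_death = sum(death) - length(x),
                      missing_nondeath = sum(!death) - length(y),
                      test = mann_whitney(x, y))
  }
  list(gender = gender, age = age, onset = onset_cmp)
}

#' Drug-specific mortality rates
#'
#' Death rate and exact binomial CI per primary-suspect drug, restricted to
#' drugs with at least \code{min_deaths} death reports among target cases.
#'
#' @param cohort an \code{"ncdia_cohort"}.
#' @param min_deaths minimum death reports to emit a drug (default 20).
#' @param conf confidence level.
#' @return a \code{"mortality_summary"} data.frame ordered by descending
#'   rate.
#' @export
drug_mortality <- function(cohort, min_deaths = 20, conf = 0.95) {
  cases <- cohort[cohort$is_case, , drop = FALSE]
  death <- flag_deaths(cases)
  d <- tapply(death, cases$ps_drug_norm, sum)
  n <- tapply(rep(1L, nrow(cases)), cases$ps_drug_norm, sum)
  keep <- names(d)[d >= min_deaths]
  out <- mortality_summary(as.integer(d[keep]), as.integer(n[keep] - d[keep]),
                           keep, conf)
  out[order(-out$rate, out$label), , drop = FALSE]
}
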