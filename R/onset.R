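age_group_levels <- c("<18", "18-44", "45-64", ">=65", "UNK")

#' Assign the standard reporting age groups
#' @param age_years numeric vector (NA allowed).
#' @return factor over \code{<18, 18-44, 45-64, >=65, UNK}.
#' @export
age_group <- function(age_years) {
  g <- cut(age_years, breaks = c(-Inf, 18, 45, 65, Inf), right = FALSE,
           labels = c("<18", "18-44", "45-64", ">=65"))
  g <- as.character(g)
  g[is.na(g)] <- "UNK"
  factor(g, levels = age_group_levels)
}

#' Time-to-onset records for target cases
#'
#' Onset is the whole-day difference between the report's event date and the
#' primary suspect drug's earliest therapy start date (a plain difference:
#' same-day onset is 0 days). Only target cases with both dates resolved
#' qualify; records with a negative interval (start after event) are
#' excluded and counted.
#'
#' @param cohort an \code{"ncdia_cohort"}.
#' @return data.frame with \code{primaryid}, \code{ps_drug_norm},
#'   \code{atc_codes}, \code{onset_days}, \code{sex}, \code{age_group};
#'   attribute \code{"onset_log"} records exclusion counts.
#' @export
compute_onsets <- function(cohort) {
  cases <- cohort[cohort$is_case, , drop = FALSE]
  onset <- as.integer(cases$event_dt - cases$ther_start)
  resolved <- !is.na(onset)
  negative <- resolved & onset < 0
  keep <- resolved & !negative
  out <- data.frame(primaryid = cases$primaryid[keep],
                    ps_drug_norm = cases$ps_drug_norm[keep],
                    atc_codes = cases$atc_codes[keep],
                    onset_days = onset[keep],
                    sex = cases$sex[keep],
                    age_group = age_group(cases$age_years[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "onset_log") <- list(n_cases = nrow(cases),
                                 n_unresolved = sum(!resolved),
                                 n_negative = sum(negative),
                                 n_onset = nrow(out))
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' Wilcoxon rank-sum comparison of two groups. Exact enumeration when both
#' groups have at most \code{exact_max} untied observations; otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param x,y numeric vectors.
#' @param exact_max size bound for the exact test (default 8).
#' @return list with \code{U}, \code{p}, \code{defined}.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  if (length(x) == 0L || length(y) == 0L)
    return(list(U = NA_real_, p = NA_real_, defined = FALSE))
  exact <- length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, defined = TRUE)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square reference on k-1 degrees of freedom.
#' Degenerate inputs (fewer than two nonempty groups, or zero rank variance
#' because every observation is identical) are flagged rather than erroring.
#'
#' @param groups list of numeric vectors.
#' @return list with \code{H}, \code{df}, \code{p}, \code{defined}.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L)
    return(list(H = NA_real_, df = NA_integer_, p = NA_real_, defined = FALSE))
  all_vals <- unlist(groups)
  if (length(unique(all_vals)) == 1L)
    return(list(H = NA_real_, df = length(groups) - 1L, p = NA_real_,
                defined = FALSE))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value,
       defined = TRUE)
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise z-statistics on mean ranks after a Kruskal-Wallis test, with the
#' usual tie correction to the rank variance. Raw two-sided p-values are
#' multiplied by the number of pairs k(k-1)/2; the capped (at 1) value is the
#' default adjusted p, the uncapped product is also reported.
#'
#' @param groups named list of numeric vectors (>= 2 nonempty groups).
#' @return data.frame with one row per pair: \code{group1}, \code{group2},
#'   \code{z}, \code{p_raw}, \code{p_adj} (capped), \code{p_adj_uncapped}.
#' @export
dunn_bonferroni <- function(groups) {
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  groups <- groups[lengths(groups) > 0L]
  k <- length(groups)
  if (k < 2L) stop("dunn_bonferroni needs at least two nonempty groups")
  n <- lengths(groups)
  N <- sum(n)
  r <- rank(unlist(groups))
  grp <- rep(names(groups), n)
  rbar <- tapply(r, factor(grp, levels = names(groups)), mean)
  ties <- table(unlist(groups))
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2_base <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  npairs <- ncol(pairs)
  z <- vapply(seq_len(npairs), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    (rbar[[g1]] - rbar[[g2]]) /
      sqrt(sigma2_base * (1 / n[[g1]] + 1 / n[[g2]]))
  }, numeric(1))
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p_raw = p_raw,
             p_adj = pmin(1, p_raw * npairs),
             p_adj_uncapped = p_raw * npairs,
             stringsAsFactors = FALSE)
}

# median / quartiles by linear interpolation (quantile type 7)
quartile_summary <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(n = length(x), median = q[2], q1 = q[1], q3 = q[3])
}

#' Onset summaries and test battery by gender and age group
#'
#' Emits per-stratum n / median / IQR for sex (F, M) and age groups, the
#' two-group Mann-Whitney comparison of the sexes, the Kruskal-Wallis test
#' over the four age groups, and Dunn-Bonferroni pairwise age comparisons.
#' Unknown sex/age strata are tabulated but excluded from every test.
#'
#' @param onsets data.frame from \code{\link{compute_onsets}}.
#' @return list: \code{overall}, \code{by_sex}, \code{by_age} (summary
#'   data.frames), \code{sex_test}, \code{age_test}, \code{age_pairwise}.
#' @export
onset_strata_summary <- function(onsets) {
  summ <- function(split_var, levels_keep) {
    keep <- split_var %in% levels_keep
    sp <- split(onsets$onset_days[keep], factor(split_var[keep], levels = levels_keep))
    sp <- sp[lengths(sp) > 0L]
    if (length(sp) == 0L)
      return(data.frame(stratum = character(0), n = integer(0),
                        median = numeric(0), q1 = numeric(0), q3 = numeric(0)))
    qs <- t(vapply(sp, quartile_summary, numeric(4)))
    data.frame(stratum = names(sp), n = as.integer(qs[, "n"]),
               median = qs[, "median"], q1 = qs[, "q1"], q3 = qs[, "q3"],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  by_sex <- summ(onsets$sex, c("F", "M", "UNK"))
  by_age <- summ(as.character(onsets$age_group), age_group_levels)
  sexF <- onsets$onset_days[onsets$sex == "F"]
  sexM <- onsets$onset_days[onsets$sex == "M"]
  age_groups <- split(onsets$onset_days[onsets$age_group != "UNK"],
                      droplevels(onsets$age_group[onsets$age_group != "UNK"]))
  list(overall = data.frame(stratum = "Overall",
                            t(quartile_summary(onsets$onset_days))),
       by_sex = by_sex, by_age = by_age,
       sex_test = mann_whitney(sexF, sexM),
       age_test = kruskal_wallis(age_groups),
       age_pairwise = if (length(age_groups) >= 2) dunn_bonferroni(age_groups) else NULL)
}

#' Drug- and class-specific onset summaries
#'
#' Median and IQR of onset days per primary-suspect drug and per ATC level-2
#' class, restricted to drugs/classes with at least \code{min_reports} onset
#' records (sparser strata give unstable medians and are suppressed).
#'
#' @param onsets data.frame from \code{\link{compute_onsets}}.
#' @param min_reports minimum onset records to emit a stratum (default 20).
#' @return list of two data.frames, \code{by_drug} and \code{by_class}, each
#'   with \code{stratum}, \code{n}, \code{median}, \code{q1}, \code{q3},
#'   ordered by ascending median.
#' @export
drug_onset_summaries <- function(onsets, min_reports = 20) {
  summarize_split <- function(sp) {
    sp <- sp[lengths(sp) >= min_reports]
    if (length(sp) == 0L)
      return(data.frame(stratum = character(0), n = integer(0),
                        median = numeric(0), q1 = numeric(0), q3 = numeric(0)))
    qs <- t(vapply(sp, quartile_summary, numeric(4)))
    out <- data.frame(stratum = names(sp), n = as.integer(qs[, "n"]),
                      median = qs[, "median"], q1 = qs[, "q1"], q3 = qs[, "q3"],
                      row.names = NULL, stringsAsFactors = FALSE)
    out[order(out$median, out$stratum), , drop = FALSE]
  }
  by_drug <- summarize_split(split(onsets$onset_days, onsets$ps_drug_norm))
  cls_list <- lapply(split_multi(onsets$atc_codes), function(cc) {
    if (all(is.na(cc))) character(0) else unique(substr(cc, 1, 3))
  })
  long_onset <- rep(onsets$onset_days, lengths(cls_list))
  by_class <- summarize_split(split(long_onset, unlist(cls_list)))
  list(by_drug = by_drug, by_class = by_class)
}

#' Cumulative onset-percentage curve data
#'
#' For each observed onset day, the cumulative percentage of onset records
#' occurring at or before that day.
#'
#' @param onsets data.frame from \code{\link{compute_onsets}}.
#' @return data.frame with \code{onset_days} and \code{cum_pct}.
#' @export
onset_cumulative_curve <- function(onsets) {
  d <- sort(unique(onsets$onset_days))
  cum <- stats::ecdf(onsets$onset_days)(d) * 100
  data.frame(onset_days = d, cum_pct = cum)
}
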