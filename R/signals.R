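#' 2x2 contingency table for one drug (or ATC class) versus the target event
#'
#' Cells follow the standard disproportionality layout over the cohort:
#' \code{a} = reports with the index drug as primary suspect and the target
#' event, \code{b} = index drug, other events, \code{c} = other drugs, target
#' event, \code{d} = other drugs, other events. For a class index, "index
#' drug" means the PS drug carries an ATC code whose first three characters
#' equal the class code.
#'
#' @param cohort an \code{"ncdia_cohort"}.
#' @param drug index drug name (matched after normalization), or \code{NULL}.
#' @param atc_class three-character ATC level-2 class code, or \code{NULL}.
#'   Exactly one of \code{drug}/\code{atc_class} must be given.
#' @return named integer vector \code{c(a, b, c, d)}.
#' @export
contingency <- function(cohort, drug = NULL, atc_class = NULL) {
  stopifnot(xor(is.null(drug), is.null(atc_class)))
  if (!is.null(drug)) {
    idx <- cohort$ps_drug_norm == normalize_drug_name(drug)
  } else {
    cls <- toupper(atc_class)
    idx <- vapply(split_multi(cohort$atc_codes), function(cc) {
      !all(is.na(cc)) && any(substr(cc, 1, 3) == cls)
    }, logical(1))
  }
  a <- sum(idx & cohort$is_case)
  b <- sum(idx & !cohort$is_case)
  c_ <- sum(!idx & cohort$is_case)
  d <- sum(!idx & !cohort$is_case)
  c(a = a, b = b, c = c_, d = d)
}

#' Reporting odds ratio with normal-approximation confidence interval
#'
#' ROR = (a d)/(b c); the CI is \code{exp(log ROR +/- z * se)} with
#' \code{se = sqrt(1/a + 1/b + 1/c + 1/d)}. Any zero cell leaves all three
#' values undefined (\code{NA}) — no continuity correction is applied, since
#' the signal rule already requires three or more target reports.
#'
#' @param a,b,c,d nonnegative cell counts (vectorized).
#' @param z normal quantile for the interval; 1.96 gives a 95% CI.
#' @return data.frame with columns \code{ror}, \code{ci_low}, \code{ci_high}.
#' @export
ror_estimate <- function(a, b, c, d, z = 1.96) {
  if (any(c(a, b, c, d) < 0)) stop("contract violation: negative cell count")
  defined <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ifelse(defined, (a * d) / (b * c), NA_real_)
  se <- ifelse(defined, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  data.frame(ror = ror,
             ci_low = exp(log(ror) - z * se),
             ci_high = exp(log(ror) + z * se))
}

signal_frame <- function(id, a, b, c, d, min_reports, z) {
  est <- ror_estimate(a, b, c, d, z = z)
  out <- data.frame(id = id, a = a, b = b, c = c, d = d,
                    n_reports = a, ror = est$ror,
                    ci_low = est$ci_low, ci_high = est$ci_high,
                    stringsAsFactors = FALSE)
  out$is_positive <- out$a >= min_reports & !is.na(out$ci_low) & out$ci_low > 1
  # rank by ROR desc then name; primary ordering by report count desc then name
  out$rank_by_ror <- rank_desc(out$ror, out$id)
  out$rank_by_n <- rank_desc(out$n_reports, out$id)
  out[order(out$rank_by_n), , drop = FALSE]
}

rank_desc <- function(v, nm) {
  if (length(v) == 0L) return(integer(0))
  key <- ifelse(is.na(v), -Inf, v)
  match(seq_along(v), order(-key, as.character(nm)))
}

#' Per-drug disproportionality signals
#'
#' Computes one 2x2 table and ROR per distinct primary-suspect drug with at
#' least one target report. A drug is a positive signal when it has
#' \code{min_reports} or more target reports and the lower 95% CI bound of
#' its ROR exceeds one. Results carry both orderings used in reporting:
#' by target-report count and by ROR (ties broken by drug name).
#'
#' @param cohort an \code{"ncdia_cohort"}.
#' @param min_reports minimum target reports for positivity (default 3).
#' @param z normal quantile for the CI (default 1.96).
#' @return data.frame of class \code{"signal_results"}, rows ordered by
#'   target-report count (descending).
#' @export
detect_signals <- function(cohort, min_reports = 3, z = 1.96) {
  n_case <- sum(cohort$is_case)
  n_tot <- nrow(cohort)
  tab_a <- table(cohort$ps_drug_norm[cohort$is_case])
  drugs <- if (is.null(names(tab_a))) character(0) else names(tab_a)
  tab_n <- table(cohort$ps_drug_norm[cohort$ps_drug_norm %in% drugs])
  a <- as.integer(tab_a)
  b <- as.integer(tab_n[drugs]) - a
  c_ <- n_case - a
  d <- (n_tot - n_case) - b
  out <- signal_frame(drugs, a, b, c_, d, min_reports, z)
  names(out)[names(out) == "id"] <- "drug"
  class(out) <- c("signal_results", class(out))
  out
}

#' ATC level-2 class disproportionality signals
#'
#' Aggregates the cohort by ATC level-2 class (first three characters of the
#' PS drug's codes; a multi-coded drug contributes to each of its classes;
#' unmapped drugs contribute to none). Each class result also reports how
#' many of its member drugs are individually positive.
#'
#' @inheritParams detect_signals
#' @return data.frame of class \code{"signal_results"} with an extra
#'   \code{n_positive_drugs} column.
#' @export
class_signals <- function(cohort, min_reports = 3, z = 1.96) {
  n_case <- sum(cohort$is_case)
  n_tot <- nrow(cohort)
  code_list <- split_multi(cohort$atc_codes)
  cls_list <- lapply(code_list, function(cc) {
    if (all(is.na(cc))) character(0) else unique(substr(cc, 1, 3))
  })
  nrep <- lengths(cls_list)
  long <- data.frame(cls = unlist(cls_list),
                     is_case = rep(cohort$is_case, nrep),
                     drug = rep(cohort$ps_drug_norm, nrep),
                     stringsAsFactors = FALSE)
  if (nrow(long) == 0L) {
    out <- signal_frame(character(0), integer(0), integer(0), integer(0),
                        integer(0), min_reports, z)
    names(out)[names(out) == "id"] <- "atc_class"
    out$n_positive_drugs <- integer(0)
    class(out) <- c("signal_results", class(out))
    return(out)
  }
  tab_a <- table(long$cls[long$is_case])
  classes <- sort(names(tab_a)[tab_a > 0])
  tab_n <- table(factor(long$cls, levels = classes))
  a <- as.integer(tab_a[classes])
  b <- as.integer(tab_n[classes]) - a
  c_ <- n_case - a
  d <- (n_tot - n_case) - b
  out <- signal_frame(classes, a, b, c_, d, min_reports, z)
  names(out)[names(out) == "id"] <- "atc_class"

  drug_sig <- detect_signals(cohort, min_reports = min_reports, z = z)
  pos_drugs <- drug_sig$drug[drug_sig$is_positive]
  drug_cls <- unique(long[long$drug %in% pos_drugs, c("cls", "drug")])
  npos <- table(factor(drug_cls$cls, levels = out$atc_class))
  out$n_positive_drugs <- as.integer(npos[out$atc_class])
  class(out) <- c("signal_results", class(out))
  out
}
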