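#' Read a drug risk-annotation table
#'
#' The annotation table is the product of an external literature/database
#' review (drug labels, compendia, case reports); it is an input here, never
#' computed. Columns: \code{drug}, \code{agran_documented},
#' \code{hematologic_documented} (logical as TRUE/FALSE or 1/0), optional
#' \code{case_report}.
#'
#' @param path TSV path.
#' @return a data.frame with normalized drug names and logical flags.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  need <- c("drug", "agran_documented", "hematologic_documented")
  if (!all(need %in% names(tab)))
    stop("schema error: annotation table needs columns ",
         paste(need, collapse = ", "))
  to_lgl <- function(x) toupper(trimws(x)) %in% c("TRUE", "T", "1", "YES")
  data.frame(drug = normalize_drug_name(tab$drug),
             agran_documented = to_lgl(tab$agran_documented),
             hematologic_documented = to_lgl(tab$hematologic_documented),
             case_report = if ("case_report" %in% names(tab))
               to_lgl(tab$case_report) else FALSE,
             stringsAsFactors = FALSE)
}

#' Three-tier risk classification of a single drug
#'
#' Precedence: a drug with documented agranulocytosis is KNOWN regardless of
#' other annotations; otherwise documented hematologic reactions involving
#' decreased white-cell or neutrophil counts (febrile neutropenia,
#' neutropenia, leukopenia, decreased white blood cell count, aplastic
#' anemia) make it POSSIBLE; a drug with neither is NEW_POTENTIAL.
#'
#' @param agran_documented logical: agranulocytosis documented as an adverse
#'   effect in any reviewed source.
#' @param hematologic_documented logical: other qualifying hematologic
#'   reactions documented.
#' @return one of \code{"KNOWN"}, \code{"POSSIBLE"}, \code{"NEW_POTENTIAL"}.
#' @export
classify_drug <- function(agran_documented, hematologic_documented) {
  stopifnot(is.logical(agran_documented), is.logical(hematologic_documented))
  ifelse(agran_documented, "KNOWN",
         ifelse(hematologic_documented, "POSSIBLE", "NEW_POTENTIAL"))
}

#' Classify every positive-signal drug
#'
#' Joins positive signals with the annotation table by normalized drug name.
#' A positive drug absent from the annotations is routed to an explicit
#' UNANNOTATED bucket — absence of annotation is never treated as "not
#' documented". Tiers partition the positive drugs.
#'
#' @param signals a \code{"signal_results"} data.frame from
#'   \code{\link{detect_signals}}.
#' @param annotations data.frame as from \code{\link{read_annotations}}.
#' @return list with \code{table} (per-drug tier, ROR-ranked within tier) and
#'   \code{counts} (named vector over KNOWN, POSSIBLE, NEW_POTENTIAL,
#'   UNANNOTATED).
#' @export
classify_all <- function(signals, annotations) {
  pos <- signals[signals$is_positive, , drop = FALSE]
  m <- match(pos$drug, annotations$drug)
  tier <- rep("UNANNOTATED", nrow(pos))
  ann <- !is.na(m)
  tier[ann] <- classify_drug(annotations$agran_documented[m[ann]],
                             annotations$hematologic_documented[m[ann]])
  tab <- data.frame(drug = pos$drug, tier = tier, n_reports = pos$n_reports,
                    ror = pos$ror, ci_low = pos$ci_low, ci_high = pos$ci_high,
                    case_report = ifelse(ann, annotations$case_report[m], NA),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$tier, -ifelse(is.na(tab$ror), -Inf, tab$ror), tab$drug), , drop = FALSE]
  rownames(tab) <- NULL
  lev <- c("KNOWN", "POSSIBLE", "NEW_POTENTIAL", "UNANNOTATED")
  counts <- table(factor(tier, levels = lev))
  list(table = tab, counts = stats::setNames(as.integer(counts), lev))
}
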