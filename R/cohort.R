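#' Read a drug-name to ATC-code mapping table
#'
#' @param path two-column TSV with header \code{drug_name}, \code{atc_code};
#'   multiple rows per drug name are allowed (multi-coded products).
#' @return a normalized data.frame of class \code{"atc_map"}.
#' @export
read_atc_map <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  if (!all(c("drug_name", "atc_code") %in% names(tab)))
    stop("schema error: ATC map needs columns drug_name, atc_code")
  atc_map(tab$drug_name, tab$atc_code)
}

#' Build an ATC map from vectors
#'
#' Lookup is total: a name absent from the map resolves to "missing" rather
#' than an error, so unmapped drugs stay in the reference population.
#'
#' @param drug_name,atc_code parallel character vectors.
#' @return a data.frame of class \code{"atc_map"} with normalized names.
#' @export
atc_map <- function(drug_name, atc_code) {
  out <- unique(data.frame(drug_name = normalize_drug_name(drug_name),
                           atc_code = toupper(trimws(atc_code)),
                           stringsAsFactors = FALSE))
  class(out) <- c("atc_map", class(out))
  out
}

# All ATC codes for a vector of normalized names, ";"-packed; "" if unmapped.
lookup_atc <- function(map, names_norm) {
  codes <- tapply(map$atc_code, map$drug_name, pack_multi)
  out <- as.character(ifelse(names_norm %in% names(codes), codes[names_norm], ""))
  out
}

#' Build the analysis cohort
#'
#' Attaches ATC codes to each report's primary suspect drug, removes reports
#' whose PS drug carries any chemotherapy code (ATC starting \code{L01}), and
#' flags target cases: reports whose reaction list contains the target
#' preferred term (exact, case-insensitive match — no MedDRA query
#' expansion). Reports with unmapped drugs stay in the reference population;
#' they simply carry no ATC class.
#'
#' @param cases a \code{"case_reports"} data.frame.
#' @param map an \code{"atc_map"}.
#' @param target_pt target preferred term; default \code{"Agranulocytosis"}.
#' @return the cohort data.frame (class \code{"ncdia_cohort"}) with columns
#'   \code{atc_codes} (";"-packed) and \code{is_case}; attribute
#'   \code{"cohort_log"} holds exclusion counts.
#' @export
build_cohort <- function(cases, map, target_pt = "Agranulocytosis") {
  stopifnot(is.data.frame(cases), inherits(map, "atc_map"))
  if (nrow(cases) == 0L) warning("empty report list: cohort is empty")
  atc <- lookup_atc(map, cases$ps_drug_norm)
  is_chemo <- vapply(split_multi(atc), function(cc) {
    !all(is.na(cc)) && any(startsWith(cc, "L01"))
  }, logical(1))
  cohort <- cases[!is_chemo, , drop = FALSE]
  cohort$atc_codes <- atc[!is_chemo]
  tgt <- toupper(target_pt)
  cohort$is_case <- vapply(split_multi(cohort$reactions), function(rr) {
    !all(is.na(rr)) && tgt %in% toupper(rr)
  }, logical(1))
  rownames(cohort) <- NULL
  attr(cohort, "cohort_log") <- list(
    n_input = nrow(cases), n_excluded_chemo = sum(is_chemo),
    n_cohort = nrow(cohort), n_cases = sum(cohort$is_case),
    n_unmapped_drug = sum(cohort$atc_codes == ""), target_pt = target_pt)
  class(cohort) <- unique(c("ncdia_cohort", class(cohort)))
  cohort
}
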