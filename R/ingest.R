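#' Read a FAERS-style quarterly bundle from disk
#'
#' Loads the "$"-delimited DEMO/DRUG/REAC/OUTC/THER tables from every quarter
#' subdirectory of \code{dir} and any delete lists. All fields are read as
#' character; empty fields are the FAERS convention for missing and are kept
#' as empty strings at this stage. Rows whose field count does not match the
#' header are counted in the parse log, never silently dropped without trace.
#'
#' @param dir bundle directory: one subdirectory per quarter, as written by
#'   \code{\link{write_bundle}} (or unpacked from an FDA quarterly archive
#'   with the same file roles).
#' @return a list of class \code{"raw_record_set"}: tables \code{demo},
#'   \code{drug}, \code{reac}, \code{outc}, \code{ther}, the
#'   \code{delete_ids} character vector and a \code{parse_log}.
#' @export
parse_bundle <- function(dir) {
  if (!dir.exists(dir)) stop("input error: bundle directory not found: ", dir)
  qdirs <- list.dirs(dir, recursive = FALSE)
  if (length(qdirs) == 0L) stop("input error: no quarter subdirectories in ", dir)
  required <- c(demo = "DEMO", drug = "DRUG", reac = "REAC",
                outc = "OUTC", ther = "THER")
  mandatory_cols <- list(
    demo = c("primaryid", "caseid", "fda_dt"),
    drug = c("primaryid", "drug_seq", "role_cod", "drugname"),
    reac = c("primaryid", "pt"),
    outc = c("primaryid", "outc_cod"),
    ther = c("primaryid", "dsg_drug_seq", "start_dt"))
  out <- list()
  malformed <- 0L
  for (nm in names(required)) {
    parts <- list()
    for (qd in qdirs) {
      hits <- list.files(qd, pattern = paste0("^", required[[nm]], ".*\\.(txt|TXT)$"),
                         full.names = TRUE)
      if (length(hits) == 0L)
        stop("input error: missing mandatory file ", required[[nm]], " in ", qd)
      parsed <- read_dollar_table(hits[[1]])
      malformed <- malformed + parsed$malformed
      parts[[qd]] <- parsed$table
    }
    tab <- do.call(rbind, parts)
    rownames(tab) <- NULL
    miss <- setdiff(mandatory_cols[[nm]], names(tab))
    if (length(miss))
      stop("schema error: table ", required[[nm]], " lacks column(s): ",
           paste(miss, collapse = ", "))
    out[[nm]] <- tab
  }
  delete_ids <- character(0)
  for (qd in qdirs) {
    hits <- list.files(qd, pattern = "(?i)delete", full.names = TRUE)
    for (h in hits) {
      ln <- readLines(h, warn = FALSE)
      ln <- trimws(ln[-1])  # header
      delete_ids <- c(delete_ids, ln[nzchar(ln)])
    }
  }
  out$delete_ids <- unique(delete_ids)
  out$parse_log <- list(malformed_rows = malformed)
  class(out) <- "raw_record_set"
  out
}

# Parse one "$"-delimited file with a header row. A trailing "$" yields an
# empty final field (missing). Rows with a wrong field count are skipped and
# counted.
read_dollar_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- strsplit(lines[[1]], "$", fixed = TRUE)[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    tab <- as.data.frame(matrix(character(0), ncol = length(header),
                                dimnames = list(NULL, header)),
                         stringsAsFactors = FALSE)
    return(list(table = tab, malformed = 0L))
  }
  fields <- strsplit(paste0(body, "$\x01"), "$", fixed = TRUE)  # sentinel keeps trailing empties
  nf <- lengths(fields) - 1L
  ok <- nf == length(header)
  rows <- fields[ok]
  mat <- matrix(unlist(lapply(rows, function(r) r[seq_along(header)])),
                ncol = length(header), byrow = TRUE)
  tab <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(tab) <- header
  list(table = tab, malformed = sum(!ok))
}

# Numeric-first ordering key for PRIMARYID tie-breaks: FAERS PRIMARYIDs are
# numeric strings, so "highest value" is numeric; non-numeric values fall
# back to lexicographic rank among themselves.
primaryid_order_key <- function(pid) {
  num <- suppressWarnings(as.numeric(pid))
  bad <- is.na(num)
  if (any(bad)) num[bad] <- rank(pid[bad], ties.method = "min") - .Machine$double.xmax
  num
}

#' Deduplicate case versions
#'
#' FAERS cases are re-submitted as new versions sharing a CASEID. For each
#' CASEID the version with the latest FDA_DT is retained; when FDA_DT is also
#' tied, the highest PRIMARYID wins. Child-table rows belonging to dropped
#' versions are removed.
#'
#' @param rs a \code{"raw_record_set"}.
#' @return the record set with one DEMO row per CASEID; the number of dropped
#'   versions is recorded in \code{parse_log$dropped_versions}.
#' @export
deduplicate <- function(rs) {
  stopifnot(inherits(rs, "raw_record_set"))
  demo <- rs$demo
  if (nrow(demo) == 0L) return(rs)
  fda <- suppressWarnings(as.numeric(demo$fda_dt))
  fda[is.na(fda)] <- -Inf
  o <- order(demo$caseid, fda, primaryid_order_key(demo$primaryid))
  keep_last <- !duplicated(demo$caseid[o], fromLast = TRUE)
  retained <- demo$primaryid[o][keep_last]
  dropped <- nrow(demo) - length(retained)
  rs$demo <- demo[demo$primaryid %in% retained, , drop = FALSE]
  for (tb in c("drug", "reac", "outc", "ther"))
    rs[[tb]] <- rs[[tb]][rs[[tb]]$primaryid %in% retained, , drop = FALSE]
  rs$parse_log$dropped_versions <-
    (rs$parse_log$dropped_versions %||% 0L) + dropped
  rs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply quarterly delete lists
#'
#' Removes every report whose PRIMARYID appears in a delete list. Applied
#' after \code{\link{deduplicate}}: a deleted latest version removes the case
#' entirely (its older versions were already discarded).
#'
#' @param rs a \code{"raw_record_set"}.
#' @return the filtered record set; deletions counted in
#'   \code{parse_log$deleted_reports}.
#' @export
apply_deletes <- function(rs) {
  stopifnot(inherits(rs, "raw_record_set"))
  del <- rs$delete_ids
  n0 <- nrow(rs$demo)
  if (length(del)) {
    rs$demo <- rs$demo[!(rs$demo$primaryid %in% del), , drop = FALSE]
    for (tb in c("drug", "reac", "outc", "ther"))
      rs[[tb]] <- rs[[tb]][!(rs[[tb]]$primaryid %in% del), , drop = FALSE]
  }
  rs$parse_log$deleted_reports <-
    (rs$parse_log$deleted_reports %||% 0L) + (n0 - nrow(rs$demo))
  rs
}

# FAERS age unit codes -> years multiplier
age_unit_factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
                     DY = 1 / 365.25, HR = 1 / 8766)

#' Build normalized case reports
#'
#' Restricts each deduplicated, delete-filtered report to its primary suspect
#' (PS) drug and normalizes demographics: age converted to years from its
#' unit code (DEC, YR, MON, WK, DY, HR; other codes give missing age), ages
#' outside \[0, 150\] set missing and counted as implausible, dates parsed
#' with mid-period imputation for partial values. Reports without a PS drug
#' are excluded and counted; reports with several PS rows keep the lowest
#' drug sequence number.
#'
#' @param rs a deduplicated, delete-filtered \code{"raw_record_set"}.
#' @return a data.frame of class \code{"case_reports"}, one row per retained
#'   report, with an \code{"ingest_log"} attribute of stage counts.
#' @export
build_case_reports <- function(rs) {
  stopifnot(inherits(rs, "raw_record_set"))
  demo <- rs$demo
  drug <- rs$drug
  ps <- drug[drug$role_cod == "PS", , drop = FALSE]
  seqn <- suppressWarnings(as.numeric(ps$drug_seq))
  seqn[is.na(seqn)] <- Inf
  o <- order(ps$primaryid, seqn)
  ps <- ps[o, , drop = FALSE]
  multi_ps <- sum(duplicated(ps$primaryid))
  ps <- ps[!duplicated(ps$primaryid), , drop = FALSE]

  keep <- demo$primaryid %in% ps$primaryid
  no_ps <- sum(!keep)
  demo <- demo[keep, , drop = FALSE]
  m <- match(demo$primaryid, ps$primaryid)

  age_num <- suppressWarnings(as.numeric(demo$age))
  fac <- age_unit_factor[toupper(trimws(demo$age_cod))]
  age_years <- age_num * as.numeric(fac)
  implausible <- !is.na(age_years) & (age_years < 0 | age_years > 150)
  age_years[implausible] <- NA_real_

  reac_pack <- tapply(rs$reac$pt, rs$reac$primaryid, pack_multi)
  outc_pack <- if (nrow(rs$outc)) tapply(rs$outc$outc_cod, rs$outc$primaryid, pack_multi) else character(0)

  # earliest parseable therapy start for the PS drug's sequence number
  ther <- rs$ther
  ther_key <- paste(ther$primaryid, ther$dsg_drug_seq)
  ps_key <- paste(ps$primaryid, ps$drug_seq)
  ther <- ther[ther_key %in% ps_key, , drop = FALSE]
  ther_dates <- parse_faers_date(ther$start_dt)
  okt <- !is.na(ther_dates)
  ther_min <- tapply(as.numeric(ther_dates[okt]), ther$primaryid[okt], min)

  sex <- toupper(trimws(demo$sex))
  sex[!(sex %in% c("F", "M"))] <- "UNK"

  out <- data.frame(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    fda_dt = parse_faers_date(demo$fda_dt),
    event_dt = parse_faers_date(demo$event_dt),
    sex = sex,
    age_years = age_years,
    country = ifelse(nzchar(demo$reporter_country), demo$reporter_country, NA_character_),
    occupation = ifelse(nzchar(demo$occp_cod), demo$occp_cod, NA_character_),
    outcomes = as.character(ifelse(demo$primaryid %in% names(outc_pack),
                                   outc_pack[demo$primaryid], "")),
    ps_drug = ps$drugname[m],
    ps_drug_norm = normalize_drug_name(ps$drugname[m]),
    ther_start = as.Date(as.numeric(ther_min[demo$primaryid]), origin = "1970-01-01"),
    reactions = as.character(ifelse(demo$primaryid %in% names(reac_pack),
                                    reac_pack[demo$primaryid], "")),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ingest_log") <- c(rs$parse_log,
                               list(no_ps_drug = no_ps,
                                    multiple_ps_rows = multi_ps,
                                    implausible_age = sum(implausible),
                                    n_case_reports = nrow(out)))
  class(out) <- c("case_reports", class(out))
  out
}

#' One-call ingest: parse, deduplicate, delete-filter, normalize
#'
#' @param dir bundle directory.
#' @return a \code{"case_reports"} data.frame (see
#'   \code{\link{build_case_reports}}).
#' @export
ingest_bundle <- function(dir) {
  build_case_reports(apply_deletes(deduplicate(parse_bundle(dir))))
}
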