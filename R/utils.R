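#' Parse FAERS-style date strings
#'
#' FAERS ASCII tables carry dates as digit strings: \code{YYYYMMDD} (full),
#' \code{YYYYMM} (month known) or \code{YYYY} (year only). Partial dates are
#' imputed to an unbiased mid-period anchor: the 15th for \code{YYYYMM}, 1 July
#' for \code{YYYY}. Anything else (empty, non-digit, impossible calendar date)
#' parses to \code{NA}.
#'
#' @param x character vector of date strings.
#' @return a \code{Date} vector of the same length.
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[!grepl("^[0-9]+$", x)] <- NA_character_
  full <- ifelse(is.na(x), NA_character_,
          ifelse(nchar(x) == 8L, x,
          ifelse(nchar(x) == 6L, paste0(x, "15"),
          ifelse(nchar(x) == 4L, paste0(x, "0701"), NA_character_))))
  as.Date(full, format = "%Y%m%d")
}

#' Format a Date as a FAERS YYYYMMDD integer string
#' @param d Date vector.
#' @return character vector; \code{NA} becomes the empty string.
#' @keywords internal
format_faers_date <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(out)] <- ""
  out
}

#' Normalize a drug name for matching
#'
#' Trim, uppercase, collapse internal whitespace. Used for every join between
#' report drug names, the ATC map and the annotation table.
#'
#' @param x character vector of drug names.
#' @return normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  toupper(gsub("\\s+", " ", trimws(as.character(x))))
}

# Split a ";"-packed multi-value field into a list of character vectors.
split_multi <- function(x) {
  x <- as.character(x)
  if (length(x) == 0L) return(list())
  strsplit(ifelse(is.na(x) | x == "", NA_character_, x), ";", fixed = TRUE)
}

# Pack a character vector into a ";"-joined field (sorted, unique).
pack_multi <- function(x) {
  x <- sort(unique(x[!is.na(x) & x != ""]))
  if (length(x) == 0L) "" else paste(x, collapse = ";")
}

# Quarter label helpers: "2023Q1" <-> dates.
quarter_bounds <- function(label) {
  stopifnot(grepl("^[0-9]{4}Q[1-4]$", label))
  yr <- as.integer(substr(label, 1, 4))
  q <- as.integer(substr(label, 6, 6))
  start <- as.Date(sprintf("%d-%02d-01", yr, (q - 1L) * 3L + 1L))
  end <- seq(start, by = "3 months", length.out = 2L)[2L] - 1L
  list(start = start, end = end, year = yr, quarter = q)
}

date_to_quarter <- function(d) {
  sprintf("%sQ%d", format(d, "%Y"), (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
}
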