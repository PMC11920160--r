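#' Drug profile for the synthetic report generator
#'
#' Each profile describes one drug in the simulated market: how often it is
#' the primary suspect of a report, the planted odds multiplier linking it to
#' the target event (1 = background risk, the null), the log-normal
#' distribution of time to onset, and the probability that a target-event
#' report ends in death.
#'
#' @param name drug name (verbatim, as it would appear in a DRUG table).
#' @param atc_code 7-character ATC code, e.g. \code{"N05AH02"}.
#' @param base_report_prob relative weight of this drug among reports.
#' @param event_odds_multiplier planted true odds ratio (>= 0) of the target
#'   event given this drug versus background.
#' @param onset_log_mean,onset_log_sd meanlog/sdlog of the log-normal
#'   onset-days distribution.
#' @param death_prob_given_event probability in \[0,1\] that a target-event
#'   report for this drug carries outcome code DE.
#' @return a one-row data.frame.
#' @export
drug_profile <- function(name, atc_code, base_report_prob = 1,
                         event_odds_multiplier = 1,
                         onset_log_mean = log(20), onset_log_sd = 1,
                         death_prob_given_event = 0.1) {
  if (!nzchar(atc_code)) stop("invalid drug profile: atc_code must be nonempty")
  if (event_odds_multiplier < 0) stop("invalid drug profile: event_odds_multiplier must be >= 0")
  data.frame(name = name, atc_code = atc_code,
             base_report_prob = base_report_prob,
             event_odds_multiplier = event_odds_multiplier,
             onset_log_mean = onset_log_mean, onset_log_sd = onset_log_sd,
             death_prob_given_event = death_prob_given_event,
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic FAERS bundle generator
#'
#' Defines the simulated reporting system: number of reports, the drug market
#' (a stack of \code{\link{drug_profile}} rows), the quarters covered, the
#' rates of duplicate case versions and delete-list entries, demographic
#' distributions and missingness. A fixed seed makes output byte-identical.
#'
#' @param n_reports number of distinct cases to emit (>= 1).
#' @param drugs data.frame of drug profiles (rbind of \code{drug_profile}).
#' @param quarters character vector of quarter labels, e.g. \code{"2023Q1"}.
#' @param duplicate_rate fraction in \[0,1) of cases emitted as two versions.
#' @param delete_rate fraction in \[0,1) of retained reports listed in delete
#'   files (only honoured for quarters from 2019Q1 on, when FAERS began
#'   shipping delete lists).
#' @param dup_same_date_frac among duplicated cases, fraction whose versions
#'   share FDA_DT and differ only in PRIMARYID (exercises the tie-break).
#' @param partial_date_frac fraction of event dates emitted as partial
#'   (YYYYMM or YYYY) to exercise date parsing.
#' @param background_event_prob baseline probability of the target event for
#'   a multiplier-1 drug.
#' @param background_death_prob death probability for non-event reports.
#' @param target_pt the target preferred term planted in REAC.
#' @param sex_probs probabilities for F, M, UNK.
#' @param age_missing_frac fraction of reports with missing age.
#' @param onset_missing_frac fraction of reports lacking a usable
#'   therapy-start/event-date pair (mirrors the heavy missingness of
#'   spontaneous reports).
#' @param seed integer random seed.
#' @return a list of class \code{"faers_generator_config"}.
#' @export
generator_config <- function(n_reports, drugs,
                             quarters = c("2023Q1", "2023Q2"),
                             duplicate_rate = 0.1, delete_rate = 0.01,
                             dup_same_date_frac = 0.25,
                             partial_date_frac = 0.05,
                             background_event_prob = 0.02,
                             background_death_prob = 0.05,
                             target_pt = "Agranulocytosis",
                             sex_probs = c(F = 0.46, M = 0.46, UNK = 0.08),
                             age_missing_frac = 0.15,
                             onset_missing_frac = 0.5,
                             seed = 1L) {
  cfg <- list(n_reports = n_reports, drugs = drugs, quarters = quarters,
              duplicate_rate = duplicate_rate, delete_rate = delete_rate,
              dup_same_date_frac = dup_same_date_frac,
              partial_date_frac = partial_date_frac,
              background_event_prob = background_event_prob,
              background_death_prob = background_death_prob,
              target_pt = target_pt, sex_probs = sex_probs,
              age_missing_frac = age_missing_frac,
              onset_missing_frac = onset_missing_frac, seed = as.integer(seed))
  class(cfg) <- "faers_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n_reports) || cfg$n_reports < 1)
    stop("invalid generator config: n_reports must be >= 1")
  if (!is.data.frame(cfg$drugs) || nrow(cfg$drugs) < 1)
    stop("invalid generator config: drugs must contain at least one profile")
  if (any(!nzchar(cfg$drugs$atc_code)))
    stop("invalid generator config: atc_code must be nonempty")
  if (any(cfg$drugs$event_odds_multiplier < 0))
    stop("invalid generator config: event_odds_multiplier must be >= 0")
  for (f in c("duplicate_rate", "delete_rate", "dup_same_date_frac",
              "partial_date_frac", "age_missing_frac", "onset_missing_frac")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v >= 1)
      stop(sprintf("invalid generator config: %s must be in [0,1)", f))
  }
  if (!all(grepl("^[0-9]{4}Q[1-4]$", cfg$quarters)))
    stop("invalid generator config: quarters must look like '2023Q1'")
  invisible(cfg)
}

filler_pts <- c("Nausea", "Headache", "Rash", "Dizziness", "Pyrexia",
                "Fatigue", "Diarrhoea", "Vomiting", "Pruritus", "Insomnia")
countries <- c("US", "FR", "DE", "JP", "GB", "CA")
occupations <- c("MD", "PH", "CN", "OT")

#' Generate a synthetic FAERS bundle
#'
#' Draws \code{n_reports} cases. The target event is assigned per report from
#' the planted odds model: for a drug with multiplier m and background event
#' probability p0, the event probability is \code{m*odds0/(1+m*odds0)} with
#' \code{odds0 = p0/(1-p0)}, so m is the true odds ratio of the event for
#' that drug versus a multiplier-1 drug. A configurable fraction of cases is
#' emitted twice (an earlier FDA_DT version, or a same-FDA_DT version with a
#' different PRIMARYID) and a fraction of retained reports is listed in
#' delete files for quarters from 2019Q1 on.
#'
#' @param config a \code{\link{generator_config}}.
#' @return a list of class \code{"faers_bundle"} with the five record tables
#'   (\code{demo}, \code{drug}, \code{reac}, \code{outc}, \code{ther}),
#'   \code{deletes} (PRIMARYID + quarter), \code{ground_truth} (per-drug
#'   planted multiplier and emitted case counts) and \code{counts}
#'   (bookkeeping: cases, versions, deletions).
#' @export
generate_bundle <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_reports)
  drugs <- config$drugs

  di <- sample.int(nrow(drugs), n, replace = TRUE,
                   prob = drugs$base_report_prob)
  odds0 <- config$background_event_prob / (1 - config$background_event_prob)
  p_event <- drugs$event_odds_multiplier[di] * odds0 /
    (1 + drugs$event_odds_multiplier[di] * odds0)
  is_event <- stats::runif(n) < p_event

  sex <- sample(names(config$sex_probs), n, replace = TRUE,
                prob = config$sex_probs)
  sex[sex == "UNK"] <- ""
  age <- pmin(pmax(round(stats::rnorm(n, 57, 19)), 0), 100)
  age_cod <- rep("YR", n)
  age_missing <- stats::runif(n) < config$age_missing_frac
  age_chr <- as.character(age)
  age_chr[age_missing] <- ""
  age_cod[age_missing] <- ""
  country <- sample(countries, n, replace = TRUE)
  occp <- sample(occupations, n, replace = TRUE)

  q <- sample(config$quarters, n, replace = TRUE)
  qb <- lapply(config$quarters, quarter_bounds)
  names(qb) <- config$quarters
  fda_dt <- as.Date(vapply(seq_len(n), function(i) {
    b <- qb[[q[i]]]
    as.numeric(b$start) + floor(stats::runif(1) * (as.numeric(b$end) - as.numeric(b$start) + 1))
  }, numeric(1)), origin = "1970-01-01")

  event_dt <- fda_dt - sample(0:60, n, replace = TRUE)
  onset_days <- round(stats::rlnorm(n, drugs$onset_log_mean[di],
                                    drugs$onset_log_sd[di]))
  ther_start <- event_dt - onset_days
  no_onset <- stats::runif(n) < config$onset_missing_frac
  ther_start[no_onset] <- NA

  # partial event dates: degrade a fraction to YYYYMM / YYYY precision
  event_chr <- format_faers_date(event_dt)
  part <- which(stats::runif(n) < config$partial_date_frac)
  if (length(part)) {
    half <- part[seq_len(length(part) %/% 2)]
    event_chr[half] <- substr(event_chr[half], 1, 6)
    event_chr[setdiff(part, half)] <- substr(event_chr[setdiff(part, half)], 1, 4)
  }

  death <- ifelse(is_event,
                  stats::runif(n) < drugs$death_prob_given_event[di],
                  stats::runif(n) < config$background_death_prob)
  hosp <- stats::runif(n) < 0.3
  lt <- stats::runif(n) < 0.1

  caseid <- as.character(seq_len(n) + 10000000L)
  primaryid <- paste0(caseid, "2")   # retained version

  demo <- data.frame(primaryid = primaryid, caseid = caseid,
                     caseversion = "2", fda_dt = format_faers_date(fda_dt),
                     event_dt = event_chr, sex = sex, age = age_chr,
                     age_cod = age_cod, occp_cod = occp,
                     reporter_country = country, stringsAsFactors = FALSE)

  drug_tab <- data.frame(primaryid = primaryid, caseid = caseid,
                         drug_seq = "1", role_cod = "PS",
                         drugname = drugs$name[di], stringsAsFactors = FALSE)
  # a second, concomitant drug on ~40% of reports
  conc <- which(stats::runif(n) < 0.4)
  if (length(conc)) {
    ci2 <- sample.int(nrow(drugs), length(conc), replace = TRUE)
    drug_tab <- rbind(drug_tab, data.frame(
      primaryid = primaryid[conc], caseid = caseid[conc], drug_seq = "2",
      role_cod = "C", drugname = drugs$name[ci2], stringsAsFactors = FALSE))
  }

  pt1 <- ifelse(is_event, config$target_pt,
                sample(filler_pts, n, replace = TRUE))
  reac <- data.frame(primaryid = primaryid, caseid = caseid, pt = pt1,
                     stringsAsFactors = FALSE)
  extra <- which(stats::runif(n) < 0.3)
  if (length(extra)) {
    reac <- rbind(reac, data.frame(primaryid = primaryid[extra],
                                   caseid = caseid[extra],
                                   pt = sample(filler_pts, length(extra), replace = TRUE),
                                   stringsAsFactors = FALSE))
  }

  outc <- rbind(
    data.frame(primaryid = character(0), caseid = character(0),
               outc_cod = character(0), stringsAsFactors = FALSE),
    if (any(death)) data.frame(primaryid = primaryid[death], caseid = caseid[death],
                               outc_cod = "DE", stringsAsFactors = FALSE),
    if (any(hosp)) data.frame(primaryid = primaryid[hosp], caseid = caseid[hosp],
                              outc_cod = "HO", stringsAsFactors = FALSE),
    if (any(lt)) data.frame(primaryid = primaryid[lt], caseid = caseid[lt],
                            outc_cod = "LT", stringsAsFactors = FALSE))

  has_ther <- which(!is.na(ther_start))
  ther <- data.frame(primaryid = primaryid[has_ther], caseid = caseid[has_ther],
                     dsg_drug_seq = "1",
                     start_dt = format_faers_date(ther_start[has_ther]),
                     stringsAsFactors = FALSE)

  # duplicate versions: an extra version-1 row per selected case
  n_dup <- floor(config$duplicate_rate * n)
  dup_idx <- if (n_dup > 0) sample.int(n, n_dup) else integer(0)
  if (n_dup > 0) {
    same_dt <- stats::runif(n_dup) < config$dup_same_date_frac
    dup_pid <- paste0(caseid[dup_idx], "1")  # numerically below retained "...2"
    dup_fda <- ifelse(same_dt, format_faers_date(fda_dt[dup_idx]),
                      format_faers_date(fda_dt[dup_idx] - sample(10:90, n_dup, replace = TRUE)))
    demo_dup <- demo[dup_idx, ]
    demo_dup$primaryid <- dup_pid
    demo_dup$caseversion <- "1"
    demo_dup$fda_dt <- dup_fda
    demo <- rbind(demo, demo_dup)
    for (tb in c("drug_tab", "reac", "outc", "ther")) {
      t0 <- get(tb)
      sub <- t0[t0$primaryid %in% primaryid[dup_idx], ]
      if (nrow(sub)) {
        sub$primaryid <- paste0(sub$caseid, "1")
        assign(tb, rbind(t0, sub))
      }
    }
  }

  # delete lists: only quarters >= 2019Q1 ship them
  deletable <- which(q >= "2019Q1")
  n_del <- min(floor(config$delete_rate * n), length(deletable))
  del_idx <- if (n_del > 0) sample(deletable, n_del) else integer(0)
  deletes <- data.frame(primaryid = primaryid[del_idx], quarter = q[del_idx],
                        stringsAsFactors = FALSE)

  gt_counts <- table(factor(drugs$name[di], levels = drugs$name))
  gt_event <- table(factor(drugs$name[di][is_event], levels = drugs$name))
  ground_truth <- data.frame(drug = drugs$name,
                             atc_code = drugs$atc_code,
                             planted_multiplier = drugs$event_odds_multiplier,
                             n_reports = as.integer(gt_counts),
                             n_event_reports = as.integer(gt_event),
                             stringsAsFactors = FALSE)

  structure(list(demo = demo, drug = drug_tab, reac = reac, outc = outc,
                 ther = ther, deletes = deletes, ground_truth = ground_truth,
                 quarter = q,
                 counts = list(n_cases = n, n_versions = nrow(demo),
                               n_duplicated_cases = n_dup, n_deleted = n_del,
                               n_event_cases = sum(is_event)),
                 config = config),
            class = "faers_bundle")
}

#' Write a synthetic bundle as FAERS-style quarterly ASCII files
#'
#' Creates one subdirectory per quarter under \code{dir}, each holding
#' "$"-delimited \code{DEMO.txt}, \code{DRUG.txt}, \code{REAC.txt},
#' \code{OUTC.txt}, \code{THER.txt} and, for quarters from 2019Q1 on, a
#' \code{DELETE.txt} list of PRIMARYIDs. A \code{ground_truth.tsv} with the
#' planted multipliers is written at the top level.
#'
#' @param bundle a \code{"faers_bundle"} from \code{\link{generate_bundle}}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "faers_bundle"))
  # duplicates share the case's quarter assignment
  case_quarter <- stats::setNames(bundle$quarter,
                                  bundle$demo$caseid[seq_along(bundle$quarter)])
  for (qq in bundle$config$quarters) {
    qdir <- file.path(dir, qq)
    dir.create(qdir, recursive = TRUE, showWarnings = FALSE)
    for (tb in c("demo", "drug", "reac", "outc", "ther")) {
      t0 <- bundle[[tb]]
      sel <- t0[case_quarter[t0$caseid] == qq, , drop = FALSE]
      writeLines(c(paste(names(t0), collapse = "$"),
                   do.call(paste, c(unname(as.list(sel)), sep = "$"))),
                 file.path(qdir, paste0(toupper(tb), ".txt")))
    }
    if (qq >= "2019Q1") {
      del <- bundle$deletes$primaryid[bundle$deletes$quarter == qq]
      writeLines(c("primaryid", del), file.path(qdir, "DELETE.txt"))
    }
  }
  write_tsv(bundle$ground_truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

#' Convert an in-memory bundle to a raw record set
#'
#' Fast path used by simulations: yields the same object
#' \code{\link{parse_bundle}} would produce from \code{\link{write_bundle}}
#' output, without touching the filesystem.
#'
#' @param bundle a \code{"faers_bundle"}.
#' @return a \code{"raw_record_set"}.
#' @export
as_raw_record_set <- function(bundle) {
  stopifnot(inherits(bundle, "faers_bundle"))
  structure(list(demo = bundle$demo, drug = bundle$drug, reac = bundle$reac,
                 outc = bundle$outc, ther = bundle$ther,
                 delete_ids = bundle$deletes$primaryid,
                 parse_log = list(malformed_rows = 0L)),
            class = "raw_record_set")
}
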