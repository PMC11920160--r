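#' Run the full analysis pipeline
#'
#' Orchestrates ingest (or synthetic generation), cohort construction, signal
#' detection, risk classification, onset analysis and mortality analysis,
#' and collects a stage-by-stage run report of input/retained counts.
#'
#' @param bundle_dir directory of FAERS-style quarterly files, or \code{NULL}
#'   to generate synthetically.
#' @param generator_cfg a \code{\link{generator_config}} used when
#'   \code{bundle_dir} is \code{NULL}.
#' @param atc_map an \code{"atc_map"}.
#' @param annotations optional annotation data.frame (see
#'   \code{\link{read_annotations}}); classification is skipped when absent.
#' @param target_pt target preferred term.
#' @param min_signal_reports,min_onset_reports,min_deaths reporting
#'   thresholds (defaults 3, 20, 20).
#' @param bins period bins for mortality trends.
#' @param out_dir optional directory; when given, all result tables are
#'   written there as TSV.
#' @return list with \code{cohort}, \code{signals}, \code{class_signals},
#'   \code{classification}, \code{onsets}, \code{onset_summary},
#'   \code{drug_onsets}, \code{period_mortality}, \code{mortality_tests},
#'   \code{drug_mortality}, and \code{report} (stage counts).
#' @export
run_pipeline <- function(bundle_dir = NULL, generator_cfg = NULL,
                         atc_map, annotations = NULL,
                         target_pt = "Agranulocytosis",
                         min_signal_reports = 3, min_onset_reports = 20,
                         min_deaths = 20, bins = default_period_bins(),
                         out_dir = NULL) {
  stopifnot(min_signal_reports >= 1, min_onset_reports >= 1, min_deaths >= 1)
  if (is.null(bundle_dir) && is.null(generator_cfg))
    stop("pipeline error [stage=input]: need bundle_dir or generator_cfg")
  rs <- if (!is.null(bundle_dir)) parse_bundle(bundle_dir)
        else as_raw_record_set(generate_bundle(generator_cfg))
  n_raw <- nrow(rs$demo)
  rs <- apply_deletes(deduplicate(rs))
  cases <- build_case_reports(rs)
  cohort <- build_cohort(cases, atc_map, target_pt = target_pt)

  sig <- detect_signals(cohort, min_reports = min_signal_reports)
  csig <- class_signals(cohort, min_reports = min_signal_reports)
  cls <- if (!is.null(annotations)) classify_all(sig, annotations) else NULL

  onsets <- compute_onsets(cohort)
  osum <- if (nrow(onsets) > 0) onset_strata_summary(onsets) else NULL
  donset <- drug_onset_summaries(onsets, min_reports = min_onset_reports)

  pm <- period_rates(cohort, bins = bins)
  in_window <- pm[pm$label != "out-of-window" & pm$total > 0, , drop = FALSE]
  mtests <- list(
    omnibus = if (nrow(in_window) >= 2) omnibus_period_test(in_window) else NULL,
    pairwise = if (nrow(in_window) >= 2) pairwise_period_tests(in_window) else NULL,
    death_vs_nondeath = if (sum(cohort$is_case) > 0)
      death_vs_nondeath_comparisons(cohort, onsets) else NULL)
  dmort <- drug_mortality(cohort, min_deaths = min_deaths)

  report <- list(n_raw_reports = n_raw,
                 ingest = attr(cases, "ingest_log"),
                 cohort = attr(cohort, "cohort_log"),
                 n_signals = nrow(sig),
                 n_positive_signals = sum(sig$is_positive),
                 classification_counts = if (!is.null(cls)) cls$counts else NULL,
                 onset = attr(onsets, "onset_log"),
                 n_deaths = sum(pm$deaths))

  out <- list(cohort = cohort, signals = sig, class_signals = csig,
              classification = cls, onsets = onsets, onset_summary = osum,
              drug_onsets = donset, period_mortality = pm,
              mortality_tests = mtests, drug_mortality = dmort,
              report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(sig, file.path(out_dir, "signals.tsv"))
    write_tsv(csig, file.path(out_dir, "class_signals.tsv"))
    if (!is.null(cls)) write_tsv(cls$table, file.path(out_dir, "risk_tiers.tsv"))
    write_tsv(onsets, file.path(out_dir, "onsets.tsv"))
    write_tsv(donset$by_drug, file.path(out_dir, "onset_by_drug.tsv"))
    write_tsv(donset$by_class, file.path(out_dir, "onset_by_class.tsv"))
    write_tsv(pm, file.path(out_dir, "period_mortality.tsv"))
    write_tsv(dmort, file.path(out_dir, "drug_mortality.tsv"))
  }
  out
}
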