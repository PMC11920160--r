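# Shared fixtures: a small simulated drug market, its ATC map, and the
# published summary counts used in the mortality fixture tests.

fixture_drugs <- function() {
  rbind(
    drug_profile("Clozapine", "N05AH02", base_report_prob = 5,
                 event_odds_multiplier = 10, onset_log_mean = log(15),
                 death_prob_given_event = 0.10),
    drug_profile("Ibuprofen", "M01AE01", base_report_prob = 10,
                 event_odds_multiplier = 2, onset_log_mean = log(10),
                 death_prob_given_event = 0.05),
    drug_profile("Metformin", "A10BA02", base_report_prob = 10,
                 event_odds_multiplier = 1, onset_log_mean = log(30),
                 death_prob_given_event = 0.05),
    drug_profile("Methotrexate", "L01BA01", base_report_prob = 3,
                 event_odds_multiplier = 4, onset_log_mean = log(20),
                 death_prob_given_event = 0.20),
    drug_profile("Amoxicillin", "J01CA04", base_report_prob = 8,
                 event_odds_multiplier = 1, onset_log_mean = log(7),
                 death_prob_given_event = 0.02))
}

fixture_atc_map <- function() {
  d <- fixture_drugs()
  atc_map(d$name, d$atc_code)
}

fixture_bundle <- function(n = 2000, seed = 7, ...) {
  cfg <- generator_config(n, fixture_drugs(),
                          quarters = c("2018Q4", "2019Q1", "2023Q2"),
                          seed = seed, ...)
  generate_bundle(cfg)
}

fixture_cohort <- function(n = 2000, seed = 7, ...) {
  b <- fixture_bundle(n, seed, ...)
  cases <- build_case_reports(apply_deletes(deduplicate(as_raw_record_set(b))))
  build_cohort(cases, fixture_atc_map())
}

# Published four-period death / non-death counts (mortality trend fixture).
period_counts_fixture <- function() {
  mortality_summary(deaths = c(262L, 245L, 361L, 188L),
                    non_deaths = c(1937L, 2111L, 3414L, 2395L),
                    label = c("2004-2010", "2011-2015", "2016-2020", "2021-2024"))
}

# Gender x outcome counts from the same summary table.
gender_counts_fixture <- function() {
  c(f_death = 514L, m_death = 467L, unk_death = 75L,
    f_alive = 4497L, m_alive = 4625L, unk_alive = 735L)
}

# Hand-built tiny raw record set for targeted ingest tests.
tiny_record_set <- function(demo, drug = NULL, reac = NULL, outc = NULL,
                            ther = NULL, delete_ids = character(0)) {
  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                  stringsAsFactors = FALSE)
  }
  structure(list(
    demo = demo,
    drug = if (is.null(drug)) empty(c("primaryid", "caseid", "drug_seq", "role_cod", "drugname")) else drug,
    reac = if (is.null(reac)) empty(c("primaryid", "caseid", "pt")) else reac,
    outc = if (is.null(outc)) empty(c("primaryid", "caseid", "outc_cod")) else outc,
    ther = if (is.null(ther)) empty(c("primaryid", "caseid", "dsg_drug_seq", "start_dt")) else ther,
    delete_ids = delete_ids,
    parse_log = list(malformed_rows = 0L)), class = "raw_record_set")
}

demo_row <- function(primaryid, caseid, fda_dt, event_dt = "", sex = "F",
                     age = "50", age_cod = "YR", occp = "MD", country = "US") {
  data.frame(primaryid = primaryid, caseid = caseid, caseversion = "1",
             fda_dt = fda_dt, event_dt = event_dt, sex = sex, age = age,
             age_cod = age_cod, occp_cod = occp, reporter_country = country,
             stringsAsFactors = FALSE)
}

ps_row <- function(primaryid, caseid, drugname, drug_seq = "1", role = "PS") {
  data.frame(primaryid = primaryid, caseid = caseid, drug_seq = drug_seq,
             role_cod = role, drugname = drugname, stringsAsFactors = FALSE)
}
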