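#!/usr/bin/env Rscript
# Simulate a FAERS-style report stream with known ground truth.
#
# Five quarters (straddling the 2019 introduction of delete lists), a small
# drug market with two planted agranulocytosis associations (Clozapine at
# true odds ratio 10, Ibuprofen at 2), one chemotherapy drug (Methotrexate,
# L01) that must later be excluded, duplicate case versions at 15% and a 2%
# delete rate. Writes the "$"-delimited quarterly bundle under
# results/bundle/ and prints the generator's bookkeeping.

suppressMessages(library(agranuvigil))

drugs <- rbind(
  drug_profile("Clozapine",    "N05AH02", base_report_prob = 5,
               event_odds_multiplier = 10, onset_log_mean = log(15),
               onset_log_sd = 1.0, death_prob_given_event = 0.08),
  drug_profile("Olanzapine",   "N05AH03", base_report_prob = 6,
               event_odds_multiplier = 3,  onset_log_mean = log(25),
               onset_log_sd = 1.1, death_prob_given_event = 0.10),
  drug_profile("Ibuprofen",    "M01AE01", base_report_prob = 12,
               event_odds_multiplier = 2,  onset_log_mean = log(10),
               onset_log_sd = 1.2, death_prob_given_event = 0.06),
  drug_profile("Metformin",    "A10BA02", base_report_prob = 12,
               event_odds_multiplier = 1,  onset_log_mean = log(30),
               onset_log_sd = 1.0, death_prob_given_event = 0.05),
  drug_profile("Methotrexate", "L01BA01", base_report_prob = 4,
               event_odds_multiplier = 4,  onset_log_mean = log(20),
               onset_log_sd = 1.0, death_prob_given_event = 0.20),
  drug_profile("Amoxicillin",  "J01CA04", base_report_prob = 10,
               event_odds_multiplier = 1,  onset_log_mean = log(7),
               onset_log_sd = 0.8, death_prob_given_event = 0.03),
  drug_profile("Furosemide",   "C03CA01", base_report_prob = 8,
               event_odds_multiplier = 2,  onset_log_mean = log(6),
               onset_log_sd = 1.0, death_prob_given_event = 0.25))

cfg <- generator_config(
  n_reports = 30000, drugs = drugs,
  quarters = c("2017Q2", "2019Q1", "2020Q3", "2022Q1", "2023Q4"),
  duplicate_rate = 0.15, delete_rate = 0.02, dup_same_date_frac = 0.25,
  partial_date_frac = 0.05, onset_missing_frac = 0.5, seed = 20240615L)

bundle <- generate_bundle(cfg)
dir.create("results", showWarnings = FALSE)
write_bundle(bundle, "results/bundle")

cat("Simulated", bundle$counts$n_cases, "cases as",
    bundle$counts$n_versions, "report versions;",
    bundle$counts$n_duplicated_cases, "cases have a duplicate version and",
    bundle$counts$n_deleted, "retained reports are on delete lists.\n")
cat("Target-event cases planted:", bundle$counts$n_event_cases, "\n")
print(bundle$ground_truth)
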