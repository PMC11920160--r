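# agranuvigil

Pharmacovigilance analysis of **non-chemotherapy drug-induced
agranulocytosis (NCDIA)** in FAERS-style spontaneous adverse-event report
data. Agranulocytosis — an absolute neutrophil count below 0.5 × 10⁹/L —
is a rare, idiosyncratic and potentially fatal reaction to many drugs
outside the chemotherapy classes, and large spontaneous-reporting databases
are the main way new drug associations surface. This package is for
pharmacoepidemiologists and clinical pharmacists who want a tested,
reproducible version of the standard analysis chain, exercisable entirely on
synthetic data or on published summary tables.

## What it computes

The core statistic is the **reporting odds ratio (ROR)** over the 2×2 table
for drug *D* (as primary suspect) versus the target preferred term:

|              | target event | other events |
|--------------|--------------|--------------|
| drug *D*     | a            | b            |
| other drugs  | c            | d            |

ROR = (a·d)/(b·c), with 95% CI exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)).
A drug is a **positive signal** when a ≥ 3 and the lower CI bound exceeds 1.
The reference group is every deduplicated report except those whose primary
suspect drug carries an ATC code starting `L01` (antineoplastic agents).

Around that core the package provides:

- **`generate_bundle()`** — synthetic FAERS quarterly bundles
  ("$"-delimited DEMO/DRUG/REAC/OUTC/THER tables plus post-2019 delete
  lists) with planted drug–event odds multipliers, duplicate case versions,
  partial dates and configurable missingness, so every downstream stage has
  known ground truth.
- **`parse_bundle()` / `deduplicate()` / `apply_deletes()` /
  `build_case_reports()`** — ingestion with the standard FAERS cleaning
  rules: per CASEID keep the latest FDA_DT (ties: highest PRIMARYID), honour
  quarterly delete lists, keep only the primary suspect drug, normalize ages
  to years.
- **`build_cohort()` / `detect_signals()` / `class_signals()`** — cohort
  construction, per-drug and ATC level-2 class RORs and the signal rule.
- **`classify_all()`** — three-tier risk classification of positive drugs
  (KNOWN / POSSIBLE / NEW_POTENTIAL) from a curated annotation table.
- **`compute_onsets()` + test battery** — time-to-onset medians/IQRs by
  gender and age group, Mann-Whitney, Kruskal-Wallis, Dunn-Bonferroni, and
  drug-specific onset for strata with ≥ 20 records.
- **`mortality_summary()` and friends** — death-rate trends with exact
  Clopper–Pearson CIs, omnibus and Yates-corrected pairwise Bonferroni
  chi-square tests, death-vs-non-death comparisons, drug-specific mortality
  (≥ 20 deaths). All mortality functions accept pre-aggregated counts, so
  published tables can be re-analyzed directly.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_ingest.R
Rscript analysis/03_signals.R
```

simulates 30,000 reports (Clozapine planted at true odds ratio 10 among a
seven-drug market including one chemotherapy drug), ingests them, and prints:

```
Parsed 34500 report versions; 600 delete-list entries; 0 malformed rows.
After version dedup: 30000 reports (4500 versions dropped).
After delete lists: 29400 reports (600 removed).
...
Cohort: 27417 reports after excluding 1983 chemotherapy (L01) reports; 1269 target cases.

Per-drug signals (by target-report count):
         drug   a n_reports   ror ci_low ci_high is_positive
2   CLOZAPINE 434       434 5.846  5.163   6.619        TRUE
4   IBUPROFEN 277       277 0.936  0.816   1.072       FALSE
6  OLANZAPINE 186       186 1.309  1.115   1.536        TRUE
...
```

Clozapine and Olanzapine (planted multipliers 10 and 3) are flagged;
multiplier-1 drugs are not. The drug-level ROR (5.85) sits below the planted
10 because the reference group itself contains other elevated drugs — the
usual masking behaviour of disproportionality statistics, demonstrated here
with known truth. `analysis/04_onset.R` and `analysis/05_mortality.R`
continue with the onset and mortality analyses, the latter also re-analyzing
the published period × outcome and gender × outcome count tables shipped
under `inst/extdata/`.

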