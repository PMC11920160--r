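---
title: "Methods: disproportionality analysis of drug-induced agranulocytosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality analysis of drug-induced agranulocytosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agranuvigil)
```

## The problem

Agranulocytosis (absolute neutrophil count < 0.5 × 10⁹/L) caused by
non-chemotherapy drugs is rare, idiosyncratic and often dose-independent,
which makes it nearly invisible to clinical trials; spontaneous
adverse-event reporting systems such as FAERS are the main instrument for
detecting which drugs carry the risk. This package implements the full
analysis chain for such a study — ingestion and cleaning of quarterly report
bundles, disproportionality signal detection, risk classification of the
flagged drugs, time-to-onset characterization and mortality trends —
together with a synthetic report generator that makes every stage testable
against known ground truth.

## The disproportionality model

For a drug $D$ and target preferred term (PT), the cohort's reports cross
into a 2×2 table: $a$ (PS drug $D$, target event), $b$ ($D$, other events),
$c$ (other drugs, target event), $d$ (other drugs, other events). The
reporting odds ratio is

$$\mathrm{ROR} = \frac{a\,d}{b\,c},\qquad
  \mathrm{CI}_{95\%} = \exp\!\left(\ln \mathrm{ROR} \pm
  1.96\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right).$$

A **positive signal** requires $a \ge 3$ *and* lower CI bound $> 1$. Any
zero cell leaves the estimate undefined rather than applying a
Haldane–Anscombe 0.5 correction: the signal rule already demands $a \ge 3$,
so a correction would only manufacture estimates for tables the rule cannot
flag anyway, and the uncorrected formula is the one conventionally cited for
this statistic. The $z$ quantile (default 1.96) is an argument of
`ror_estimate()` for other coverage levels.

Case definition is the exact, case-insensitive PT string (default
"Agranulocytosis") — deliberately *not* an SMQ-style expansion into related
PTs (neutropenia, aplastic anemia, ...), which trades sensitivity for
specificity. Tests confirm that a report carrying only "Neutropenia" is not
a case. The reference group is all deduplicated reports minus those whose
primary suspect (PS) drug maps to any ATC code beginning `L01`; a
multi-coded product is excluded if *any* of its codes is chemotherapy
(conservative), and a drug the ATC map does not know stays in the reference
population but cannot contribute to class-level aggregation.

## Cleaning rules

FAERS cases are resubmitted as versions sharing a CASEID. `deduplicate()`
keeps, per CASEID, the version maximizing (FDA_DT, PRIMARYID)
lexicographically, with PRIMARYID compared numerically (FAERS PRIMARYIDs are
numeric strings; non-numeric values fall back to lexicographic rank among
themselves). Delete lists — shipped with quarterly bundles since 2019 — are
applied *after* deduplication, so a deleted latest version removes the case
entirely. Both operations are idempotent and only ever shrink the data;
tests assert equivalence with a brute-force group-by oracle on a thousand
shuffled versioned cases.

Each retained report is restricted to its PS drug. Raw data can
(rarely) carry several PS-coded rows; we keep the lowest drug-sequence row —
a deterministic rule preferred over dropping the report. Ages are converted
to years from their unit code (decades ×10, months ÷12, weeks ÷52.18, days
÷365.25, hours ÷8766); unknown unit codes and values outside [0, 150] years
become missing and are counted. Partial dates are imputed mid-period
(YYYYMM → day 15, YYYY → 1 July), unbiased within the stated period; onset
computation only uses reports where both therapy-start and event dates
resolve.

## Time-to-onset analysis

Onset is the plain day difference `event_date − therapy_start_date`
(same-day onset = 0); when several therapy rows exist for the PS drug the
*earliest* start anchors the interval, first exposure being the
pharmacologically relevant origin. Negative intervals are excluded and
counted — with mid-period imputation of partial dates these do occur and are
not errors. Strata are sex and the age bins <18, 18–44, 45–64, ≥65; unknown
strata are tabulated but excluded from every test. The battery is
Mann-Whitney (two groups; exact enumeration when both $n \le 8$, otherwise
normal approximation with tie and continuity corrections, via
`stats::wilcox.test`), Kruskal-Wallis (tie-corrected, `stats::kruskal.test`)
and Dunn's post-hoc z-tests on mean ranks, implemented here directly (no
post-hoc package is among the dependencies) and verified in tests against an
independent mean-rank recomputation and against the two-group equivalence
with Mann-Whitney. Bonferroni adjustment multiplies by the number of pairs
and caps at 1. Quartiles use linear interpolation between order statistics
(R's default type 7); medians/IQRs are permutation-invariant by
construction. Drug- and class-specific onset summaries require ≥ 20 onset
records — below that, medians of heavy-tailed onset distributions are too
unstable to report.

## Mortality analysis

A death is outcome code `DE`; life-threatening (`LT`) and other serious
outcomes are not deaths. Period trends bin by the *FDA receipt year* — the
same clock the deduplication uses — over 2004–2010, 2011–2015, 2016–2020,
2021–2024 by default (event-year binning would require complete event
dates, which spontaneous reports lack). Rates carry **Clopper–Pearson**
exact binomial CIs from beta quantiles; this choice was verified
numerically against the published intervals it must reproduce (e.g.
262/2199 → 10.59–13.34%), which a Wald interval does not match at the
printed precision. The omnibus test is the Pearson chi-square on the
$k \times 2$ table without continuity correction (standard for df > 1);
pairwise comparisons use 2×2 chi-squares *with* Yates correction, again the
only convention that reproduces the published adjusted values (0.687,
0.028, 0.010). Bonferroni-adjusted pairwise p-values are reported both
capped at 1 (default) and uncapped, because published tables sometimes
print the raw product (e.g. 1.838). The gender-balance check is a
one-degree-of-freedom goodness-of-fit chi-square of (F, M) counts against
50:50 with unknowns excluded — verified to reproduce the published
p = 0.420 from the reconstructed counts — while the death-vs-non-death
gender comparison is the 2×2-with-Yates test (reproduces p = 0.070; the
3×2 variant including unknowns was computed during verification and does
not). Every mortality function accepts pre-aggregated death/non-death
counts, so published summary tables are first-class inputs ("fixture
mode") and none of these checks require the unavailable raw extract.

## The synthetic generator

`generate_bundle()` emulates the modern FAERS quarterly layout: one
directory per quarter of "$"-delimited DEMO/DRUG/REAC/OUTC/THER tables,
empty string for missing, delete lists only for quarters ≥ 2019Q1. Ground
truth is planted through an odds model: a drug with multiplier $m$ has event
probability $m\,\omega_0/(1+m\,\omega_0)$ where $\omega_0 = p_0/(1-p_0)$ and
$p_0$ (default 0.02) is the background event probability, so $m$ *is* the
true odds ratio versus a background drug. Onset days are log-normal per drug
— the simplest skewed family consistent with the heavy-tailed medians/IQRs
such studies report; death-given-event is Bernoulli per drug. Demographics
default to the broad shape of real agranulocytosis report streams: roughly
balanced sexes with ~8% unknown, age centred near 57 years, ~15% missing
age, and half of reports lacking a usable onset interval. Duplicate
versions (default 10% of cases, a quarter of them FDA_DT ties that exercise
the PRIMARYID tie-break), delete rates and partial-date fractions are
configurable; missingness is injected independently per field.

What the generator does *not* emulate: reporter-dependent drug-name variants
(one verbatim name per drug), multi-ingredient products, true duplicate
*cases* (as opposed to versions), secular reporting trends and
notoriety-driven event bursts. Passing tests therefore certify the
computational chain — cleaning rules, estimators, test conventions — on data
whose generative model is known, not robustness to real-world name noise or
reporting bias.

## Calibration and recovery under known truth

Three property suites anchor the statistics (sizes chosen to estimate each
property to within a few percentage points of Monte-Carlo error):

- **Coverage.** One drug planted at odds ratio 10 among multiplier-1
  background drugs, $n = 50{,}000$ reports, 100 replicates: the estimated
  95% CI must cover 10 in ≥ 90 replicates (observed ≈ 93–95%).
- **Null calibration.** All multipliers 1, expected target count per drug
  ≈ 25, 200 replicates of $n = 5{,}000$: the positive-signal rate must stay
  ≤ 7.5% and agree with a direct Monte-Carlo of the same 2×2 generative
  model and rule. The rule is one-sided (lower bound > 1), so its null rate
  sits near 2–3%, below the two-sided 5%.
- **Consistency.** Median absolute log-ROR error against the planted
  multiplier must shrink from $n = 5{,}000$ to $n = 50{,}000$.

A deliberate subtlety the example analysis surfaces: with *several* elevated
drugs in the market, each drug's ROR is attenuated toward 1 because the
reference group itself is enriched in events (masking). The coverage suite
therefore uses exactly one elevated drug, matching the estimand the CI is
built for; the workflow scripts show the attenuated case with known truth.

## Risk classification

Positive-signal drugs are classified from an externally curated annotation
table (label/compendia review): documented agranulocytosis → **KNOWN**;
otherwise documented neutropenia-spectrum hematologic reactions →
**POSSIBLE**; neither → **NEW_POTENTIAL**. The review itself is an input,
not a computation — the shipped annotation file is synthetic and named
accordingly. A positive drug missing from the table lands in an explicit
UNANNOTATED bucket; absence is never read as "not documented". The four
buckets partition the positive drugs, and precedence is monotone:
documenting agranulocytosis can only move a drug to KNOWN.

## Interface choices and limitations

The package is organised as an analysis workflow: numbered scripts under
`analysis/` narrate a complete simulated study over the functions in `R/`,
which the test-suite and `scripts/acceptance.R` call directly; there is no
shell CLI beyond `Rscript`. Multi-valued fields (reactions, outcomes, ATC
codes) travel as ";"-packed strings so every intermediate table is a plain
TSV. Known limitations: no PRR/EBGM/Bayesian-shrinkage alternatives, no
survival treatment of onset censoring, no MedDRA version reconciliation, no
pre-2012 ISR-keyed layouts, and headline counts from any real FAERS extract
depend on the extract date and cannot be reproduced from this repository —
the validated quantities are the published summary-table statistics and the
synthetic-truth properties above.
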