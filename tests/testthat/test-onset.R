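test_that("onset is a whole-day difference; negatives are excluded and counted", {
  coh <- data.frame(
    primaryid = c("1", "2", "3", "4"),
    ps_drug_norm = "D", atc_codes = "N05AH02",
    event_dt = as.Date(c("2023-01-01", "2023-01-10", "2023-01-05", NA)),
    ther_start = as.Date(c("2023-01-01", "2023-01-01", "2023-01-08", "2023-01-01")),
    sex = "F", age_years = 50, outcomes = "",
    is_case = TRUE, stringsAsFactors = FALSE)
  on <- compute_onsets(coh)
  expect_equal(on$onset_days[on$primaryid == "1"], 0L)  # same day
  expect_equal(on$onset_days[on$primaryid == "2"], 9L)  # difference, not inclusive
  log <- attr(on, "onset_log")
  expect_equal(log$n_negative, 1L)
  expect_equal(log$n_unresolved, 1L)
  expect_equal(nrow(on), 2)
})

test_that("age groups bin at 18/45/65 with unknowns separate", {
  g <- age_group(c(0, 17.9, 18, 44, 45, 64.9, 65, 90, NA))
  expect_equal(as.character(g),
               c("<18", "<18", "18-44", "18-44", "45-64", "45-64",
                 ">=65", ">=65", "UNK"))
})

test_that("Mann-Whitney: symmetry, exact small-sample enumeration, power", {
  set.seed(61)
  x <- rlnorm(200, log(20), 1)
  expect_gt(mann_whitney(x, x)$p, 0.95)
  # exact two-sided p for complete separation of 3 vs 3 is 2/C(6,3) = 0.1
  r <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  # strongly shifted log-normals
  y <- rlnorm(400, log(60), 0.5)
  expect_lt(mann_whitney(rlnorm(400, log(10), 0.5), y)$p, 1e-3)
  # empty group is flagged undefined
  expect_false(mann_whitney(numeric(0), 1:3)$defined)
})

test_that("Kruskal-Wallis handles degenerate input and is calibrated under the null", {
  expect_false(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$defined)
  expect_false(kruskal_wallis(list(1:5))$defined)
  set.seed(67)
  rej <- mean(replicate(400, {
    g <- split(rlnorm(90, log(20), 1), rep(1:3, each = 30))
    kruskal_wallis(g)$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("two-group Kruskal-Wallis agrees in decision with Mann-Whitney", {
  set.seed(71)
  agree <- vapply(1:100, function(i) {
    shift <- sample(c(1, 1.6), 1)
    a <- rlnorm(40, log(20), 0.8)
    b <- rlnorm(40, log(20 * shift), 0.8)
    (kruskal_wallis(list(a, b))$p < 0.05) ==
      (mann_whitney(a, b)$p < 0.05)
  }, NA)
  expect_gte(mean(agree), 0.95)
})

test_that("Dunn-Bonferroni: single pair unadjusted, identical groups null, planted shift", {
  set.seed(73)
  a <- rlnorm(50, log(20), 1); b <- rlnorm(50, log(25), 1)
  d2 <- dunn_bonferroni(list(A = a, B = b))
  expect_equal(d2$p_adj_uncapped, d2$p_raw)  # one pair: no multiplication
  g <- rlnorm(60, log(20), 1)
  d4 <- dunn_bonferroni(list(a = g, b = g, c = g, d = g))
  expect_true(all(d4$p_adj == 1))
  # a strong shift in one of four groups: exactly its three pairs significant
  gs <- list(g1 = rlnorm(500, log(20), 0.6), g2 = rlnorm(500, log(20), 0.6),
             g3 = rlnorm(500, log(20), 0.6), g4 = rlnorm(500, log(70), 0.6))
  dd <- dunn_bonferroni(gs)
  hit <- dd$group1 == "g4" | dd$group2 == "g4"
  expect_true(all(dd$p_adj[hit] < 0.05))
  expect_true(all(dd$p_adj[!hit] > 0.05))
  # Bonferroni monotonicity, cap at 1
  expect_true(all(dd$p_adj >= dd$p_raw - 1e-15))
  expect_true(all(dd$p_adj <= 1))
})

test_that("Dunn z-statistics match an independent mean-rank recomputation", {
  set.seed(79)
  gs <- list(x = sample(1:30, 20, TRUE), y = sample(5:35, 25, TRUE),
             z = sample(1:40, 15, TRUE))  # ties present
  dd <- dunn_bonferroni(gs)
  # oracle: direct formula on pooled ranks
  pooled <- unlist(gs)
  r <- rank(pooled)
  N <- length(pooled)
  ties <- table(pooled)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  grp <- rep(names(gs), lengths(gs))
  for (i in seq_len(nrow(dd))) {
    g1 <- dd$group1[i]; g2 <- dd$group2[i]
    z_oracle <- (mean(r[grp == g1]) - mean(r[grp == g2])) /
      sqrt(s2 * (1 / sum(grp == g1) + 1 / sum(grp == g2)))
    expect_equal(dd$z[i], z_oracle, tolerance = 1e-12)
  }
})

test_that("drug onset summaries enforce the minimum-report filter and quartile convention", {
  onsets <- data.frame(
    primaryid = as.character(1:40),
    ps_drug_norm = c(rep("BIG", 21), rep("SMALL", 19)),
    atc_codes = c(rep("N05AH02", 21), rep("J01CA04", 19)),
    onset_days = c(1:21, 1:19), sex = "F",
    age_group = factor("45-64", levels = c("<18", "18-44", "45-64", ">=65", "UNK")),
    stringsAsFactors = FALSE)
  s <- drug_onset_summaries(onsets, min_reports = 20)
  expect_equal(s$by_drug$stratum, "BIG")
  expect_equal(s$by_drug$median, 11)
  expect_equal(s$by_drug$q1, 6)
  expect_equal(s$by_drug$q3, 16)
  expect_equal(s$by_class$stratum, "N05")
  # summaries are invariant under record order permutation
  perm <- onsets[sample(nrow(onsets)), ]
  expect_equal(drug_onset_summaries(perm, min_reports = 20)$by_drug,
               s$by_drug)
})

test_that("sample medians track generator onset parameters per drug", {
  b <- fixture_bundle(20000, seed = 83, duplicate_rate = 0, delete_rate = 0,
                      onset_missing_frac = 0.2)
  cases <- build_case_reports(as_raw_record_set(b))
  coh <- build_cohort(cases, fixture_atc_map())
  on <- compute_onsets(coh)
  s <- drug_onset_summaries(on, min_reports = 20)
  # Clozapine planted log-normal median exp(log 15) = 15 days
  cloz <- s$by_drug[s$by_drug$stratum == "CLOZAPINE", ]
  expect_gt(cloz$n, 100)
  expect_lt(abs(log(cloz$median) - log(15)), 0.35)
})

test_that("strata summaries exclude unknowns from tests but tabulate them", {
  set.seed(89)
  onsets <- data.frame(
    primaryid = as.character(1:300),
    ps_drug_norm = "D", atc_codes = "N05AH02",
    onset_days = round(rlnorm(300, log(20), 1)),
    sex = sample(c("F", "M", "UNK"), 300, TRUE, prob = c(.45, .45, .1)),
    age_group = age_group(sample(c(10, 30, 50, 80, NA), 300, TRUE)),
    stringsAsFactors = FALSE)
  s <- onset_strata_summary(onsets)
  expect_true("UNK" %in% s$by_sex$stratum)
  expect_equal(sum(s$by_sex$n), 300)
  expect_true(s$sex_test$defined)
  expect_equal(s$age_test$df, 3)
  expect_equal(nrow(s$age_pairwise), 6)
  expect_false(any(grepl("UNK", c(s$age_pairwise$group1, s$age_pairwise$group2))))
  # cumulative curve ends at 100%
  cc <- onset_cumulative_curve(onsets)
  expect_equal(cc$cum_pct[nrow(cc)], 100)
  expect_true(all(diff(cc$cum_pct) > 0))
})
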