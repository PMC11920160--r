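test_that("ROR point estimate and CI match the closed form", {
  # a=b=c=d: ROR 1, CI symmetric about 1 on the log scale
  e <- ror_estimate(5, 5, 5, 5)
  expect_equal(e$ror, 1)
  expect_equal(log(e$ci_low), -log(e$ci_high))
  # frozen values from an independent high-precision evaluation
  e2 <- ror_estimate(10, 90, 100, 9900)
  expect_equal(e2$ror, 11, tolerance = 1e-12)
  expect_equal(e2$ci_low, 5.559515, tolerance = 1e-5)
  expect_equal(e2$ci_high, 21.76449, tolerance = 1e-5)
  e3 <- ror_estimate(3, 7, 50, 10000)
  expect_equal(e3$ror, 85.71429, tolerance = 1e-5)
  expect_equal(e3$ci_low, 21.54709, tolerance = 1e-5)
  expect_equal(e3$ci_high, 340.9712, tolerance = 1e-3)
})

test_that("zero cells leave the estimate undefined; negative cells are rejected", {
  e <- ror_estimate(0, 10, 5, 100)
  expect_true(all(is.na(c(e$ror, e$ci_low, e$ci_high))))
  expect_error(ror_estimate(-1, 2, 3, 4), "negative")
})

test_that("ROR is invariant to scaling all cells; CI narrows as cells grow", {
  e1 <- ror_estimate(4, 16, 20, 160)
  e2 <- ror_estimate(40, 160, 200, 1600)
  expect_equal(e1$ror, e2$ror)
  expect_lt(e2$ci_high / e2$ci_low, e1$ci_high / e1$ci_low)
})

test_that("contingency tables match exhaustive enumeration on small cohorts", {
  set.seed(43)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    drugs <- sample(c("A", "B", "C"), n, replace = TRUE)
    is_case <- sample(c(TRUE, FALSE), n, replace = TRUE)
    coh <- data.frame(primaryid = as.character(seq_len(n)),
                      ps_drug_norm = drugs,
                      atc_codes = c(A = "N05AH02", B = "J01CA04", C = "N05AX08")[drugs],
                      is_case = is_case, stringsAsFactors = FALSE)
    for (dr in c("A", "B", "C")) {
      ct <- contingency(coh, drug = dr)
      # brute-force loop oracle
      a <- b <- c_ <- d <- 0L
      for (i in seq_len(n)) {
        if (drugs[i] == dr && is_case[i]) a <- a + 1L
        else if (drugs[i] == dr) b <- b + 1L
        else if (is_case[i]) c_ <- c_ + 1L
        else d <- d + 1L
      }
      expect_equal(unname(ct), c(a, b, c_, d))
      expect_equal(sum(ct), n)
    }
    # class index: N05 covers drugs A and C
    ct <- contingency(coh, atc_class = "N05")
    in_cls <- drugs %in% c("A", "C")
    expect_equal(unname(ct),
                 c(sum(in_cls & is_case), sum(in_cls & !is_case),
                   sum(!in_cls & is_case), sum(!in_cls & !is_case)))
  }
})

test_that("absent index drug gives an empty index margin", {
  coh <- data.frame(ps_drug_norm = c("A", "B"), atc_codes = c("", ""),
                    is_case = c(TRUE, FALSE), stringsAsFactors = FALSE)
  ct <- contingency(coh, drug = "ZZZ")
  expect_equal(unname(ct[c("a", "b")]), c(0L, 0L))
})

test_that("signal rule: >=3 target reports AND lower CI bound above one", {
  mk_cohort <- function(a, b, c_, d) {
    data.frame(
      ps_drug_norm = c(rep("X", a + b), rep("OTHER", c_ + d)),
      atc_codes = "",
      is_case = c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c_), rep(FALSE, d)),
      stringsAsFactors = FALSE)
  }
  sig_x <- function(coh) {
    s <- detect_signals(coh)
    s[s$drug == "X", ]
  }
  # a=3 with strong disproportionality: positive
  s <- sig_x(mk_cohort(3, 7, 50, 10000))
  expect_true(s$is_positive)
  # only 2 target reports: never positive, however large the ROR
  s <- sig_x(mk_cohort(2, 2, 50, 10000))
  expect_gt(s$ror, 1)
  expect_false(s$is_positive)
  # many reports but CI straddles 1: not positive
  s <- sig_x(mk_cohort(100, 1000, 1000, 10000))
  expect_lt(s$ci_low, 1)
  expect_false(s$is_positive)
})

test_that("detect_signals partitions cases across drugs and applies the rule", {
  coh <- fixture_cohort(4000, seed = 47)
  sig <- detect_signals(coh)
  expect_equal(sum(sig$a), sum(coh$is_case))
  expect_true(all(sig$a + sig$b + sig$c + sig$d == nrow(coh)))
  expect_equal(sig$is_positive,
               sig$a >= 3 & !is.na(sig$ci_low) & sig$ci_low > 1)
  # defined estimates keep the CI ordered around the point estimate
  ok <- !is.na(sig$ror)
  expect_true(all(sig$ci_low[ok] < sig$ror[ok] & sig$ror[ok] < sig$ci_high[ok]))
  # both rankings are permutations, deterministic under name tie-break
  expect_setequal(sig$rank_by_n, seq_len(nrow(sig)))
  expect_setequal(sig$rank_by_ror, seq_len(nrow(sig)))
  sig2 <- detect_signals(coh)
  expect_identical(sig, sig2)
})

test_that("class aggregation unions member drug tables and counts positive members", {
  coh <- fixture_cohort(4000, seed = 47)
  cs <- class_signals(coh)
  sig <- detect_signals(coh)
  for (i in seq_len(nrow(cs))) {
    cls <- cs$atc_class[i]
    member <- vapply(strsplit(coh$atc_codes, ";"), function(cc)
      any(substr(cc, 1, 3) == cls), NA)
    member[is.na(member)] <- FALSE
    expect_equal(cs$a[i], sum(member & coh$is_case))
    expect_equal(cs$b[i], sum(member & !coh$is_case))
  }
  # positive member drug counts agree with the drug-level table
  drug_cls <- substr(coh$atc_codes[match(sig$drug, coh$ps_drug_norm)], 1, 3)
  for (i in seq_len(nrow(cs)))
    expect_equal(cs$n_positive_drugs[i],
                 sum(sig$is_positive & drug_cls == cs$atc_class[i]))
})

test_that("a planted class-level signal is recovered within its CI", {
  drugs <- rbind(drug_profile("HitA", "N05AH02", 1, 8),
                 drug_profile("HitB", "N05AX08", 1, 8),
                 drug_profile("Bg1", "A10BA02", 6, 1),
                 drug_profile("Bg2", "J01CA04", 6, 1))
  cfg <- generator_config(30000, drugs, duplicate_rate = 0, delete_rate = 0,
                          seed = 53)
  cases <- build_case_reports(as_raw_record_set(generate_bundle(cfg)))
  coh <- build_cohort(cases, atc_map(drugs$name, drugs$atc_code))
  cs <- class_signals(coh)
  n05 <- cs[cs$atc_class == "N05", ]
  expect_true(n05$is_positive)
  expect_true(n05$ci_low <= 8 && 8 <= n05$ci_high)
})
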