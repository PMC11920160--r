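test_that("dollar-delimited parsing handles trailing delimiters and bad rows", {
  d <- withr::local_tempdir()
  qd <- file.path(d, "2023Q1")
  dir.create(qd, recursive = TRUE)
  writeLines(c("primaryid$caseid$caseversion$fda_dt$event_dt$sex$age$age_cod$occp_cod$reporter_country",
               "11$1$1$20230101$20230101$F$50$YR$MD$US",
               "12$2$1$20230102$$M$$$$",          # empty trailing fields
               "13$3$1$20230103$20230103$F$30$YR$MD$",  # trailing "$": empty final field
               "14$4$badrow"),                    # malformed: wrong field count
             file.path(qd, "DEMO.txt"))
  for (f in c("DRUG", "REAC", "OUTC", "THER")) {
    hdr <- switch(f, DRUG = "primaryid$caseid$drug_seq$role_cod$drugname",
                  REAC = "primaryid$caseid$pt", OUTC = "primaryid$caseid$outc_cod",
                  THER = "primaryid$caseid$dsg_drug_seq$start_dt")
    writeLines(hdr, file.path(qd, paste0(f, ".txt")))
  }
  rs <- parse_bundle(d)
  expect_equal(nrow(rs$demo), 3)
  expect_equal(rs$parse_log$malformed_rows, 1L)
  expect_equal(rs$demo$reporter_country[rs$demo$primaryid == "13"], "")
  expect_equal(rs$demo$event_dt[rs$demo$primaryid == "12"], "")
})

test_that("missing files and columns raise named errors", {
  d <- withr::local_tempdir()
  qd <- file.path(d, "2023Q1")
  dir.create(qd, recursive = TRUE)
  writeLines("primaryid$caseid$fda_dt", file.path(qd, "DEMO.txt"))
  expect_error(parse_bundle(d), "DRUG")
  expect_error(parse_bundle(file.path(d, "nope")), "not found")
})

test_that("deduplication keeps latest FDA_DT, then highest PRIMARYID", {
  demo <- rbind(demo_row("7", "100", "20230101"),
                demo_row("5", "100", "20230301"),
                demo_row("11", "200", "20230101"),
                demo_row("12", "200", "20230101"))
  rs <- deduplicate(tiny_record_set(demo))
  kept <- rs$demo$primaryid
  expect_setequal(kept, c("5", "12"))
})

test_that("deduplication removes child rows of dropped versions", {
  demo <- rbind(demo_row("1", "100", "20230101"), demo_row("2", "100", "20230601"))
  drug <- rbind(ps_row("1", "100", "OldDrug"), ps_row("2", "100", "NewDrug"))
  rs <- deduplicate(tiny_record_set(demo, drug = drug))
  expect_equal(rs$drug$drugname, "NewDrug")
})

test_that("deduplication matches a brute-force group-by oracle on 1000 shuffled cases", {
  set.seed(41)
  n_cases <- 1000
  versions <- sample(1:3, n_cases, replace = TRUE)
  demo <- do.call(rbind, lapply(seq_len(n_cases), function(i) {
    k <- versions[i]
    fda <- sample(c("20200101", "20210615", "20230301"), k, replace = TRUE)
    demo_row(as.character(sample(1e6, k)), as.character(i), fda)
  }))
  demo <- demo[sample(nrow(demo)), ]
  # oracle: per case, keep max by (numeric fda, numeric pid)
  oracle <- vapply(split(demo, demo$caseid), function(g) {
    g$primaryid[order(as.numeric(g$fda_dt), as.numeric(g$primaryid))][nrow(g)]
  }, "")
  rs <- deduplicate(tiny_record_set(demo))
  expect_setequal(rs$demo$primaryid, unname(oracle))
  # idempotence and monotonicity
  expect_identical(deduplicate(rs)$demo, rs$demo)
  expect_lte(nrow(rs$demo), nrow(demo))
})

test_that("delete lists remove retained cases entirely, after deduplication", {
  demo <- rbind(demo_row("1", "100", "20230101"), demo_row("2", "100", "20230601"),
                demo_row("3", "200", "20230101"))
  # deleting the retained latest version kills the case; the stale delete id
  # of an already-dropped old version is a no-op
  rs <- tiny_record_set(demo, delete_ids = c("2", "1"))
  out <- apply_deletes(deduplicate(rs))
  expect_setequal(out$demo$caseid, "200")
  expect_identical(apply_deletes(out)$demo, out$demo)  # idempotent
  # empty delete list is the identity
  rs2 <- deduplicate(tiny_record_set(demo))
  expect_identical(apply_deletes(rs2)$demo, rs2$demo)
})

test_that("age units normalize to years and implausible ages go missing", {
  demo <- rbind(demo_row("1", "1", "20230101", age = "24", age_cod = "MON"),
                demo_row("2", "2", "20230101", age = "700", age_cod = "YR"),
                demo_row("3", "3", "20230101", age = "6", age_cod = "DEC"),
                demo_row("4", "4", "20230101", age = "104.36", age_cod = "WK"),
                demo_row("5", "5", "20230101", age = "50", age_cod = "XX"))
  drug <- do.call(rbind, lapply(1:5, function(i) ps_row(as.character(i), as.character(i), "D")))
  cr <- build_case_reports(tiny_record_set(demo, drug = drug))
  ages <- cr$age_years[match(as.character(1:5), cr$primaryid)]
  expect_equal(ages[1], 2.0)
  expect_true(is.na(ages[2]))
  expect_equal(ages[3], 60)
  expect_equal(ages[4], 2.0, tolerance = 1e-6)
  expect_true(is.na(ages[5]))
  expect_equal(attr(cr, "ingest_log")$implausible_age, 1L)
})

test_that("only the primary suspect drug is carried; lowest seq wins among several PS rows", {
  demo <- demo_row("1", "1", "20230101")
  drug <- rbind(ps_row("1", "1", "Suspect", drug_seq = "2"),
                ps_row("1", "1", "FirstSuspect", drug_seq = "1"),
                ps_row("1", "1", "Concom", drug_seq = "3", role = "C"),
                ps_row("1", "1", "Secondary", drug_seq = "4", role = "SS"))
  cr <- build_case_reports(tiny_record_set(demo, drug = drug))
  expect_equal(cr$ps_drug, "FirstSuspect")
  expect_equal(attr(cr, "ingest_log")$multiple_ps_rows, 1L)
  # report with no PS drug is excluded and counted
  demo2 <- rbind(demo, demo_row("2", "2", "20230101"))
  drug2 <- rbind(drug, ps_row("2", "2", "OnlyConcom", role = "C"))
  cr2 <- build_case_reports(tiny_record_set(demo2, drug = drug2))
  expect_equal(nrow(cr2), 1)
  expect_equal(attr(cr2, "ingest_log")$no_ps_drug, 1L)
})

test_that("partial dates are imputed to mid-period anchors", {
  expect_equal(parse_faers_date("20230110"), as.Date("2023-01-10"))
  expect_equal(parse_faers_date("202303"), as.Date("2023-03-15"))
  expect_equal(parse_faers_date("2021"), as.Date("2021-07-01"))
  expect_true(is.na(parse_faers_date("")))
  expect_true(is.na(parse_faers_date("20231301")))
})

test_that("synthetic bundles round-trip: parsed counts equal generator bookkeeping", {
  b <- fixture_bundle(800, seed = 29, duplicate_rate = 0.2, delete_rate = 0.03)
  d <- withr::local_tempdir()
  write_bundle(b, d)
  rs <- parse_bundle(d)
  expect_equal(nrow(rs$demo), b$counts$n_versions)
  expect_equal(nrow(rs$drug), nrow(b$drug))
  expect_equal(sort(rs$delete_ids), sort(b$deletes$primaryid))
  cases <- build_case_reports(apply_deletes(deduplicate(rs)))
  expect_equal(nrow(cases), b$counts$n_cases - b$counts$n_deleted)
  # and the in-memory fast path agrees with the file round-trip
  cases2 <- build_case_reports(apply_deletes(deduplicate(as_raw_record_set(b))))
  expect_equal(sort(cases$primaryid), sort(cases2$primaryid))
})
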