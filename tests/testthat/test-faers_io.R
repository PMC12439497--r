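test_that("read_faers_table parses the dollar-delimited dialect", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid$fda_dt$sex$age$occr_country",
               "100001$9001$20230101$F$34$US",
               "100002$9002$20230102$$$"), f)
  x <- read_faers_table(f, "DEMO")
  expect_equal(nrow(x), 2L)
  expect_equal(x$sex[1], "F")
  expect_equal(x$age[1], "34")
  expect_equal(x$occr_country[2], "")  # missing preserved as empty string
  expect_equal(names(x), c("primaryid", "caseid", "fda_dt", "sex", "age",
                           "occr_country"))
})

test_that("header-only file yields an empty table", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("primaryid$caseid$fda_dt", f)
  x <- read_faers_table(f, "DEMO")
  expect_equal(nrow(x), 0L)
  expect_equal(names(x), c("primaryid", "caseid", "fda_dt"))
})

test_that("format errors name the offending column or line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$fda_dt", "1$20230101"), f)
  expect_error(read_faers_table(f, "DEMO"), "caseid",
               class = "faersig_format_error")
  writeLines(c("primaryid$caseid$fda_dt", "1$2$20230101", "1$2"), f)
  expect_error(read_faers_table(f, "DEMO"), "line 3",
               class = "faersig_format_error")
})

test_that("write/read round trip is the identity", {
  gen <- generate_faers(synthetic_config(n_reports = 60, seed = 11,
                                         duplicate_fraction = 0.2))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (kind in names(gen$reports)) {
    p1 <- file.path(d1, paste0(kind, ".txt"))
    write_faers_table(gen$reports[[kind]], p1)
    back <- read_faers_table(p1, kind)
    expect_equal(as.data.frame(back), as.data.frame(gen$reports[[kind]]),
                 ignore_attr = TRUE)
    p2 <- file.path(d2, paste0(kind, ".txt"))
    write_faers_table(back, p2)
    expect_identical(readLines(p1), readLines(p2))
  }
})

test_that("assemble_reports joins child rows and types fields", {
  tabs <- list(
    DEMO = data.table(primaryid = c("100001", "100002", "abc"),
                      caseid = c("9001", "9002", "9003"),
                      fda_dt = c("20230101", "20230102", "20230103"),
                      sex = c("F", "x", ""), age = c("34", "7", "700"),
                      age_cod = c("YR", "MON", "YR"),
                      occr_country = c("US", "", "")),
    REAC = data.table(primaryid = c("100001", "100001", "100002", "999"),
                      pt = c("Somnolence", "Dizziness", "Fall", "Orphan")),
    OUTC = data.table(primaryid = c("100001", "100002"),
                      outc_cod = c("HO", "ZZ")),
    DRUG = data.table(primaryid = "100001", drugname = "VIMPAT",
                      role_cod = "ps", dose_amt = "200", dose_unit = "MG",
                      dose_freq = "QD"))
  rs <- assemble_reports(tabs)
  expect_equal(n_reports(rs), 2L)  # non-numeric primaryid rejected
  rej <- attr(rs, "rejects")
  expect_equal(nrow(rej$demo_rejects), 1L)
  expect_equal(unname(rej$orphans[["REAC"]]), 1L)
  expect_equal(sum(rs$reac$primaryid == 100001), 2L)
  expect_equal(rs$demo$sex, c("female", "unknown"))
  expect_equal(rs$demo$age_years, c(34, NA))  # non-year unit -> missing
  expect_equal(rs$demo$country, c("US", NA))
  expect_equal(rs$outc$outcome[rs$outc$primaryid == 100001], "hospitalization")
  expect_equal(rs$outc$outcome[rs$outc$primaryid == 100002], "unknown")
  expect_equal(rs$drug$role, "PS")
  expect_equal(rs$drug$daily_dose_mg, 200)
})

test_that("assembly conserves counts", {
  gen <- generate_faers(synthetic_config(n_reports = 200, seed = 5))
  rs <- assemble_reports(gen$reports)
  expect_equal(n_reports(rs), nrow(gen$reports$DEMO))
  matched <- unique(gen$reports$REAC)
  expect_equal(nrow(rs$reac), nrow(matched))
})

test_that("the bundled signal fixture matches the published structure", {
  fx <- read_signal_fixture()
  expect_equal(nrow(fx), 153L)
  mdr <- fx[pt == "Multiple-drug resistance" & drug == "lacosamide"]
  expect_equal(mdr$n, 177L)
  expect_equal(mdr$prr, 95.75)
  expect_equal(mdr$ic_minus_2sd, 6.25)
  dip <- fx[pt == "Diplopia" & drug == "cenobamate"]
  expect_equal(dip$n, 83L)
  expect_equal(dip$ic_minus_2sd, 3.8)
  # "/" cells were transcribed as absent rows
  expect_equal(nrow(fx[pt == "Atrial flutter" & drug == "cenobamate"]), 0L)
  socs <- fx[drug == "lacosamide", .N, by = soc]
  expect_equal(socs[soc == "Cardiac disorders"]$N, 18L)
  expect_equal(socs[soc == "Congenital, familial and genetic disorders"]$N, 13L)
  expect_equal(socs[soc == "Investigations"]$N, 5L)
})

test_that("fixture validation catches transcription bugs", {
  fx <- read_signal_fixture()
  bad <- copy(fx)[1, n := 5L]
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_signal_fixture(f), "n >= 6")
  bad2 <- copy(fx)[2, ror_ci025 := 1e6]
  utils::write.csv(bad2, f, row.names = FALSE)
  expect_error(read_signal_fixture(f), "ror_ci025")
})
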