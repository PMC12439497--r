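test_that("baseline blocks count and percentage with half-up rounding", {
  rs <- mk_rs(list(
    list(pid = 1, sex = "female", age = 17.9, country = "US",
         events = "evE", outcomes = "hospitalization"),
    list(pid = 2, sex = "male", age = 18, country = "US", events = "evE"),
    list(pid = 3, sex = "female", age = 50, country = "JP", events = "evE",
         outcomes = c("hospitalization", "death")),
    list(pid = 4, age = 80, events = "evE"),
    list(pid = 5, events = "evE"),
    list(pid = 6, age = 49.5, country = "US", events = "evE")))
  bl <- baseline_characteristics(rs)
  expect_equal(bl$n_reports, 6)
  expect_equal(bl$sex[level == "female"]$count, 2)
  expect_equal(bl$sex[level == "unknown"]$count, 3)
  age <- setNames(bl$age$count, bl$age$level)
  expect_equal(unname(age[c("<18", "18-49", "50-79", ">=80", "Unknown")]),
               c(1, 2, 1, 1, 1))
  expect_equal(bl$outcomes[level == "hospitalization"]$count, 2)
  expect_equal(bl$outcomes[level == "death"]$count, 1)
  expect_equal(bl$country[level == "US"]$count, 3)
  expect_equal(bl$country[level == "US"]$pct, 50.0)
  # percentages within a complete block sum to ~100
  expect_equal(sum(bl$sex$pct), 100, tolerance = 0.3)
  expect_equal(sum(bl$age$pct), 100, tolerance = 0.3)
  expect_error(baseline_characteristics(report_set(rs$demo[0])), "zero reports")
})

test_that("half-up rounding matches the printing convention", {
  expect_equal(round_half_up(0.25, 1), 0.3)  # base round() would give 0.2
  expect_equal(round_half_up(12.04, 1), 12.0)
  expect_equal(round_half_up(-0.25, 1), -0.3)
})

test_that("top_events ranks by count with alphabetical ties", {
  rs <- mk_rs(c(
    lapply(1:5, function(i) list(pid = i, events = "evE")),
    lapply(6:8, function(i) list(pid = i, events = c("evF", "evB"))),
    list(list(pid = 9, events = "evB"))))
  te <- top_events(rs, 10)
  expect_equal(te$pt, c("evE", "evB", "evF"))
  expect_equal(te$count, c(5, 4, 3))
  expect_equal(nrow(top_events(rs, 2)), 2L)
  # tie broken alphabetically
  te2 <- top_events(rs, 10)[count == 3 | count == 4]
  expect_equal(te2$pt, sort(te2$pt))
})

test_that("dose strata use half-open range bins and exact titration bins", {
  rs <- mk_rs(list(
    list(pid = 1, age = 34, drugs = list(c("VIMPAT", "PS", 150)), events = "evE"),
    list(pid = 2, age = 40, drugs = list(c("VIMPAT", "PS", 200)), events = "evE"),
    list(pid = 3, age = 17, drugs = list(c("VIMPAT", "PS", 150)), events = "evE"),
    list(pid = 4, age = 50, drugs = list(c("VIMPAT", "PS", 100)), events = "evE"),
    list(pid = 5, age = 60, drugs = list(c("VIMPAT", "PS", 500)), events = "evE"),
    list(pid = 6, age = 70, drugs = list(c("VIMPAT", "PS")), events = "evE")))
  ds <- dose_strata_counts(rs, dose_bins_ranges(c(100, 200, 400)))
  cnt <- setNames(ds$count, ds$bin)
  # 200 mg falls in (100, 200]; 100 mg in <=100; age 17 excluded
  expect_equal(unname(cnt[c("<=100", "100-200", "200-400", ">400")]),
               c(1, 2, 0, 1))
  expect_equal(attr(ds, "unparsed_dose"), 1L)

  rs2 <- mk_rs(list(
    list(pid = 1, age = 30, drugs = list(c("XCOPRI", "PS", 12.5)), events = "evE"),
    list(pid = 2, age = 30, drugs = list(c("XCOPRI", "PS", 25)), events = "evE"),
    list(pid = 3, age = 30, drugs = list(c("XCOPRI", "PS", 30)), events = "evE")))
  ds2 <- dose_strata_counts(rs2, dose_bins_exact())
  expect_equal(ds2[bin == "12.5 mg"]$count, 1)
  expect_equal(ds2[bin == "25 mg"]$count, 1)
  expect_equal(sum(ds2$count), 2)  # 30 mg matches no titration dose
})

test_that("compare_signals unions signal sets and restricts the forest", {
  mk_res <- function(drug, events, socs, sig) {
    data.table(drug = drug, event = events, level = "PT", soc = socs,
               a = 20, prr = 3, chi2 = 50, ror = 3, ror_ci_low = 2,
               ror_ci_high = 4.5, e_ic = 1.5, v_ic = 0.01,
               ic_minus_2sd = 1.3, is_signal = sig, is_strong = sig)
  }
  ra <- mk_res("drugX", c("evE", "evF", "evG"), c("SOC1", "SOC1", "SOC2"),
               c(TRUE, TRUE, FALSE))
  rb <- mk_res("drugY", c("evE", "evG"), c("SOC1", "SOC2"), c(TRUE, TRUE))
  cmp <- compare_signals(ra, rb)
  expect_equal(nrow(cmp$comparison), 3L)  # |signals_A union signals_B|
  expect_equal(sum(cmp$comparison$shared), 1L)  # only evE in both
  expect_true(cmp$comparison[pt == "evE"]$shared)
  expect_setequal(unique(cmp$forest$pt), "evE")
  expect_equal(nrow(cmp$forest), 2L)
  # Sankey edges connect drug -> PT and PT -> SOC
  expect_true(all(c("drugX", "drugY") %in% cmp$sankey$from))
  expect_true("SOC1" %in% cmp$sankey$to)
})

test_that("strong signals are counted at the IC-2SD cut", {
  fx <- read_signal_fixture()
  expect_equal(count_strong_signals(fx, "cenobamate"), 55L)
  expect_equal(count_strong_signals(fx, "lacosamide"), 98L)
  expect_equal(count_strong_signals(fx[0], "cenobamate"), 0L)
  # threshold is inclusive
  one <- data.frame(drug = "x", ic_minus_2sd = 1.0)
  expect_equal(count_strong_signals(one, "x"), 1L)
})
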