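test_that("ROR and Woolf interval reproduce hand-computed values", {
  r <- ror_with_ci(10, 10, 10, 10)
  expect_equal(r$ror, 1.0)
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)

  r2 <- ror_with_ci(5, 95, 100, 9900)
  expect_equal(r2$ror, 5.2105, tolerance = 1e-4)
  expect_equal(r2$ci_low, 2.075, tolerance = 1e-3)

  # odds-ratio antisymmetry under (a<->b, c<->d)
  r3 <- ror_with_ci(95, 5, 9900, 100)
  expect_equal(r3$ror, 1 / r2$ror)

  # any zero cell -> incalculable
  expect_true(all(is.na(ror_with_ci(0, 10, 10, 10))))
})

test_that("PRR and chi-squared reproduce hand-computed values", {
  p <- prr_chi2(10, 10, 10, 10)
  expect_equal(p$prr, 1.0)
  expect_equal(p$chi2, 0)

  p2 <- prr_chi2(5, 95, 100, 9900)
  expect_equal(p2$prr, 5.0)
  expect_equal(p2$chi2, 15.40, tolerance = 1e-3)

  # transpose invariance of the Pearson statistic
  p3 <- prr_chi2(5, 100, 95, 9900)
  expect_equal(p3$chi2, p2$chi2)

  expect_true(is.na(prr_chi2(5, 95, 0, 9900)$prr))
})

test_that("BCPNN posterior moments behave at independence and in the limit", {
  ic <- bcpnn_ic(1000, 9000, 9000, 81000)
  expect_lt(abs(ic$e_ic), 0.01)

  # scaling a fixed-proportion table approaches the closed-form MLE IC
  k <- 1000
  ic2 <- bcpnn_ic(5 * k, 95 * k, 100 * k, 9900 * k)
  expect_equal(ic2$e_ic, 2.266, tolerance = 1e-3)  # log2(50500/10500)

  # shrinkage keeps a = 0 finite and negative
  ic0 <- bcpnn_ic(0, 100, 100, 9800)
  expect_true(is.finite(ic0$e_ic))
  expect_lt(ic0$e_ic, 0)
  expect_true(is.finite(ic0$ic_minus_2sd))
})

test_that("all statistics match independent oracles on random tables", {
  set.seed(99)
  for (i in 1:200) {
    a <- sample(1:50, 1); b <- sample(1:500, 1)
    cc <- sample(1:500, 1); d <- sample(10:20000, 1)
    r <- ror_with_ci(a, b, cc, d)
    o <- oracle_ror(a, b, cc, d)
    expect_equal(c(r$ror, r$ci_low, r$ci_high), o, tolerance = 1e-9)
    p <- prr_chi2(a, b, cc, d)
    expect_equal(p$prr, oracle_prr(a, b, cc, d), tolerance = 1e-9)
    expect_equal(p$chi2, oracle_chi2(a, b, cc, d), tolerance = 1e-9)
    py <- prr_chi2(a, b, cc, d, yates = TRUE)
    expect_equal(py$chi2, oracle_chi2(a, b, cc, d, yates = TRUE),
                 tolerance = 1e-9)
    ic <- bcpnn_ic(a, b, cc, d)
    oic <- oracle_ic(a, b, cc, d)
    expect_equal(c(ic$e_ic, ic$v_ic, ic$ic_minus_2sd), oic, tolerance = 1e-9)
  }
})

test_that("ror, prr and e_ic are monotone in a with b, c, d fixed", {
  b <- 200; cc <- 300; d <- 50000
  a <- 1:60
  r <- ror_with_ci(a, b, cc, d)$ror
  p <- prr_chi2(a, b, cc, d)$prr
  e <- bcpnn_ic(a, b, cc, d)$e_ic
  expect_true(all(diff(r) >= 0))
  expect_true(all(diff(p) >= 0))
  expect_true(all(diff(e) >= 0))
})

test_that("the composite signal rule applies the printed thresholds", {
  crit <- signal_criteria()
  # published strong-signal row, fed through with its printed statistics
  row <- data.frame(a = 177, ror = 96.17, ror_ci_low = 82.51, prr = 95.75,
                    chi2 = 15413.47, ic_minus_2sd = 6.25)
  out <- evaluate_signal(row, crit)
  expect_true(out$is_signal)
  expect_true(out$is_strong)

  # a = 5 fails the report-count floor even if all else passes
  out2 <- evaluate_signal(transform(row, a = 5), crit)
  expect_false(out2$is_signal)

  # lower CI bound at or below 1 fails
  out3 <- evaluate_signal(transform(row, ror = 2.5, ror_ci_low = 0.9), crit)
  expect_false(out3$is_signal)

  # boundary semantics: a >= 6 and ROR >= 2 inclusive, PRR > 2 strict,
  # chi2 > 4 strict, IC-2SD > 0 strict
  edge <- data.frame(a = 6, ror = 2, ror_ci_low = 1.01, prr = 2.01,
                     chi2 = 4.01, ic_minus_2sd = 0.01)
  expect_true(evaluate_signal(edge, crit)$is_signal)
  expect_false(evaluate_signal(transform(edge, prr = 2), crit)$is_signal)
  expect_false(evaluate_signal(transform(edge, chi2 = 4), crit)$is_signal)
  expect_false(evaluate_signal(transform(edge, ic_minus_2sd = 0), crit)$is_signal)

  # incalculable statistics fail their condition
  out4 <- evaluate_signal(transform(row, ror = NA_real_, ror_ci_low = NA_real_),
                          crit)
  expect_false(out4$is_signal)
  # strong implies signal
  expect_false(evaluate_signal(transform(edge, ic_minus_2sd = 0), crit)$is_strong)
})

test_that("dispro_stats carries tables through to verdicts", {
  tab <- contingency_table(30, 170, 300, 49500, drug = "drugX", event = "evE")
  res <- dispro_stats(tab)
  expect_equal(res$a, 30)
  expect_equal(res$ror, (30 * 49500) / (170 * 300), tolerance = 1e-12)
  expect_true(res$is_signal)
  expect_true(res$ror_ci_low < res$ror & res$ror < res$ror_ci_high)
  expect_equal(res$ic_minus_2sd, res$e_ic - 2 * sqrt(res$v_ic))
})
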