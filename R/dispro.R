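# Disproportionality statistics on report-level 2x2 tables.
#
# All functions are vectorised over the four cell counts and also accept a
# single `contingency_table`. Zero cells make ROR/PRR incalculable (NA);
# no continuity correction is applied by default, because with the a >= 6
# signal floor no candidate table has a zero target cell, and corrections
# would silently change printed-style outputs. The BCPNN posterior keeps
# every quantity finite, including a = 0.

unpack_cells <- function(a, b, c, d) {
  x <- if (inherits(a, "contingency_table"))
    list(a = a$a, b = a$b, c = a$c, d = a$d)
  else list(a = a, b = b, c = c, d = d)
  # doubles throughout: products like (N+2)^2 overflow 32-bit integers
  lapply(x, as.numeric)
}

#' Reporting odds ratio with Woolf 95% interval
#'
#' `ROR = (a d)/(b c)`; the 95% confidence interval is computed on the log
#' scale, `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, with the
#' conventional multiplier `z = 1.96` as printed in the field's formulas.
#'
#' @param a a `contingency_table`, or the count of reports with target drug
#'   and target event.
#' @param b,c,d remaining cell counts (ignored when `a` is a table).
#' @param z normal multiplier of the Woolf interval (default 1.96).
#' @return data.frame with columns `ror`, `ci_low`, `ci_high`; all `NA`
#'   (incalculable) when any cell is zero.
#' @examples
#' ror_with_ci(5, 95, 100, 9900)
#' @export
ror_with_ci <- function(a, b = NULL, c = NULL, d = NULL, z = 1.96) {
  x <- unpack_cells(a, b, c, d)
  calc <- x$a > 0 & x$b > 0 & x$c > 0 & x$d > 0
  ror <- ifelse(calc, (x$a * x$d) / (x$b * x$c), NA_real_)
  se <- ifelse(calc, sqrt(1 / x$a + 1 / x$b + 1 / x$c + 1 / x$d), NA_real_)
  data.frame(ror = ror,
             ci_low = exp(log(ror) - z * se),
             ci_high = exp(log(ror) + z * se))
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' `PRR = (a/(a+b)) / (c/(c+d))`; the chi-squared statistic is the Pearson
#' statistic on the 2x2 table, uncorrected by default (the conventional
#' reading of the "chi-squared > 4" signal threshold), with the Yates
#' continuity correction available by flag.
#'
#' @inheritParams ror_with_ci
#' @param yates apply the Yates continuity correction.
#' @return data.frame with columns `prr`, `chi2`; `prr` is `NA`
#'   (incalculable) when `a = 0`, `c = 0` or a margin is empty, `chi2` is
#'   `NA` when any margin is zero.
#' @examples
#' prr_chi2(5, 95, 100, 9900)
#' @export
prr_chi2 <- function(a, b = NULL, c = NULL, d = NULL, yates = FALSE) {
  x <- unpack_cells(a, b, c, d)
  n1 <- x$a + x$b
  n0 <- x$c + x$d
  calc <- n1 > 0 & n0 > 0 & x$c > 0 & x$a > 0
  prr <- ifelse(calc, (x$a / n1) / (x$c / n0), NA_real_)

  N <- x$a + x$b + x$c + x$d
  m1 <- x$a + x$c
  m0 <- x$b + x$d
  ok <- n1 > 0 & n0 > 0 & m1 > 0 & m0 > 0
  e_a <- n1 * m1 / N
  e_b <- n1 * m0 / N
  e_c <- n0 * m1 / N
  e_d <- n0 * m0 / N
  dev <- abs(x$a - e_a)  # equal in absolute value across all four cells
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- ifelse(ok, dev^2 * (1 / e_a + 1 / e_b + 1 / e_c + 1 / e_d), NA_real_)
  data.frame(prr = prr, chi2 = chi2)
}

#' BCPNN information component (posterior moments)
#'
#' Closed-form posterior mean and variance of the information component
#' `IC = log2 P(drug, event) / (P(drug) P(event))` under the standard
#' BCPNN priors (`alpha1 = beta1 = 1`, `alpha = beta = 2`, `gamma11 = 1`,
#' with `gamma` tuned so the prior IC mean is 0):
#' \deqn{E(IC) = \log_2 \frac{(a+\gamma_{11})(N+\alpha)(N+\beta)}
#'   {(N+\gamma)(a+b+\alpha_1)(a+c+\beta_1)}}
#' and the matching delta-method variance. The conservative signal bound is
#' `IC - 2SD = E(IC) - 2 sqrt(V(IC))`; the Bayesian shrinkage keeps both
#' finite for any table, including `a = 0`.
#'
#' @inheritParams ror_with_ci
#' @return data.frame with columns `e_ic` (bits), `v_ic` (bits^2),
#'   `ic_minus_2sd` (bits).
#' @examples
#' bcpnn_ic(1000, 9000, 9000, 81000) # independence: E(IC) ~ 0
#' @export
bcpnn_ic <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- unpack_cells(a, b, c, d)
  N <- x$a + x$b + x$c + x$d
  if (any(N <= 0)) stop_faersig("bcpnn_ic: N must be positive")
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  n1 <- x$a + x$b   # drug margin
  m1 <- x$a + x$c   # event margin
  gam <- g11 * (N + al) * (N + be) / ((n1 + a1) * (m1 + b1))
  e_ic <- log2((x$a + g11) * (N + al) * (N + be) /
                 ((N + gam) * (n1 + a1) * (m1 + b1)))
  v_ic <- ((N - x$a + gam - g11) / ((x$a + g11) * (1 + N + gam)) +
             (N - n1 + al - a1) / ((n1 + a1) * (1 + N + al)) +
             (N - m1 + be - b1) / ((m1 + b1) * (1 + N + be))) / log(2)^2
  data.frame(e_ic = e_ic, v_ic = v_ic,
             ic_minus_2sd = e_ic - 2 * sqrt(v_ic))
}

#' Composite signal-detection thresholds
#'
#' The four-part rule: (1) `a >= 6`; (2) `ROR >= 2` with the lower 95%
#' bound `> 1`; (3) `PRR > 2` with `chi-squared > 4` (both strict); and
#' (4) `IC - 2SD > 0`. A strong signal additionally has
#' `IC - 2SD >= strong_ic_minus_2sd` (default 1.0). Inequalities are
#' inclusive or strict exactly as the rule prints them.
#'
#' @param min_a minimum target-cell count (inclusive).
#' @param min_ror minimum ROR (inclusive).
#' @param ror_ci_low_gt lower 95% ROR bound must exceed this (strict).
#' @param min_prr PRR must exceed this (strict).
#' @param min_chi2 chi-squared must exceed this (strict).
#' @param ic_minus_2sd_gt IC-2SD must exceed this (strict).
#' @param strong_ic_minus_2sd IC-2SD cut for a strong signal (inclusive).
#' @return an object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_a = 6, min_ror = 2, ror_ci_low_gt = 1,
                            min_prr = 2, min_chi2 = 4, ic_minus_2sd_gt = 0,
                            strong_ic_minus_2sd = 1.0) {
  vals <- c(min_a, min_ror, ror_ci_low_gt, min_prr, min_chi2,
            ic_minus_2sd_gt, strong_ic_minus_2sd)
  if (any(!is.finite(vals))) stop_faersig("signal_criteria: thresholds must be finite")
  structure(list(min_a = min_a, min_ror = min_ror,
                 ror_ci_low_gt = ror_ci_low_gt, min_prr = min_prr,
                 min_chi2 = min_chi2, ic_minus_2sd_gt = ic_minus_2sd_gt,
                 strong_ic_minus_2sd = strong_ic_minus_2sd),
            class = "signal_criteria")
}

#' Apply the composite signal rule
#'
#' Evaluates the four-condition rule on computed statistics. An
#' incalculable (`NA`) statistic fails its condition. `is_strong` implies
#' `is_signal`.
#'
#' @param results data.frame/data.table with columns `a`, `ror`,
#'   `ror_ci_low`, `prr`, `chi2`, `ic_minus_2sd` (as produced by
#'   [dispro_stats()], or assembled from published statistics).
#' @param criteria a [signal_criteria()].
#' @return `results` with logical columns `is_signal` and `is_strong`
#'   added/overwritten.
#' @export
evaluate_signal <- function(results, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  res <- data.table::as.data.table(results)
  pass <- function(x) !is.na(x) & x
  sig <- pass(res$a >= criteria$min_a) &
    pass(res$ror >= criteria$min_ror) &
    pass(res$ror_ci_low > criteria$ror_ci_low_gt) &
    pass(res$prr > criteria$min_prr) &
    pass(res$chi2 > criteria$min_chi2) &
    pass(res$ic_minus_2sd > criteria$ic_minus_2sd_gt)
  res[, is_signal := sig]
  res[, is_strong := sig & pass(res$ic_minus_2sd >= criteria$strong_ic_minus_2sd)]
  res[]
}

#' Compute all disproportionality statistics for a set of tables
#'
#' @param tables data.table of 2x2 tables as from [build_all_tables()]
#'   (columns `a`, `b`, `c`, `d` at minimum), or a single
#'   `contingency_table`.
#' @param criteria a [signal_criteria()]; pass `NULL` to skip the verdicts.
#' @param yates use the Yates-corrected chi-squared.
#' @return the input with columns `ror`, `ror_ci_low`, `ror_ci_high`,
#'   `prr`, `chi2`, `e_ic`, `v_ic`, `ic_minus_2sd` (+ `is_signal`,
#'   `is_strong` unless `criteria` is `NULL`).
#' @export
dispro_stats <- function(tables, criteria = signal_criteria(), yates = FALSE) {
  if (inherits(tables, "contingency_table")) {
    tables <- data.table::data.table(drug = tables$drug, event = tables$event,
                                     level = tables$level, a = tables$a,
                                     b = tables$b, c = tables$c, d = tables$d)
  }
  res <- data.table::as.data.table(tables)
  r <- ror_with_ci(res$a, res$b, res$c, res$d)
  p <- prr_chi2(res$a, res$b, res$c, res$d, yates = yates)
  ic <- bcpnn_ic(res$a, res$b, res$c, res$d)
  res[, `:=`(ror = r$ror, ror_ci_low = r$ci_low, ror_ci_high = r$ci_high,
             prr = p$prr, chi2 = p$chi2, e_ic = ic$e_ic, v_ic = ic$v_ic,
             ic_minus_2sd = ic$ic_minus_2sd)]
  if (!is.null(criteria)) res <- evaluate_signal(res, criteria)
  res[]
}

#' End-to-end disproportionality analysis for one drug
#'
#' Builds every PT (and SOC) table for the drug within the analysed report
#' universe, computes ROR/PRR/chi-squared/IC, and applies the composite
#' signal rule.
#'
#' @inheritParams build_all_tables
#' @inheritParams dispro_stats
#' @return data.table, one row per (drug, event) table, mirroring the
#'   published column order: `drug`, `event`, `level`, `soc`, `a` (N),
#'   `prr`, `chi2`, `ror`, `ror_ci_low`, `ror_ci_high`, `e_ic`,
#'   `ic_minus_2sd`, `is_signal`, `is_strong`.
#' @export
dispro_analysis <- function(reports, drug, dict, vocab = NULL,
                            criteria = signal_criteria(),
                            roles = c("PS", "SS"), levels = c("PT", "SOC"),
                            yates = FALSE) {
  tabs <- build_all_tables(reports, drug, dict, vocab, roles, levels)
  dispro_stats(tabs, criteria, yates)
}
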