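# Descriptive tables and two-drug signal comparison: baseline
# characteristics, top events, daily-dose strata, shared-signal comparison
# (forest + Sankey exports) and strong-signal counting.

AGE_BANDS <- c("<18", "18-49", "50-79", ">=80", "Unknown")
OUTCOME_LEVELS <- c("death", "disability", "life_threatening",
                    "hospitalization", "other", "unknown")

age_band <- function(age) {
  band <- rep("Unknown", length(age))
  band[!is.na(age) & age < 18] <- "<18"
  band[!is.na(age) & age >= 18 & age < 50] <- "18-49"
  band[!is.na(age) & age >= 50 & age < 80] <- "50-79"
  band[!is.na(age) & age >= 80] <- ">=80"
  band
}

#' Baseline characteristics of a drug's reports
#'
#' Counts and percentages per block — sex, age band (`<18`, `18-49`,
#' `50-79`, `>=80`, `Unknown`), serious outcomes, reporter country — with
#' the drug's total report count as the denominator throughout and
#' percentages rounded half-up to one decimal (the table-printing
#' convention). Missing sex/age/country count as `Unknown`.
#'
#' @param reports a drug-selected, deduplicated `report_set`.
#' @param top_countries how many individual countries to list before
#'   collapsing into "Other countries".
#' @return list of data.tables (`sex`, `age`, `outcomes`, `country`), each
#'   with columns `level`, `count`, `pct`, plus `n_reports`.
#' @export
baseline_characteristics <- function(reports, top_countries = 5L) {
  n <- n_reports(reports)
  if (n == 0L) stop_faersig("baseline_characteristics: zero reports")
  demo <- reports$demo

  block <- function(values, levels) {
    cnt <- vapply(levels, function(l) sum(values == l), integer(1))
    data.table::data.table(level = levels, count = cnt, pct = pct1(cnt, n))
  }

  sex_block <- block(demo$sex, c("female", "male", "unknown"))
  age_block <- block(age_band(demo$age_years), AGE_BANDS)

  oc <- reports$outc
  out_cnt <- vapply(OUTCOME_LEVELS, function(l)
    length(unique(oc$primaryid[oc$outcome == l])), integer(1))
  out_block <- data.table::data.table(level = OUTCOME_LEVELS, count = out_cnt,
                                      pct = pct1(out_cnt, n))

  country <- demo$country
  country[is.na(country)] <- "Unknown"
  ctab <- sort(table(country), decreasing = TRUE)
  top <- names(utils::head(ctab, top_countries))
  cn <- ifelse(country %in% top, country, "Other countries")
  ctab2 <- sort(table(cn), decreasing = TRUE)
  country_block <- data.table::data.table(level = names(ctab2),
                                          count = as.integer(ctab2),
                                          pct = pct1(as.integer(ctab2), n))

  list(n_reports = n, sex = sex_block, age = age_block,
       outcomes = out_block, country = country_block)
}

#' Most frequently reported events for a drug
#'
#' PTs ranked by the number of distinct reports mentioning them,
#' descending, ties broken alphabetically by PT.
#'
#' @param reports a drug-selected `report_set`.
#' @param k number of PTs to return (the full ranking if fewer exist).
#' @return data.table with columns `pt`, `count`.
#' @export
top_events <- function(reports, k = 10L) {
  reac <- unique(data.table::data.table(primaryid = reports$reac$primaryid,
                                        pt = reports$reac$pt))
  if (nrow(reac) == 0L)
    return(data.table::data.table(pt = character(0), count = integer(0)))
  cnt <- reac[, .(count = .N), by = pt]
  data.table::setorder(cnt, -count, pt)
  utils::head(cnt, k)[]
}

#' Daily-dose bins as half-open ranges
#' @param breaks increasing numeric cut points; bins are `(low, high]`
#'   (half-open on the left), with an implicit `<= breaks[1]` first bin
#'   and `> breaks[length(breaks)]` last bin.
#' @return a dose-bin specification for [dose_strata_counts()].
#' @export
dose_bins_ranges <- function(breaks = c(100, 200, 400)) {
  stopifnot(is.numeric(breaks), !is.unsorted(breaks, strictly = TRUE))
  structure(list(type = "ranges", breaks = breaks), class = "dose_bins")
}

#' Daily-dose bins as exact titration doses
#' @param values the exact daily doses (mg) that define the bins, e.g. the
#'   cenobamate titration steps `c(12.5, 25, 50, 100, 150)`.
#' @return a dose-bin specification for [dose_strata_counts()].
#' @export
dose_bins_exact <- function(values = c(12.5, 25, 50, 100, 150)) {
  structure(list(type = "exact", values = values), class = "dose_bins")
}

#' Adverse-event report counts by daily-dose stratum
#'
#' Counts adult reports (age `>= 18`) with a parseable daily dose in each
#' bin. Range bins are half-open on the left, `(low, high]`, so a 200 mg
#' dose falls in the 100-200 bin. A report with several dose entries for
#' the drug contributes its maximum daily dose.
#'
#' @param reports a drug-selected `report_set`.
#' @param bins a [dose_bins_ranges()] or [dose_bins_exact()] specification.
#' @return data.table with columns `bin`, `count`; unparseable-dose adult
#'   reports are tallied in attribute `"unparsed_dose"`.
#' @export
dose_strata_counts <- function(reports, bins) {
  stopifnot(inherits(bins, "dose_bins"))
  demo <- reports$demo
  adults <- demo$primaryid[!is.na(demo$age_years) & demo$age_years >= 18]
  dr <- reports$drug[primaryid %in% adults]
  dose <- dr[, .(daily_dose_mg = suppressWarnings(max(daily_dose_mg, na.rm = TRUE))),
             by = primaryid]
  dose[!is.finite(daily_dose_mg), daily_dose_mg := NA_real_]
  unparsed <- sum(is.na(dose$daily_dose_mg))
  x <- dose$daily_dose_mg[!is.na(dose$daily_dose_mg)]

  if (bins$type == "ranges") {
    br <- bins$breaks
    labels <- c(sprintf("<=%g", br[1]),
                if (length(br) > 1)
                  sprintf("%g-%g", br[-length(br)], br[-1]),
                sprintf(">%g", br[length(br)]))
    idx <- findInterval(x, br, left.open = TRUE) + 1L  # (low, high] bins
    cnt <- vapply(seq_along(labels), function(i) sum(idx == i), integer(1))
    out <- data.table::data.table(bin = labels, count = cnt)
  } else {
    labels <- sprintf("%g mg", bins$values)
    cnt <- vapply(bins$values, function(v) sum(x == v), integer(1))
    out <- data.table::data.table(bin = labels, count = cnt)
  }
  data.table::setattr(out, "unparsed_dose", unparsed)
  out[]
}

#' Compare the signal sets of two drugs
#'
#' Takes per-drug PT-level disproportionality results (rows flagged
#' `is_signal`), forms their union, marks the PTs signalled by both drugs,
#' and derives the plot-ready exports: a forest table (ROR with interval,
#' shared signals only) and a Sankey edge list (drug -> PT and PT -> SOC,
#' weighted by report counts).
#'
#' @param results_a,results_b data.tables from [dispro_analysis()] for the
#'   two drugs (PT-level rows are used).
#' @return list of data.tables: `comparison` (one row per signalled PT,
#'   per-drug statistics side by side, logical `shared`), `forest`
#'   (`pt`, `drug`, `ror`, `ci_low`, `ci_high`), `sankey`
#'   (`from`, `to`, `weight`).
#' @export
compare_signals <- function(results_a, results_b) {
  pick <- function(res) {
    res <- data.table::as.data.table(res)
    res[level == "PT" & is_signal == TRUE]
  }
  sa <- pick(results_a)
  sb <- pick(results_b)
  pts <- sort(union(sa$event, sb$event))

  one <- function(s, pts) {
    s[match(pts, s$event),
      .(soc, a, prr, chi2, ror, ror_ci_low, ror_ci_high, e_ic, ic_minus_2sd)]
  }
  da <- one(sa, pts)
  db <- one(sb, pts)
  lab_a <- if (nrow(sa) > 0L) sa$drug[1] else "drug_a"
  lab_b <- if (nrow(sb) > 0L) sb$drug[1] else "drug_b"
  soc <- ifelse(is.na(da$soc), db$soc, da$soc)
  comparison <- data.table::data.table(soc = soc, pt = pts)
  for (nm in setdiff(names(da), "soc")) {
    data.table::set(comparison, j = paste0(lab_a, "_", nm), value = da[[nm]])
    data.table::set(comparison, j = paste0(lab_b, "_", nm), value = db[[nm]])
  }
  data.table::set(comparison, j = "shared",
                  value = pts %in% intersect(sa$event, sb$event))

  shared_pts <- pts[comparison$shared]
  forest <- data.table::rbindlist(lapply(list(sa, sb), function(s) {
    s[event %in% shared_pts,
      .(pt = event, drug = drug, ror = ror, ci_low = ror_ci_low,
        ci_high = ror_ci_high)]
  }))

  sankey <- data.table::rbindlist(list(
    data.table::rbindlist(lapply(list(sa, sb), function(s)
      s[, .(from = drug, to = event, weight = a)])),
    data.table::rbindlist(lapply(list(sa, sb), function(s)
      s[, .(from = event, to = soc, weight = a)]))
  ))
  sankey <- sankey[, .(weight = sum(weight)), by = .(from, to)]

  list(comparison = comparison[], forest = forest[], sankey = sankey[])
}

#' Count strong signals for a drug
#'
#' A strong signal has `IC - 2SD` at or above the threshold (default 1.0
#' bit). Accepts either fixture rows ([read_signal_fixture()]) or computed
#' results ([dispro_analysis()]), i.e. anything with `drug` and
#' `ic_minus_2sd` columns.
#'
#' @param rows data.frame with columns `drug` and `ic_minus_2sd` (and
#'   optionally `level`, in which case only PT rows are counted).
#' @param drug drug label to count.
#' @param threshold inclusive IC-2SD cut, in bits.
#' @return integer count.
#' @examples
#' count_strong_signals(read_signal_fixture(), "cenobamate") # 55
#' @export
count_strong_signals <- function(rows, drug, threshold = 1.0) {
  rows <- data.table::as.data.table(rows)
  if (nrow(rows) == 0L) return(0L)
  if ("level" %in% names(rows)) rows <- rows[level == "PT"]
  sum(rows$drug == drug & !is.na(rows$ic_minus_2sd) &
        rows$ic_minus_2sd >= threshold)
}
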