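#' Deduplicate reports by the FDA case rule
#'
#' FAERS cases accumulate multiple report versions under one CASEID. The
#' FDA deduplication rule keeps, per CASEID, the report with the highest
#' FDA_DT; ties on FDA_DT are broken by the largest PRIMARYID. Both
#' comparisons are numeric. Reports missing any of the three keys cannot be
#' deduplicated and are routed to the rejects rather than silently kept.
#' Survivors keep their relative input order, so the result is independent
#' of any permutation of the input.
#'
#' @param reports a `report_set` (see [report_set()]).
#' @return list with elements `reports` (deduplicated `report_set`),
#'   `removed` (number of duplicate versions dropped) and `rejects`
#'   (`demo` rows with incomplete keys).
#' @examples
#' demo <- data.table::data.table(
#'   primaryid = c(1, 2), caseid = c(9, 9), fda_dt = c(20230101, 20230301),
#'   sex = "unknown", age_years = NA_real_, country = NA_character_)
#' deduplicate(report_set(demo))$reports$demo$primaryid # 2
#' @export
deduplicate <- function(reports) {
  stopifnot(inherits(reports, "report_set"))
  demo <- reports$demo
  complete <- !is.na(demo$caseid) & !is.na(demo$fda_dt) & !is.na(demo$primaryid)
  rejects <- demo[!complete]
  d <- demo[complete]
  if (nrow(d) == 0L) {
    out <- subset_report_set(reports, numeric(0))
    return(list(reports = out, removed = 0L, rejects = rejects))
  }
  dd <- data.table::data.table(caseid = d$caseid, fda_dt = d$fda_dt,
                               primaryid = d$primaryid, orig = seq_len(nrow(d)))
  data.table::setorder(dd, fda_dt, primaryid)
  surv <- dd[, .(orig = orig[.N]), by = caseid]$orig
  surv_ids <- d$primaryid[sort(surv)]
  out <- subset_report_set(reports, surv_ids)
  list(reports = out,
       removed = nrow(d) - length(surv_ids),
       rejects = rejects)
}
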