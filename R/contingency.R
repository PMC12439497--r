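# Report-level 2x2 contingency tables. The counting unit is the unique
# deduplicated report: a report contributes at most 1 to cell `a` no matter
# how many matching drug entries or PT rows it carries. The background
# (c, d) is every analysed report not listing the target drug, within
# whatever report universe was ingested.

#' Build one 2x2 contingency table
#'
#' @param reports a deduplicated, indication-excluded `report_set` — the
#'   analysis universe defining `N = a+b+c+d`.
#' @param drug canonical target drug.
#' @param event PT string (`level = "PT"`) or SOC label (`level = "SOC"`).
#' @param level counting level; at SOC level a report carries the event if
#'   any of its PTs maps to that SOC.
#' @param dict a [drug_dictionary()].
#' @param vocab a [vocab_map()]; required for `level = "SOC"`.
#' @param roles admitted drug role codes, see [drug_report_ids()].
#' @return an object of class `contingency_table`: list with counts `a`,
#'   `b`, `c`, `d` plus `drug`, `event`, `level`, `counting_unit`.
#' @export
build_table <- function(reports, drug, event, level = c("PT", "SOC"),
                        dict, vocab = NULL, roles = c("PS", "SS")) {
  level <- match.arg(level)
  N <- n_reports(reports)
  if (N == 0L) stop_faersig("build_table: empty report universe")
  A <- drug_report_ids(reports, drug, dict, roles)
  reac <- reports$reac
  E <- if (level == "PT") {
    unique(reac$primaryid[norm_str(reac$pt) == norm_str(event)])
  } else {
    if (is.null(vocab)) stop_faersig("build_table: SOC level requires a vocab")
    unique(reac$primaryid[map_pt_to_soc(reac$pt, vocab) == event])
  }
  a <- length(intersect(A, E))
  contingency_table(a = a, b = length(A) - a, c = length(E) - a,
                    d = N - length(A) - length(E) + a,
                    drug = drug, event = event, level = level)
}

#' Construct a 2x2 contingency table object
#'
#' @param a,b,c,d non-negative report counts: target drug & event, target
#'   drug & other events, other reports with the event, neither.
#' @param drug,event,level labels carried along for reporting.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, drug = NA_character_,
                              event = NA_character_, level = "PT") {
  if (any(c(a, b, c, d) < 0)) stop_faersig("contingency_table: negative cell count")
  structure(list(a = a, b = b, c = c, d = d, drug = drug, event = event,
                 level = level, counting_unit = "report"),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s / %s (%s), report-level\n",
              x$drug, x$event, x$level))
  print(matrix(c(x$a, x$c, x$b, x$d), 2, 2,
               dimnames = list(c("drug", "other"), c("event", "no event"))))
  invisible(x)
}

#' Build every 2x2 table for one drug
#'
#' One table per PT observed among the drug's reports (there are no `a = 0`
#' PT tables by construction) and, when a vocabulary is given, one per SOC.
#'
#' @inheritParams build_table
#' @param levels which levels to emit.
#' @return data.table with one row per table: `drug`, `event`, `level`,
#'   `soc` (SOC of a PT row, or the SOC itself), `a`, `b`, `c`, `d`.
#' @export
build_all_tables <- function(reports, drug, dict, vocab = NULL,
                             roles = c("PS", "SS"), levels = c("PT", "SOC")) {
  N <- n_reports(reports)
  if (N == 0L) stop_faersig("build_all_tables: empty report universe")
  A <- drug_report_ids(reports, drug, dict, roles)
  nA <- length(A)
  reac <- unique(data.table::data.table(primaryid = reports$reac$primaryid,
                                        pt_lc = norm_str(reports$reac$pt),
                                        pt = reports$reac$pt))
  reac <- unique(reac, by = c("primaryid", "pt_lc"))
  out <- list()

  if ("PT" %in% levels) {
    tot <- reac[, .(n_ev = .N), by = .(pt_lc, pt)]
    ina <- reac[primaryid %in% A, .(a = .N), by = pt_lc]
    tab <- merge(tot, ina, by = "pt_lc")
    if (nrow(tab) > 0L) {
      pt_dt <- data.table::data.table(
        drug = drug, event = tab$pt, level = "PT",
        soc = if (is.null(vocab)) NA_character_ else map_pt_to_soc(tab$pt, vocab),
        a = tab$a, b = nA - tab$a, c = tab$n_ev - tab$a,
        d = N - nA - (tab$n_ev - tab$a))
      out <- c(out, list(pt_dt))
    }
  }

  if ("SOC" %in% levels && !is.null(vocab)) {
    rs <- unique(data.table::data.table(primaryid = reac$primaryid,
                                        soc = map_pt_to_soc(reac$pt, vocab)))
    tot <- rs[, .(n_ev = .N), by = soc]
    ina <- rs[primaryid %in% A, .(a = .N), by = soc]
    tab <- merge(tot, ina, by = "soc")
    if (nrow(tab) > 0L) {
      soc_dt <- data.table::data.table(
        drug = drug, event = tab$soc, level = "SOC", soc = tab$soc,
        a = tab$a, b = nA - tab$a, c = tab$n_ev - tab$a,
        d = N - nA - (tab$n_ev - tab$a))
      out <- c(out, list(soc_dt))
    }
  }

  if (length(out) == 0L)
    return(data.table::data.table(drug = character(0), event = character(0),
                                  level = character(0), soc = character(0),
                                  a = integer(0), b = integer(0),
                                  c = integer(0), d = integer(0)))
  res <- data.table::rbindlist(out)
  data.table::setorder(res, level, event)
  res[]
}
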