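# Drug-name normalisation and MedDRA PT -> SOC mapping.
#
# FAERS verbatim drug names carry dose/form noise ("VIMPAT 100MG TABLETS"),
# so matching is: case-fold, trim, split on whitespace/punctuation, and a
# synonym matches when its token sequence equals the leading tokens of the
# verbatim name; trailing tokens are ignored.

#' Build a drug synonym dictionary
#'
#' @param entries named list: canonical drug name -> character vector of
#'   synonyms (generic and brand names). Synonyms are stored case-folded;
#'   a synonym shared by two canonical drugs violates the dictionary
#'   invariant and errors.
#' @return an object of class `drug_dictionary`.
#' @examples
#' drug_dictionary(list(cenobamate = c("cenobamate", "xcopri")))
#' @export
drug_dictionary <- function(entries) {
  stopifnot(is.list(entries), !is.null(names(entries)))
  entries <- lapply(entries, function(s) unique(norm_str(s)))
  all_syn <- unlist(entries, use.names = FALSE)
  if (anyDuplicated(all_syn)) {
    dup <- all_syn[duplicated(all_syn)][1L]
    stop_faersig("drug dictionary: synonym '%s' maps to more than one canonical drug", dup)
  }
  structure(list(entries = entries,
                 tokens = lapply(entries, function(s) lapply(s, drug_tokens))),
            class = "drug_dictionary")
}

#' @export
print.drug_dictionary <- function(x, ...) {
  cat("<drug_dictionary>\n")
  for (nm in names(x$entries))
    cat(sprintf("  %s: %s\n", nm, paste(x$entries[[nm]], collapse = ", ")))
  invisible(x)
}

#' Read a drug dictionary from TSV
#'
#' Two tab-separated columns, `canonical<TAB>synonym`, one synonym per line.
#'
#' @param path TSV path; defaults to the bundled dictionary covering
#'   cenobamate (Xcopri, Motpoly XR) and lacosamide (Vimpat).
#' @return a `drug_dictionary`.
#' @export
read_drug_dictionary <- function(path = faersig_example("drug_dictionary.tsv")) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("canonical", "synonym"))
  drug_dictionary(split(x$synonym, x$canonical))
}

drug_tokens <- function(x) {
  toks <- strsplit(gsub("[^a-z0-9.]+", " ", norm_str(x)), " ", fixed = TRUE)[[1L]]
  toks[nzchar(toks)]
}

#' Normalise verbatim drug names to canonical study drugs
#'
#' @param raw character vector of verbatim `drugname`/`prod_ai` strings.
#' @param dict a [drug_dictionary()].
#' @return character vector: canonical drug name, or `NA` where no synonym
#'   matches. A verbatim name matching synonyms of two canonical drugs is
#'   an error (ambiguous dictionary).
#' @examples
#' d <- read_drug_dictionary()
#' normalize_drug_name(c("XCOPRI", "VIMPAT 100MG TABLETS", "aspirin"), d)
#' @export
normalize_drug_name <- function(raw, dict) {
  stopifnot(inherits(dict, "drug_dictionary"))
  u <- unique(raw)
  res <- vapply(u, function(nm) {
    toks <- drug_tokens(nm)
    hits <- character(0)
    for (canon in names(dict$tokens)) {
      for (syn in dict$tokens[[canon]]) {
        k <- length(syn)
        if (k > 0L && length(toks) >= k && identical(toks[seq_len(k)], syn)) {
          hits <- c(hits, canon)
          break
        }
      }
    }
    hits <- unique(hits)
    if (length(hits) > 1L)
      stop_faersig("ambiguous drug name '%s' matches: %s", nm,
                   paste(hits, collapse = ", "))
    if (length(hits) == 1L) hits else NA_character_
  }, character(1))
  unname(res[match(raw, u)])
}

#' Report primaryids listing a drug in an admitted role
#'
#' @param reports a `report_set`.
#' @param drug canonical drug name.
#' @param dict a [drug_dictionary()].
#' @param roles admitted FAERS role codes; the default `c("PS","SS")`
#'   (primary/secondary suspect) is the usual pharmacovigilance convention,
#'   widen to `c("PS","SS","C","I")` to include concomitant/interacting.
#' @return numeric vector of primaryids.
#' @export
drug_report_ids <- function(reports, drug, dict, roles = c("PS", "SS")) {
  dtab <- reports$drug
  if (nrow(dtab) == 0L) return(numeric(0))
  canon <- normalize_drug_name(dtab$drugname, dict)
  unique(dtab$primaryid[!is.na(canon) & canon == drug &
                          !is.na(dtab$role) & dtab$role %in% roles])
}

#' Select the reports mentioning a target drug
#'
#' Selections for different drugs are independent: a report listing both
#' study drugs appears in both selections (and is therefore counted twice
#' by their union).
#'
#' @inheritParams drug_report_ids
#' @return a `report_set` restricted to the matching reports.
#' @export
select_reports <- function(reports, drug, dict, roles = c("PS", "SS")) {
  subset_report_set(reports, drug_report_ids(reports, drug, dict, roles))
}

#' Exclude indication terms from each report's events
#'
#' Removes from every report's event set the PTs that the same report lists
#' as drug indications (exact PT string match after case-folding) — the
#' treated disease is not an adverse event. Reports left with no events
#' (including reports that had none to begin with) can contribute no
#' drug-event pair and are dropped from the analysis universe.
#'
#' @param reports a `report_set`.
#' @return list with `reports` (the filtered `report_set`) and `dropped`
#'   (number of reports removed because their event set became empty).
#' @export
exclude_indications <- function(reports) {
  stopifnot(inherits(reports, "report_set"))
  reac <- reports$reac
  indi <- reports$indi
  if (nrow(reac) > 0L && nrow(indi) > 0L) {
    key <- paste(reac$primaryid, norm_str(reac$pt), sep = "\r")
    ikey <- paste(indi$primaryid, norm_str(indi$pt), sep = "\r")
    reac <- reac[!(key %in% ikey)]
  }
  keep_ids <- unique(reac$primaryid)
  dropped <- nrow(reports$demo) - sum(reports$demo$primaryid %in% keep_ids)
  out <- subset_report_set(reports, keep_ids)
  out$reac <- reac[primaryid %in% out$demo$primaryid]
  list(reports = out, dropped = dropped)
}

#' Read a PT to SOC vocabulary
#'
#' MedDRA itself is licensed and cannot be redistributed; the vocabulary is
#' therefore a user-supplied two-column TSV (`pt<TAB>soc`, no header). The
#' bundled demo vocabulary covers every PT used by the bundled fixture and
#' the synthetic generator.
#'
#' @param path TSV path; defaults to the bundled demo vocabulary.
#' @return an object of class `vocab_map` (named character vector,
#'   case-folded PT -> SOC).
#' @export
read_vocab <- function(path = faersig_example("demo_vocab.tsv")) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("pt", "soc"), quote = "")
  vocab_map(stats::setNames(x$soc, x$pt))
}

#' Construct a PT to SOC vocabulary map
#' @param mapping named character vector, PT name -> SOC name.
#' @return an object of class `vocab_map`.
#' @export
vocab_map <- function(mapping) {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  names(mapping) <- norm_str(names(mapping))
  if (anyDuplicated(names(mapping)))
    stop_faersig("vocab: PT '%s' mapped twice", names(mapping)[duplicated(names(mapping))][1L])
  structure(mapping, class = "vocab_map")
}

#' Map preferred terms to system organ classes
#'
#' @param pt character vector of PT strings (matched case-insensitively).
#' @param vocab a [vocab_map()].
#' @return character vector of SOC names; PTs absent from the vocabulary
#'   are routed to the explicit `"unmapped"` bucket.
#' @export
map_pt_to_soc <- function(pt, vocab) {
  stopifnot(inherits(vocab, "vocab_map"))
  soc <- unclass(vocab)[norm_str(pt)]
  soc[is.na(soc)] <- "unmapped"
  unname(soc)
}
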