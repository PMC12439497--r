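# FAERS quarterly ASCII dialect: dollar-delimited records with a header line
# and no quoting (the public distribution never quotes). Column names are
# matched case-insensitively; columns beyond the required set pass through.

FAERS_TABLE_KINDS <- c("DEMO", "DRUG", "REAC", "OUTC", "THER", "INDI")

# minimal required columns per table kind (lowercase)
faers_required_cols <- list(
  DEMO = c("primaryid", "caseid", "fda_dt"),
  DRUG = c("primaryid", "drugname"),
  REAC = c("primaryid", "pt"),
  OUTC = c("primaryid", "outc_cod"),
  THER = c("primaryid"),
  INDI = c("primaryid", "indi_pt")
)

# FDA outcome codes of the OUTC table -> outcome labels used in baseline
# tables (Death / Disability / Life-threatening / Hospitalization / Other)
OUTCOME_CODES <- c(
  DE = "death", DS = "disability", LT = "life_threatening",
  HO = "hospitalization", OT = "other"
)

#' Read one FAERS quarterly ASCII table
#'
#' Parses a dollar-delimited FAERS table (header line naming columns, one
#' record per line, empty string meaning missing). All values are returned
#' as character; typing happens in [assemble_reports()].
#'
#' @param path path to a `.txt` FAERS table file.
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`,
#'   `"THER"`, `"INDI"`.
#' @return a `data.table` of character columns, names lowercased, row order
#'   as in the file.
#' @seealso [write_faers_table()], [assemble_reports()]
#' @export
read_faers_table <- function(path, table_kind) {
  table_kind <- match.arg(toupper(table_kind), FAERS_TABLE_KINDS)
  if (!file.exists(path)) stop_faersig("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop_faersig("%s: empty file, no header line", path)
  header <- tolower(strsplit(lines[1L], "$", fixed = TRUE)[[1L]])
  missing_cols <- setdiff(faers_required_cols[[table_kind]], header)
  if (length(missing_cols) > 0L) {
    stop_faersig("%s: malformed %s header, missing column '%s'",
                 path, table_kind, missing_cols[1L],
                 class = "faersig_format_error")
  }
  body <- lines[-1L]
  if (length(body) > 0L && !nzchar(body[length(body)]))
    body <- body[-length(body)]  # tolerate a trailing blank line
  if (length(body) == 0L) {
    out <- data.table::as.data.table(
      stats::setNames(rep(list(character(0)), length(header)), header))
    return(out[])
  }
  # no quoting in the dialect, so field count is delimiter count + 1
  # (strsplit drops trailing empty fields; pad after the count check)
  nfields <- nchar(body) - nchar(gsub("$", "", body, fixed = TRUE)) + 1L
  wrong <- which(nfields != length(header))
  if (length(wrong) > 0L) {
    stop_faersig("%s: record on line %d has %d fields, expected %d",
                 path, wrong[1L] + 1L, nfields[wrong[1L]], length(header),
                 class = "faersig_format_error")
  }
  parts <- strsplit(body, "$", fixed = TRUE)
  parts <- lapply(parts, function(p) c(p, rep("", length(header) - length(p))))
  out <- data.table::as.data.table(
    stats::setNames(lapply(seq_along(header), function(j)
      vapply(parts, `[[`, character(1), j)), header))
  out[]
}

#' Write a table in the FAERS ASCII dialect
#'
#' Inverse of [read_faers_table()]: header line of dollar-joined column
#' names, then one dollar-joined record per row. `NA` is written as the
#' empty string. Values must not contain the `$` delimiter.
#'
#' @param x data.frame/data.table to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(x, path) {
  x <- data.table::as.data.table(x)
  cols <- lapply(x, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })
  if (any(vapply(cols, function(col) any(grepl("$", col, fixed = TRUE)), logical(1))))
    stop_faersig("values must not contain the '$' delimiter")
  lines <- c(paste(names(x), collapse = "$"),
             if (nrow(x)) do.call(paste, c(cols, sep = "$")))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble per-report records from raw FAERS tables
#'
#' Joins the DEMO/DRUG/REAC/OUTC/INDI/THER tables on PRIMARYID into a
#' relational `report_set` (one report per DEMO row). Typing rules:
#' PRIMARYID/CASEID/FDA_DT numeric (a DEMO row with a non-numeric PRIMARYID
#' is routed to the rejects, not fatal); sex `F`/`M` to `female`/`male`,
#' anything else `unknown`; age interpreted only when the unit code is
#' years (`YR`, empty, `YEAR`, `YRS`), otherwise missing; OUTC codes
#' DE/DS/LT/HO/OT mapped to outcome labels, anything else `unknown`;
#' `dose_amt` read as a daily dose in mg when `dose_unit` is `MG` or empty.
#' Child rows whose PRIMARYID matches no DEMO row are counted as orphans
#' and dropped.
#'
#' @param tables named list of character data.tables as returned by
#'   [read_faers_table()]; `DEMO` is required, the rest optional.
#' @return a `report_set` (list of data.tables `demo`, `drug`, `reac`,
#'   `outc`, `indi`) with attribute `rejects`: a list with `demo_rejects`
#'   (malformed DEMO rows) and `orphans` (named count of dropped child
#'   rows per table).
#' @export
assemble_reports <- function(tables) {
  names(tables) <- toupper(names(tables))
  if (is.null(tables$DEMO)) stop_faersig("assemble_reports: DEMO table is required")
  demo_raw <- data.table::as.data.table(tables$DEMO)

  pid <- suppressWarnings(as.numeric(demo_raw$primaryid))
  bad <- is.na(pid)
  demo_rejects <- demo_raw[bad]
  demo_raw <- demo_raw[!bad]
  pid <- pid[!bad]

  get_col <- function(dt, nm) if (nm %in% names(dt)) dt[[nm]] else rep("", nrow(dt))
  sex_raw <- toupper(trimws(get_col(demo_raw, "sex")))
  sex <- ifelse(sex_raw == "F", "female", ifelse(sex_raw == "M", "male", "unknown"))
  age_cod <- toupper(trimws(get_col(demo_raw, "age_cod")))
  age <- suppressWarnings(as.numeric(get_col(demo_raw, "age")))
  age[!(age_cod %in% c("", "YR", "YEAR", "YRS")) | age < 0] <- NA_real_
  country <- trimws(get_col(demo_raw, "occr_country"))
  country[country == ""] <- NA_character_

  demo <- data.table::data.table(
    primaryid = pid,
    caseid = suppressWarnings(as.numeric(demo_raw$caseid)),
    fda_dt = suppressWarnings(as.numeric(demo_raw$fda_dt)),
    sex = sex, age_years = age, country = country
  )

  orphans <- c(DRUG = 0L, REAC = 0L, OUTC = 0L, INDI = 0L, THER = 0L)
  known <- demo$primaryid

  child <- function(kind) {
    t <- tables[[kind]]
    if (is.null(t) || nrow(t) == 0L) return(NULL)
    t <- data.table::as.data.table(t)
    cpid <- suppressWarnings(as.numeric(t$primaryid))
    keep <- !is.na(cpid) & cpid %in% known
    orphans[[kind]] <<- sum(!keep)
    list(dt = t[keep], pid = cpid[keep])
  }

  dr <- child("DRUG")
  drug <- if (is.null(dr)) {
    data.table::data.table(primaryid = numeric(0), drugname = character(0),
                           role = character(0), daily_dose_mg = numeric(0))
  } else {
    unit <- toupper(trimws(get_col(dr$dt, "dose_unit")))
    amt <- suppressWarnings(as.numeric(get_col(dr$dt, "dose_amt")))
    amt[!(unit %in% c("", "MG")) | amt < 0] <- NA_real_
    role <- toupper(trimws(get_col(dr$dt, "role_cod")))
    role[!(role %in% c("PS", "SS", "C", "I"))] <- NA_character_
    data.table::data.table(primaryid = dr$pid, drugname = dr$dt$drugname,
                           role = role, daily_dose_mg = amt)
  }

  re <- child("REAC")
  reac <- if (is.null(re)) {
    data.table::data.table(primaryid = numeric(0), pt = character(0))
  } else {
    dt <- data.table::data.table(primaryid = re$pid, pt = trimws(re$dt$pt))
    unique(dt[nzchar(pt)])
  }

  ou <- child("OUTC")
  outc <- if (is.null(ou)) {
    data.table::data.table(primaryid = numeric(0), outcome = character(0))
  } else {
    code <- toupper(trimws(ou$dt$outc_cod))
    lab <- OUTCOME_CODES[code]
    lab[is.na(lab)] <- "unknown"
    unique(data.table::data.table(primaryid = ou$pid, outcome = unname(lab)))
  }

  ind <- child("INDI")
  indi <- if (is.null(ind)) {
    data.table::data.table(primaryid = numeric(0), pt = character(0))
  } else {
    dt <- data.table::data.table(primaryid = ind$pid, pt = trimws(ind$dt$indi_pt))
    unique(dt[nzchar(pt)])
  }

  invisible(child("THER"))  # parsed for orphan accounting only

  rs <- report_set(demo = demo, drug = drug, reac = reac, outc = outc, indi = indi)
  attr(rs, "rejects") <- list(demo_rejects = demo_rejects, orphans = orphans)
  rs
}

#' Construct a report set
#'
#' A `report_set` is the package's relational container for deduplicated (or
#' not-yet-deduplicated) safety reports: one `demo` row per report, with
#' child tables joined by `primaryid`. It is the unit every analysis stage
#' consumes and returns.
#'
#' @param demo data.table with columns `primaryid`, `caseid`, `fda_dt`,
#'   `sex`, `age_years`, `country`.
#' @param drug data.table `primaryid`, `drugname`, `role`, `daily_dose_mg`.
#' @param reac data.table `primaryid`, `pt`.
#' @param outc data.table `primaryid`, `outcome`.
#' @param indi data.table `primaryid`, `pt`.
#' @return an object of class `report_set`.
#' @export
report_set <- function(demo,
                       drug = data.table::data.table(primaryid = numeric(0), drugname = character(0), role = character(0), daily_dose_mg = numeric(0)),
                       reac = data.table::data.table(primaryid = numeric(0), pt = character(0)),
                       outc = data.table::data.table(primaryid = numeric(0), outcome = character(0)),
                       indi = data.table::data.table(primaryid = numeric(0), pt = character(0))) {
  demo <- data.table::as.data.table(demo)
  if (anyDuplicated(demo$primaryid)) stop_faersig("report_set: duplicated primaryid in demo")
  structure(list(demo = demo,
                 drug = data.table::as.data.table(drug),
                 reac = data.table::as.data.table(reac),
                 outc = data.table::as.data.table(outc),
                 indi = data.table::as.data.table(indi)),
            class = "report_set")
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d reports, %d drug rows, %d event rows\n",
              nrow(x$demo), nrow(x$drug), nrow(x$reac)))
  invisible(x)
}

#' Number of reports in a report set
#' @param x a `report_set`.
#' @return integer count of reports (DEMO rows).
#' @export
n_reports <- function(x) nrow(x$demo)

# keep only the given primaryids, in demo order
subset_report_set <- function(x, primaryids) {
  keep <- x$demo$primaryid %in% primaryids
  demo <- x$demo[keep]
  ids <- demo$primaryid
  structure(list(demo = demo,
                 drug = x$drug[primaryid %in% ids],
                 reac = x$reac[primaryid %in% ids],
                 outc = x$outc[primaryid %in% ids],
                 indi = x$indi[primaryid %in% ids]),
            class = "report_set")
}

#' Read the bundled two-drug signal fixture
#'
#' Loads a CSV of published signal rows (one row per preferred term and
#' drug with non-missing statistics; cells printed as "/" in the source
#' table simply have no row). Validates the transcription: `n >= 6`,
#' lower ROR bound below the ROR, IC-2SD below the IC, and known drug
#' labels.
#'
#' @param path CSV path; defaults to the bundled fixture.
#' @return data.table with columns `soc`, `pt`, `drug`, `n`, `prr`,
#'   `chi2`, `ror`, `ror_ci025`, `ic`, `ic_minus_2sd`.
#' @export
read_signal_fixture <- function(path = faersig_example("table5_signals.csv")) {
  x <- data.table::as.data.table(utils::read.csv(path, check.names = FALSE,
                                                 stringsAsFactors = FALSE))
  need <- c("soc", "pt", "drug", "n", "prr", "chi2", "ror", "ror_ci025",
            "ic", "ic_minus_2sd")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L)
    stop_faersig("signal fixture: missing column '%s'", missing_cols[1L])
  if (!all(x$drug %in% c("lacosamide", "cenobamate")))
    stop_faersig("signal fixture: unknown drug label '%s'",
                 setdiff(unique(x$drug), c("lacosamide", "cenobamate"))[1L])
  bad <- which(x$n < 6)
  if (length(bad) > 0L)
    stop_faersig("signal fixture row %d (%s, %s): n = %d violates n >= 6",
                 bad[1L], x$pt[bad[1L]], x$drug[bad[1L]], x$n[bad[1L]])
  bad <- which(!(x$ror_ci025 < x$ror))
  if (length(bad) > 0L)
    stop_faersig("signal fixture row %d (%s): ror_ci025 >= ror", bad[1L], x$pt[bad[1L]])
  bad <- which(!(x$ic_minus_2sd < x$ic))
  if (length(bad) > 0L)
    stop_faersig("signal fixture row %d (%s): ic_minus_2sd >= ic", bad[1L], x$pt[bad[1L]])
  x[]
}

#' Path to a bundled example/fixture file
#' @param file file name under the package's `extdata/`; with no argument,
#'   lists available files.
#' @return full path (or a character vector of file names).
#' @export
faersig_example <- function(file = NULL) {
  if (is.null(file)) return(dir(system.file("extdata", package = "faersig")))
  p <- system.file("extdata", file, package = "faersig")
  if (p == "") stop_faersig("no bundled file '%s'", file)
  p
}
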