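# Synthetic FAERS-dialect generator. The stated world it emulates: a
# spontaneous-report stream where each report carries one or more drugs,
# events drawn independently given the drug set with per-(drug, event)
# reporting-rate ratios as planted ground truth, demographics with heavy
# missingness (real baseline tables show sex/age unknown for most reports
# of a newly marketed drug), duplicate CASEID versions, outcome codes and
# daily-dose fields.

#' Synthetic generator configuration
#'
#' @param n_reports number of unique reports (cases) to generate.
#' @param drugs data.frame with columns `name` (canonical), `marginal`
#'   (probability a report lists the drug), and optionally `synonyms`
#'   (list-column of verbatim templates) and `doses` (list-column of daily
#'   doses in mg to sample from). Defaults: the two study drugs at
#'   marginals 0.10 and 0.05, verbatim names carrying brand and dose/form
#'   noise, lacosamide doses 50-600 mg, cenobamate titration doses with
#'   the 12.5 mg start dominant.
#' @param events data.frame with columns `pt`, `soc`, `base_rate`
#'   (per-report probability in a background report). Default: 20 PTs
#'   drawn from the bundled demo vocabulary with base rates 0.005-0.05.
#' @param rr data.frame with columns `drug`, `pt`, `rr`: planted relative
#'   reporting-rate ratios (unlisted pairs have rr = 1). The event
#'   probability for a report is `base_rate * max(rr over the report's
#'   drugs)`, truncated at 1 — but a product above 1 at config time is a
#'   config error naming the pair.
#' @param duplicate_fraction fraction of cases additionally emitted as an
#'   extra report version sharing the CASEID, with FDA_DT perturbed upward
#'   and a larger PRIMARYID so the intended survivor is the last version.
#' @param missingness named list of per-field missing probabilities:
#'   `sex`, `age`, `country`, `dose`.
#' @param seed integer RNG seed; the generator is deterministic given the
#'   config.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 50000,
                             drugs = default_synthetic_drugs(),
                             events = default_synthetic_events(),
                             rr = NULL,
                             duplicate_fraction = 0.1,
                             missingness = list(sex = 0.3, age = 0.45,
                                                country = 0.1, dose = 0.5),
                             seed = 1L) {
  drugs <- data.table::as.data.table(drugs)
  events <- data.table::as.data.table(events)
  if (n_reports < 1) stop_faersig("synthetic_config: n_reports must be >= 1")
  if (any(drugs$marginal < 0 | drugs$marginal > 1))
    stop_faersig("synthetic_config: drug marginals must lie in [0, 1]")
  if (any(events$base_rate < 0 | events$base_rate > 1))
    stop_faersig("synthetic_config: event base rates must lie in [0, 1]")
  miss <- unlist(missingness)
  if (any(miss < 0 | miss > 1))
    stop_faersig("synthetic_config: missingness probabilities must lie in [0, 1]")
  if (duplicate_fraction < 0 || duplicate_fraction > 1)
    stop_faersig("synthetic_config: duplicate_fraction must lie in [0, 1]")
  if (is.null(rr)) {
    rr <- data.table::data.table(drug = character(0), pt = character(0),
                                 rr = numeric(0))
  } else {
    rr <- data.table::as.data.table(rr)
    if (any(!is.finite(rr$rr) | rr$rr < 0))
      stop_faersig("synthetic_config: rr values must be finite and >= 0")
    br <- events$base_rate[match(rr$pt, events$pt)]
    over <- which(!is.na(br) & br * rr$rr > 1)
    if (length(over) > 0L)
      stop_faersig("synthetic_config: base_rate * rr > 1 for pair (%s, %s)",
                   rr$drug[over[1L]], rr$pt[over[1L]])
  }
  structure(list(n_reports = as.integer(n_reports), drugs = drugs,
                 events = events, rr = rr,
                 duplicate_fraction = duplicate_fraction,
                 missingness = as.list(miss), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default synthetic drug panel
#' @return data.table usable as the `drugs` argument of
#'   [synthetic_config()].
#' @export
default_synthetic_drugs <- function() {
  data.table::data.table(
    name = c("lacosamide", "cenobamate"),
    marginal = c(0.10, 0.05),
    synonyms = list(c("LACOSAMIDE", "VIMPAT", "VIMPAT 100MG TABLETS",
                      "VIMPAT 200 MG"),
                    c("CENOBAMATE", "XCOPRI", "XCOPRI 12.5MG TABLETS",
                      "MOTPOLY XR")),
    doses = list(c(50, 100, 150, 200, 300, 400, 500, 600),
                 c(12.5, 12.5, 12.5, 25, 50, 100, 150))
  )
}

#' Default synthetic event panel
#' @return data.table usable as the `events` argument of
#'   [synthetic_config()]; all PTs are covered by the bundled demo
#'   vocabulary.
#' @export
default_synthetic_events <- function() {
  data.table::data.table(
    pt = c("Dizziness", "Somnolence", "Fatigue", "Fall", "Balance disorder",
           "Memory impairment", "Diplopia", "Bradycardia", "Ataxia",
           "Aggression", "Irritability", "Insomnia", "Headache", "Nausea",
           "Rash", "Vomiting", "Tremor", "Sedation", "Seizure",
           "Drug ineffective"),
    soc = c("Nervous system disorders", "Nervous system disorders",
            "General disorders and administration site conditions",
            "Injury, poisoning and procedural complications",
            "Nervous system disorders", "Nervous system disorders",
            "Eye disorders", "Cardiac disorders", "Nervous system disorders",
            "Psychiatric disorders", "Psychiatric disorders",
            "Psychiatric disorders", "Nervous system disorders",
            "Gastrointestinal disorders",
            "Skin and subcutaneous tissue disorders",
            "Gastrointestinal disorders", "Nervous system disorders",
            "Nervous system disorders", "Nervous system disorders",
            "General disorders and administration site conditions"),
    base_rate = c(0.050, 0.040, 0.040, 0.030, 0.020,
                  0.020, 0.010, 0.010, 0.010,
                  0.010, 0.010, 0.015, 0.030, 0.040,
                  0.020, 0.025, 0.010, 0.005, 0.020,
                  0.050)
  )
}

BACKGROUND_DRUGS <- c("LEVETIRACETAM", "LAMOTRIGINE", "TOPIRAMATE",
                      "CARBAMAZEPINE", "VALPROIC ACID", "CLOBAZAM",
                      "METFORMIN", "ASPIRIN", "LISINOPRIL", "IBUPROFEN")
SYNTH_COUNTRIES <- c("US", "JP", "DE", "FR", "GB", "CA", "IT", "ES")
SYNTH_COUNTRY_P <- c(0.55, 0.08, 0.08, 0.04, 0.04, 0.08, 0.07, 0.06)
INDICATION_PTS <- c("Epilepsy", "Seizure", "Partial seizures")

#' Generate a synthetic FAERS-dialect dataset
#'
#' Draws reports under the configured world, optionally writes the
#' DEMO/DRUG/REAC/OUTC/THER/INDI files in the FAERS ASCII dialect, and
#' returns the planted truth. Byte-identical output for identical configs.
#'
#' @param config a [synthetic_config()].
#' @param dir if non-`NULL`, directory to write the `.txt` file set into
#'   (created if needed).
#' @return list with `reports` (the raw, duplicate-containing tables as
#'   character data.tables, keyed like [read_faers_table()] output),
#'   `files` (paths written, or `NULL`), and `truth` (list: `rr` matrix,
#'   `n_reports` pre-duplication, `seed`).
#' @export
generate_faers <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_reports
  pid <- 100000 + seq_len(n)
  caseid <- 9000000 + seq_len(n)
  fda_dt <- 20200000 + sample(101:1231, n, replace = TRUE)

  # drug exposure matrix for study drugs
  drugs <- config$drugs
  expo <- matrix(FALSE, n, nrow(drugs))
  for (j in seq_len(nrow(drugs)))
    expo[, j] <- stats::runif(n) < drugs$marginal[j]

  # per-report event probability factor = max rr over the report's drugs
  events <- config$events
  drug_rows <- list()
  reac_rows <- list()
  miss <- config$missingness

  for (j in seq_len(nrow(drugs))) {
    idx <- which(expo[, j])
    if (length(idx) == 0L) next
    syn <- drugs$synonyms[[j]]
    doses <- drugs$doses[[j]]
    dose <- sample(doses, length(idx), replace = TRUE)
    dose[stats::runif(length(idx)) < miss$dose] <- NA_real_
    drug_rows[[length(drug_rows) + 1L]] <- data.table::data.table(
      primaryid = pid[idx],
      role_cod = sample(c("PS", "SS"), length(idx), replace = TRUE,
                        prob = c(0.8, 0.2)),
      drugname = sample(syn, length(idx), replace = TRUE),
      dose_amt = dose)
  }
  # every report also carries 1-2 background drugs (concomitant or suspect
  # for drug-free reports)
  nbg <- 1L + (stats::runif(n) < 0.4)
  any_study <- rowSums(expo) > 0
  bg1 <- data.table::data.table(
    primaryid = pid,
    role_cod = ifelse(any_study, "C", "PS"),
    drugname = sample(BACKGROUND_DRUGS, n, replace = TRUE),
    dose_amt = NA_real_)
  idx2 <- which(nbg == 2L)
  bg2 <- data.table::data.table(
    primaryid = pid[idx2], role_cod = "C",
    drugname = sample(BACKGROUND_DRUGS, length(idx2), replace = TRUE),
    dose_amt = NA_real_)
  drug_rows <- c(drug_rows, list(bg1, bg2))

  rrm <- as.data.frame(config$rr)
  for (e in seq_len(nrow(events))) {
    p <- rep(events$base_rate[e], n)
    if (nrow(rrm) > 0L) {
      rre <- rrm[rrm$pt == events$pt[e], , drop = FALSE]
      for (k in seq_len(nrow(rre))) {
        j <- match(rre$drug[k], drugs$name)
        if (!is.na(j)) {
          hit <- expo[, j]
          p[hit] <- pmax(p[hit], pmin(1, events$base_rate[e] * rre$rr[k]))
        }
      }
    }
    hit <- which(stats::runif(n) < p)
    if (length(hit) > 0L)
      reac_rows[[length(reac_rows) + 1L]] <- data.table::data.table(
        primaryid = pid[hit], pt = events$pt[e])
  }
  reac <- data.table::rbindlist(reac_rows)
  data.table::setorder(reac, primaryid, pt)

  # demographics with configured missingness
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.54, 0.46))
  sex[stats::runif(n) < miss$sex] <- ""
  age <- round(stats::rgamma(n, shape = 6, scale = 7), 0)
  age_chr <- as.character(pmin(age, 100))
  age_chr[stats::runif(n) < miss$age] <- ""
  age_cod <- ifelse(nzchar(age_chr), "YR", "")
  country <- sample(SYNTH_COUNTRIES, n, replace = TRUE, prob = SYNTH_COUNTRY_P)
  country[stats::runif(n) < miss$country] <- ""

  demo <- data.table::data.table(
    primaryid = pid, caseid = caseid, fda_dt = fda_dt, sex = sex,
    age = age_chr, age_cod = age_cod, occr_country = country)

  # outcomes: 0-2 codes per report
  outc_p <- c(HO = 0.20, OT = 0.30, DE = 0.04, LT = 0.02, DS = 0.01)
  outc_rows <- lapply(names(outc_p), function(code) {
    hit <- which(stats::runif(n) < outc_p[[code]])
    if (length(hit) == 0L) return(NULL)
    data.table::data.table(primaryid = pid[hit], outc_cod = code)
  })
  outc <- data.table::rbindlist(outc_rows)
  data.table::setorder(outc, primaryid, outc_cod)

  # indications for study-drug reports (the treated disease); the
  # indication PTs also occur as events (base panel includes Seizure),
  # exercising indication exclusion downstream
  sidx <- which(any_study)
  indi <- data.table::data.table(
    primaryid = pid[sidx],
    indi_pt = sample(INDICATION_PTS, length(sidx), replace = TRUE,
                     prob = c(0.5, 0.35, 0.15)))

  ther <- data.table::data.table(primaryid = pid, start_dt = fda_dt - 30)

  drug <- data.table::rbindlist(drug_rows)
  data.table::setorder(drug, primaryid, drugname)

  # duplicate versions: extra DEMO rows sharing CASEID with strictly later
  # FDA_DT and larger PRIMARYID; child rows copied, so the survivor's
  # content equals the original's
  ndup <- floor(config$duplicate_fraction * n)
  if (ndup > 0L) {
    di <- sample.int(n, ndup)
    new_pid <- 100000 + n + seq_len(ndup)
    dup_demo <- data.table::copy(demo[di])
    new_dt <- demo$fda_dt[di] + sample(1:60, ndup, replace = TRUE)
    dup_demo[, `:=`(primaryid = new_pid, fda_dt = new_dt)]
    demo <- rbind(demo, dup_demo)
    remap <- function(tab) {
      sub <- tab[primaryid %in% pid[di]]
      sub[, primaryid := new_pid[match(primaryid, pid[di])]]
      rbind(tab, sub)
    }
    drug <- remap(drug)
    reac <- remap(reac)
    outc <- remap(outc)
    indi <- remap(indi)
    ther <- remap(ther)
  }

  to_chr <- function(dt) {
    dt <- data.table::copy(dt)
    for (nm in names(dt)) {
      v <- as.character(dt[[nm]])
      v[is.na(v)] <- ""
      data.table::set(dt, j = nm, value = v)
    }
    dt
  }
  tables <- list(DEMO = to_chr(demo), DRUG = to_chr(drug),
                 REAC = to_chr(reac), OUTC = to_chr(outc),
                 THER = to_chr(ther), INDI = to_chr(indi))

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(names(tables), function(kind) {
      p <- file.path(dir, paste0(kind, ".txt"))
      write_faers_table(tables[[kind]], p)
      p
    }, character(1))
  }

  list(reports = tables, files = files,
       truth = list(rr = data.table::copy(config$rr), n_reports = n,
                    seed = config$seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Planted signal pairs above a threshold
#'
#' @param truth the `truth` element returned by [generate_faers()].
#' @param rr_threshold minimum planted rate ratio (inclusive).
#' @return data.table with columns `drug`, `pt` — the reference set for
#'   recovery metrics.
#' @export
truth_signals <- function(truth, rr_threshold = 2) {
  rr_tab <- data.table::as.data.table(truth$rr)
  if (nrow(rr_tab) == 0L)
    return(data.table::data.table(drug = character(0), pt = character(0)))
  rr_tab[rr_tab[["rr"]] >= rr_threshold, .(drug, pt)]
}
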