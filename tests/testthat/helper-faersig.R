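# Shared helpers: compact report_set construction, independent statistical
# oracles, and a brute-force contingency counter.

library(data.table)

# Build a report_set from a list of compact per-report specs:
#   list(pid=, caseid=, fda=, sex=, age=, country=,
#        drugs = list(c(name, role, dose?)), events = c(...),
#        indis = c(...), outcomes = c(...))
mk_rs <- function(specs) {
  demo <- rbindlist(lapply(specs, function(s) data.table(
    primaryid = s$pid,
    caseid = s$caseid %||na% s$pid,
    fda_dt = s$fda %||na% 20230101,
    sex = s$sex %||na% "unknown",
    age_years = s$age %||na% NA_real_,
    country = s$country %||na% NA_character_)))
  one <- function(s, field, cols, f) {
    v <- s[[field]]
    if (is.null(v) || length(v) == 0L) return(NULL)
    f(s$pid, v)
  }
  drug <- rbindlist(lapply(specs, one, "drugs", NULL, function(pid, v)
    rbindlist(lapply(v, function(dr) data.table(
      primaryid = pid, drugname = dr[[1]], role = dr[[2]],
      daily_dose_mg = if (length(dr) > 2) as.numeric(dr[[3]]) else NA_real_)))))
  reac <- rbindlist(lapply(specs, one, "events", NULL, function(pid, v)
    data.table(primaryid = pid, pt = v)))
  outc <- rbindlist(lapply(specs, one, "outcomes", NULL, function(pid, v)
    data.table(primaryid = pid, outcome = v)))
  indi <- rbindlist(lapply(specs, one, "indis", NULL, function(pid, v)
    data.table(primaryid = pid, pt = v)))
  empty <- list(
    drug = data.table(primaryid = numeric(0), drugname = character(0),
                      role = character(0), daily_dose_mg = numeric(0)),
    reac = data.table(primaryid = numeric(0), pt = character(0)),
    outc = data.table(primaryid = numeric(0), outcome = character(0)),
    indi = data.table(primaryid = numeric(0), pt = character(0)))
  report_set(demo,
             drug = if (nrow(drug)) drug else empty$drug,
             reac = if (nrow(reac)) reac else empty$reac,
             outc = if (nrow(outc)) outc else empty$outc,
             indi = if (nrow(indi)) indi else empty$indi)
}

`%||na%` <- function(x, y) if (is.null(x)) y else x

test_dict <- function() {
  drug_dictionary(list(
    cenobamate = c("cenobamate", "xcopri", "motpoly xr"),
    lacosamide = c("lacosamide", "vimpat"),
    drugX = "drugx", drugY = "drugy"))
}

test_vocab <- function() {
  vocab_map(c(
    evE = "SOC1", evF = "SOC1", evG = "SOC2",
    Somnolence = "Nervous system disorders",
    Fall = "Injury, poisoning and procedural complications"))
}

# --- independent oracles -----------------------------------------------

# ROR and Woolf interval, scalar transcription of the closed form
oracle_ror <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) return(c(NA_real_, NA_real_, NA_real_))
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(ror, exp(log(ror) - 1.96 * se), exp(log(ror) + 1.96 * se))
}

oracle_prr <- function(a, b, c, d) {
  if (a == 0 || c == 0 || (a + b) == 0 || (c + d) == 0) return(NA_real_)
  (a / (a + b)) / (c / (c + d))
}

# chi-squared via stats::chisq.test, a genuinely independent code path
oracle_chi2 <- function(a, b, c, d, yates = FALSE) {
  m <- matrix(c(a, c, b, d), 2, 2)
  unname(suppressWarnings(stats::chisq.test(m, correct = yates)$statistic))
}

# BCPNN posterior moments, scalar transcription
oracle_ic <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  n1 <- a + b; m1 <- a + c
  gam <- g11 * (N + al) * (N + be) / ((n1 + a1) * (m1 + b1))
  e <- log2((a + g11) * (N + al) * (N + be) / ((N + gam) * (n1 + a1) * (m1 + b1)))
  v <- ((N - a + gam - g11) / ((a + g11) * (1 + N + gam)) +
          (N - n1 + al - a1) / ((n1 + a1) * (1 + N + al)) +
          (N - m1 + be - b1) / ((m1 + b1) * (1 + N + be))) / log(2)^2
  c(e, v, e - 2 * sqrt(v))
}

# brute-force 2x2 cell counts: nested loop over reports, set semantics
oracle_table <- function(reports, drug_ids, event_pts, level = "PT",
                         vocab = NULL) {
  demo_ids <- reports$demo$primaryid
  a <- b <- cc <- d <- 0L
  for (pid in demo_ids) {
    pts <- reports$reac$pt[reports$reac$primaryid == pid]
    has_event <- if (level == "PT") {
      any(tolower(pts) %in% tolower(event_pts))
    } else {
      any(map_pt_to_soc(pts, vocab) %in% event_pts)
    }
    has_drug <- pid %in% drug_ids
    if (has_drug && has_event) a <- a + 1L
    else if (has_drug) b <- b + 1L
    else if (has_event) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# small random report_set for property tests
random_rs <- function(n, seed, n_drugs = 2, n_events = 4) {
  set.seed(seed)
  drugs <- c("drugx", "drugy")[seq_len(n_drugs)]
  events <- paste0("ev", LETTERS[5:(4 + n_events)])
  specs <- lapply(seq_len(n), function(i) {
    dr <- drugs[runif(n_drugs) < 0.3]
    ev <- events[runif(n_events) < 0.3]
    list(pid = 1000 + i, caseid = 5000 + i,
         drugs = lapply(dr, function(x) c(x, "PS")),
         events = ev)
  })
  mk_rs(specs)
}
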