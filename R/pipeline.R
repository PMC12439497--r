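# Pipeline orchestration: ingest (or simulate) -> dedup -> map ->
# contingency -> disproportionality -> compare, with CSV outputs, a
# machine-readable summary and a run log.

# polynomial rolling hash over the serialised config, for the run log
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes ingest (from a FAERS-dialect input directory, or from the
#' synthetic generator), deduplication, indication exclusion, per-drug
#' disproportionality and the two-drug comparison, writing all CSV outputs
#' plus `summary.json` and `run.log` into `out_dir`. Any stage error aborts
#' with a stage-named message and removes partial outputs.
#'
#' @param config named list (or path to a JSON file) with fields:
#'   `input_dir` (FAERS-dialect directory) or `synthetic` (list of
#'   [synthetic_config()] arguments); `drugs` (canonical names to analyse,
#'   default cenobamate + lacosamide); `dictionary` and `vocab` (paths,
#'   default the bundled files); `roles` (default `c("PS","SS")`);
#'   `criteria` (named overrides of [signal_criteria()] defaults); `seed`.
#' @param out_dir output directory, created if needed.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                       sprintf(fmt, ...)))
  }
  emit_csv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    written <<- c(written, p)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop_faersig("stage '%s' failed: %s", name, conditionMessage(e),
                   class = "faersig_stage_error")
    })
  }

  note("config hash %s", config_hash(config))
  seed <- as.integer(config$seed %||% 1L)

  dict <- stage("config", {
    if (is.null(config$dictionary)) read_drug_dictionary()
    else read_drug_dictionary(config$dictionary)
  })
  vocab <- stage("config", {
    if (is.null(config$vocab)) read_vocab() else read_vocab(config$vocab)
  })
  criteria <- stage("config", do.call(signal_criteria, as.list(config$criteria)))
  roles <- config$roles %||% c("PS", "SS")
  drugs <- config$drugs %||% c("cenobamate", "lacosamide")

  raw <- stage("ingest", {
    if (!is.null(config$synthetic)) {
      sc_args <- as.list(config$synthetic)
      if (is.null(sc_args$seed)) sc_args$seed <- seed
      gen <- generate_faers(do.call(synthetic_config, sc_args))
      note("synthetic generation: %d unique reports, seed %d",
           gen$truth$n_reports, sc_args$seed)
      gen$reports
    } else if (!is.null(config$input_dir)) {
      tabs <- list()
      for (kind in FAERS_TABLE_KINDS) {
        hits <- dir(config$input_dir, pattern = paste0("(?i)^", kind, ".*\\.txt$"),
                    full.names = TRUE)
        if (length(hits) > 0L) tabs[[kind]] <- read_faers_table(hits[1L], kind)
      }
      if (is.null(tabs$DEMO))
        stop_faersig("no DEMO table found in %s", config$input_dir)
      tabs
    } else stop_faersig("config needs either 'input_dir' or 'synthetic'")
  })

  assembled <- stage("assemble", assemble_reports(raw))
  rej <- attr(assembled, "rejects")
  note("assembled %d reports; %d DEMO rejects; orphans: %s",
       n_reports(assembled), nrow(rej$demo_rejects),
       paste(sprintf("%s=%d", names(rej$orphans), rej$orphans), collapse = " "))

  dd <- stage("dedup", deduplicate(assembled))
  note("dedup removed %d duplicate versions, %d key rejects",
       dd$removed, nrow(dd$rejects))

  ex <- stage("map", exclude_indications(dd$reports))
  analysed <- ex$reports
  unmapped <- sum(map_pt_to_soc(unique(analysed$reac$pt), vocab) == "unmapped")
  note("indication exclusion dropped %d event-less reports; %d unmapped PTs",
       ex$dropped, unmapped)

  results <- list()
  summary_drugs <- list()
  stage("dispro", {
    for (dg in drugs) {
      sel <- select_reports(analysed, dg, dict, roles)
      res <- dispro_analysis(analysed, dg, dict, vocab, criteria, roles)
      results[[dg]] <- res
      summary_drugs[[dg]] <- list(
        n_reports = n_reports(sel),
        n_signals = sum(res$level == "PT" & res$is_signal),
        n_strong = count_strong_signals(res[res$is_signal == TRUE],
                                        dg, criteria$strong_ic_minus_2sd))
      note("%s: %d reports, %d PT signals, %d strong", dg,
           n_reports(sel), summary_drugs[[dg]]$n_signals,
           summary_drugs[[dg]]$n_strong)
    }
  })

  stage("compare", {
    baselines <- list(); tops <- list(); doses <- list()
    for (dg in drugs) {
      sel <- select_reports(analysed, dg, dict, roles)
      if (n_reports(sel) > 0L) {
        bl <- baseline_characteristics(sel)
        baselines[[dg]] <- data.table::rbindlist(lapply(
          c("sex", "age", "outcomes", "country"),
          function(bk) data.table::data.table(drug = dg, block = bk, bl[[bk]])))
        tops[[dg]] <- data.table::data.table(drug = dg, top_events(sel, 10L))
        bins <- if (dg == "cenobamate") dose_bins_exact() else dose_bins_ranges()
        doses[[dg]] <- data.table::data.table(drug = dg,
                                              dose_strata_counts(sel, bins))
      }
    }
    emit_csv(data.table::rbindlist(baselines), "baseline.csv")
    emit_csv(data.table::rbindlist(tops), "top_events.csv")
    emit_csv(data.table::rbindlist(doses), "dose_strata.csv")
    emit_csv(data.table::rbindlist(results), "signal_results.csv")
    if (length(results) >= 2L) {
      cmp <- compare_signals(results[[1L]], results[[2L]])
      emit_csv(cmp$comparison, "signal_comparison.csv")
      emit_csv(cmp$forest, "forest.csv")
      emit_csv(cmp$sankey, "sankey_edges.csv")
    }
  })

  summary <- list(
    config_hash = config_hash(config), seed = seed,
    total_reports = n_reports(analysed),
    dedup_removed = dd$removed,
    indication_dropped = ex$dropped,
    unmapped_pts = unmapped,
    drugs = summary_drugs)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(summary)
}

#' Check the bundled published-signal fixture
#'
#' Re-derives the headline counts from the bundled fixture: strong signals
#' per drug (IC-2SD at or above the threshold) and signal counts per SOC
#' and drug.
#'
#' @param path fixture CSV path (default the bundled transcription).
#' @param threshold strong-signal IC-2SD cut (default 1.0 bit).
#' @return list with `strong` (named counts per drug) and `per_soc`
#'   (data.table `soc`, `drug`, `n_signals`).
#' @export
fixture_check <- function(path = faersig_example("table5_signals.csv"),
                          threshold = 1.0) {
  fx <- read_signal_fixture(path)
  strong <- vapply(c("cenobamate", "lacosamide"),
                   function(dg) count_strong_signals(fx, dg, threshold),
                   integer(1))
  per_soc <- fx[, .(n_signals = .N), by = .(soc, drug)]
  data.table::setorder(per_soc, soc, drug)
  list(strong = strong, per_soc = per_soc[])
}
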