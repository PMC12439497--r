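# faersig

Disproportionality signal detection for FAERS-style spontaneous
adverse-event reports.

Spontaneous pharmacovigilance databases (the FDA Adverse Event Reporting
System, FAERS, being the largest) have no exposure denominator, so
post-marketing safety surveillance relies on *disproportionality*: for each
(drug, event) pair, the deduplicated reports are cross-classified into a
2×2 table — `a` reports with the drug and the event, `b` with the drug
only, `c` with the event only, `d` with neither — and the reporting
association is measured by

* the **reporting odds ratio**, ROR = ad/bc, with its Woolf 95% interval
  exp(log ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d));
* the **proportional reporting ratio**, PRR = [a/(a+b)]/[c/(c+d)], with
  the Pearson χ² on the table;
* the **BCPNN information component**, IC = log₂ P(drug,event)/(P(drug)P(event)),
  as closed-form Bayesian posterior moments, signalling on the conservative
  bound IC−2SD = E(IC) − 2√V(IC).

A pair is a **signal** when a ≥ 6, ROR ≥ 2 with lower 95% bound > 1,
PRR > 2 with χ² > 4, and IC−2SD > 0; a **strong signal** additionally has
IC−2SD ≥ 1.0 bit.

The package is built around the comparative safety profile of two
third-generation anti-seizure medications — cenobamate (CNB, brand Xcopri)
and lacosamide (LCM, brand Vimpat) — and ships a transcription of the
published two-drug signal table as a validation fixture, but every stage
takes an arbitrary drug dictionary and PT→SOC vocabulary.

It is aimed at pharmacoepidemiologists and methods developers who want a
*tested*, fully reproducible pipeline: FAERS ASCII ingestion (dollar
delimited, exact round trip), FDA-rule deduplication (CASEID → highest
FDA_DT → largest PRIMARYID), verbatim drug-name normalisation, indication
exclusion, report-level 2×2 construction, the three statistics, the
composite rule, descriptive tables (baseline characteristics, top events,
daily-dose strata) and the two-drug comparison exports (shared-signal
forest table, Sankey edge list). A synthetic FAERS-dialect generator with
planted reporting-rate ratios makes every stage testable offline.

## Worked example

Simulate a 20,000-report world with two planted associations
(rr = 10 for cenobamate–sedation and lacosamide–bradycardia, everything
else at the null), push it through the whole pipeline, and test for
signals:

```r
library(faersig)

cfg <- synthetic_config(
  n_reports = 20000, seed = 7,
  rr = data.frame(drug = c("cenobamate", "lacosamide"),
                  pt   = c("Sedation",   "Bradycardia"), rr = 10))
gen <- generate_faers(cfg, dir = tempfile("faers_"))   # writes DEMO.txt etc.

rs <- assemble_reports(gen$reports)
#> <report_set> 22000 reports, 34210 drug rows, 10353 event rows
dd <- deduplicate(rs)                 # dd$removed == 2000 duplicate versions
analysed <- exclude_indications(dd$reports)$reports

dict  <- read_drug_dictionary()       # cenobamate/Xcopri, lacosamide/Vimpat
vocab <- read_vocab()                 # demo PT -> SOC table
res <- dispro_analysis(analysed, "cenobamate", dict, vocab, levels = "PT")
res[res$is_signal == TRUE,
    .(event, a, prr, chi2, ror, ror_ci_low, ic_minus_2sd, is_strong)]
#>       event  a      prr  chi2   ror ror_ci_low ic_minus_2sd is_strong
#> 1: Sedation 67 10.12018 356.5 11.89       8.63          2.2      TRUE
```

The planted cenobamate–sedation pair is recovered (a = 67 of ~1,000
cenobamate reports; ROR 11.9 with lower bound 8.6; IC−2SD 2.2 bits, so a
strong signal) and nothing else is flagged — the generator's 20,000
null pairs stay below every threshold.

The bundled published-signal fixture reproduces the headline comparison —
55 strong signals for cenobamate, 98 for lacosamide:

```r
fixture_check()$strong
#> cenobamate lacosamide
#>         55         98
```

`run_pipeline(config, out_dir)` orchestrates all of the above from a JSON
config (synthetic or `input_dir` mode) and writes `baseline.csv`,
`top_events.csv`, `dose_strata.csv`, `signal_results.csv`,
`signal_comparison.csv`, `forest.csv`, `sankey_edges.csv`, a
`summary.json` and a run log; `inst/cli/faersig.R` wraps it as a
command-line tool with `simulate`, `run` and `fixture-check` subcommands.

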