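---
title: "Disproportionality signal detection on FAERS-style spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on FAERS-style spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(faersig)
```

## The problem

Spontaneous adverse-event (AE) databases such as the FDA Adverse Event
Reporting System (FAERS) collect voluntary post-marketing safety reports.
They have no denominator — we observe reports, not exposed patients — so
risk cannot be estimated directly. Disproportionality analysis instead asks
whether an event is reported *disproportionately often* with a target drug
relative to the rest of the database. For each (drug, event) pair the
deduplicated reports are cross-classified into a 2×2 table:

|                | event        | no event |
|----------------|--------------|----------|
| **target drug**| a            | b        |
| **other reports** | c         | d        |

`faersig` implements this pipeline end to end for comparative
pharmacovigilance of two anti-seizure medications, cenobamate (CNB) and
lacosamide (LCM), but every stage is generic: any drug dictionary and any
PT→SOC vocabulary can be supplied.

## The data model and its cleaning rules

FAERS quarters are dollar-delimited ASCII tables: DEMO (demographics and
administration), DRUG, REAC (MedDRA preferred terms, PTs), OUTC (outcome
codes DE/DS/LT/HO/OT), THER and INDI (indications). `read_faers_table()` /
`write_faers_table()` round-trip this dialect exactly; `assemble_reports()`
joins child tables to DEMO by PRIMARYID into a relational `report_set`.

Three cleaning rules matter for the counts:

* **Deduplication.** One case (CASEID) can have many report versions. Per
  case we keep the version with the highest FDA_DT, breaking ties by the
  largest PRIMARYID, both compared numerically (`deduplicate()`). The rule
  is idempotent and order-invariant.
* **Indication exclusion.** A report's treated disease (INDI PTs) is not an
  adverse event; `exclude_indications()` removes, per report, events that
  exactly match (case-folded) that report's own indication PTs. Reports
  left without events are dropped from the analysis universe. Published
  workflows did this semi-manually with pharmacist review against SMQ
  groupings; exact PT matching is the reproducible approximation we adopt,
  and it is deliberately conservative (it never removes a non-indication
  term).
* **Drug identification.** Verbatim FAERS drug names carry dose and form
  noise. A name matches a dictionary synonym when the synonym's token
  sequence equals the leading tokens of the case-folded, punctuation-split
  verbatim name ("VIMPAT 100MG TABLETS" → lacosamide). Only suspect roles
  (PS, SS) are admitted by default — the dominant convention; concomitant
  and interacting roles can be added via `roles = c("PS","SS","C","I")`.

**Counting unit.** All four cells count unique reports: a report
contributes at most 1 to `a` regardless of how many matching drug rows or
PTs it lists. At SOC level a report carries the class if any of its PTs
maps into it. The background (c, d) is the whole ingested report universe
minus the drug's reports — the full database in a real analysis, the
synthetic universe in tests.

## The statistics

With `N = a+b+c+d`:

* **Reporting odds ratio** `ROR = ad/bc`, with the Woolf (log-scale) 95%
  interval `exp(log ROR ± 1.96 √(1/a+1/b+1/c+1/d))`. Any zero cell makes
  the ROR incalculable; we deliberately apply **no continuity correction**,
  because the signal rule's `a ≥ 6` floor makes corrected values
  irrelevant and corrections silently change printed-style outputs.
* **Proportional reporting ratio** `PRR = [a/(a+b)] / [c/(c+d)]`, with the
  uncorrected Pearson chi-squared on the table (Yates correction available
  by flag; the conventional reading of the `χ² > 4` threshold is the
  uncorrected statistic).
* **BCPNN information component** `IC = log2 P(drug,event)/(P(drug)P(event))`,
  with closed-form posterior moments under the standard priors
  (`α₁ = β₁ = 1`, `α = β = 2`, `γ₁₁ = 1`, `γ` tuned so the prior IC mean
  is 0). The conservative bound `IC−2SD = E(IC) − 2√V(IC)` drives
  signalling; shrinkage keeps it finite even at `a = 0`. `E(IC)` converges
  to the maximum-likelihood `log2(aN/((a+b)(a+c)))` as the table grows
  with fixed proportions — a property the test suite checks.

**Composite signal rule** (`signal_criteria()`): a pair is a signal when
(1) `a ≥ 6`, (2) `ROR ≥ 2` with lower 95% bound `> 1`, (3) `PRR > 2` and
`χ² > 4`, and (4) `IC−2SD > 0`; a **strong** signal additionally has
`IC−2SD ≥ 1.0` bit. Inclusive versus strict boundaries follow the printed
inequality symbols exactly, and an incalculable statistic fails its
condition. Requiring all three families (frequentist ratios plus the
shrunk Bayesian bound) is what keeps the false-positive rate low; the
package's null-calibration property (below) quantifies that.

## The synthetic world

`generate_faers()` writes FAERS-dialect files from a configurable
generative model so the full pipeline is testable without downloading the
archive. Per report: study drugs are drawn independently from their
marginals (defaults 0.10 LCM, 0.05 CNB — desk-scale stand-ins, not the
archive's 13,874/50.3M and 3,584/50.3M proportions, which would need
millions of reports to produce countable cells); one or two background
drugs are always present; each event PT fires independently with
probability `base_rate × rr(drug, PT)` (maximum over the report's drugs,
validated ≤ 1 at config time), with the planted `rr` matrix kept as ground
truth; demographics carry configurable missingness (defaults: sex 30%,
age 45%, country 10%, dose 50% — real baseline tables for a newly marketed
drug show sex/age unknown for the vast majority of reports); outcome codes
are sampled at roughly the published frequencies (hospitalisation ~20%,
death ~4%); indication PTs (epilepsy/seizure terms) are attached to
study-drug reports and also occur as events, so indication exclusion is
exercised; a configurable fraction of cases (default 10%) is re-emitted as
a duplicate version with a later FDA_DT and larger PRIMARYID and identical
content, so the intended dedup survivor — and hence the post-dedup count —
is exact by construction.

What the generator does **not** emulate: co-prescription correlation
structure, report-level event correlation (events are conditionally
independent given the drug set, matching the independence the 2×2
statistics assume), free-text misspellings beyond dose/form tokens, and
reporting-over-time dynamics. A green test therefore establishes
correctness of the counting and the statistics under the stated model, not
robustness to real-world reporting artefacts.

Two calibration properties define "working" at the stated scales:

* **Null calibration** — with `rr ≡ 1` (50,000 reports × 5 seeds), the
  fraction of (drug, PT) pairs flagged as signals stays below 2%.
* **Planted recovery** — pairs with `rr = 10` and expected `a ≥ 20`
  (20 seeds) are flagged in ≥ 95% of runs.

## Numerical and design choices

* Percentages print with **half-up rounding** to one decimal
  (`round_half_up()`), matching published baseline tables; base R's
  banker's rounding disagrees on exact .x5 boundaries.
* Dose strata are **half-open on the left**, `(low, high]`, so a 200 mg
  daily dose falls in the 100–200 bin; published dose tables print
  overlapping labels ("100 mg ~ 200 mg", "200 mg ~ 400 mg"), which forces
  a convention. Cenobamate uses exact titration-dose bins
  (12.5/25/50/100/150 mg). "Over 18 years old" is `age ≥ 18`, consistent
  with an 18–49 age band. A report with several dose rows contributes its
  maximum daily dose.
* Ranking ties (top events) break alphabetically — determinism for tests;
  the source tables are silent.
* Age is interpreted only when the unit code is years; other unit codes
  become missing, because the published age bands are year-based and no
  conversion rule is given. Missing sex/age/country map to "unknown"
  categories rather than being dropped.
* The ROR interval uses the literal 1.96 multiplier (the constant the
  field's formulas print), not `qnorm(0.975)`.
* The bundled PT→SOC vocabulary is a small demonstration table covering
  the fixture's and generator's PTs; MedDRA licensing forbids
  redistributing the real dictionary, so production use requires a
  user-supplied TSV. PTs outside the vocabulary go to an explicit
  "unmapped" bucket rather than being silently lost.

## Known limitations

Disproportionality is hypothesis-generating: RORs are not risks and no
multiplicity adjustment is applied (none is conventional here). The
published database-scale margins cannot be reconstructed at desk scale, so
the acceptance checks validate the fixture-derived counts and the
statistical machinery against independent oracles and simulation rather
than re-deriving archive totals. Exact-match indication exclusion may
leave near-synonym indication terms in the event stream. Stratified or
adjusted analyses (age/sex) are out of scope.
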