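Package: faersig
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("faersig", "maintainers", email = "faersig@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative pharmacovigilance on FDA
    Adverse Event Reporting System (FAERS) quarterly data: reading and
    writing the dollar-delimited ASCII dialect, FDA-rule deduplication
    (CASEID / FDA_DT / PRIMARYID), drug-name normalisation against a
    generic+brand synonym dictionary, MedDRA preferred-term to
    system-organ-class mapping, indication exclusion, report-level 2x2
    contingency tables, and disproportionality statistics (reporting odds
    ratio with Woolf interval, proportional reporting ratio with Pearson
    chi-squared, and the BCPNN information component with its IC-2SD lower
    bound) combined into a composite signal rule. Includes a synthetic
    FAERS-dialect generator with planted reporting-rate ratios so every
    stage is testable without downloading the archive, and cross-drug
    comparison outputs (baseline characteristics, top events, dose strata,
    shared-signal forest and Sankey exports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
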