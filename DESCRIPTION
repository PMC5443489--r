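Package: glycomethyl
Title: Differential DNA Methylation Analysis for Hyperglycemia Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying differential DNA methylation in relation to
    blood glucose homeostasis. Implements Infinium-style beta-value
    computation with negative-control background subtraction, a longitudinal
    differentially-methylated-position (DMP) discovery cascade (paired
    stage tests, top-k ranking by case-control contrast, case-specific set
    subtraction and cross-subgroup overlap), diabetic-trait association
    statistics (HOMA-IR, QUICKI, Welch's t-test from raw data or printed
    summaries, covariate-adjusted regression), per-cytosine methylation
    calling from whole-genome bisulfite sequencing counts, and windowed
    differential-methylation summaries around a target CpG with donor
    stratification and bootstrap confidence intervals. Ships synthetic-data
    generators that emulate the statistical structure of a paired
    two-timepoint methylation-array study, a clinical trait table, and
    per-cytosine bisulfite counts, so every stage of the pipeline can be
    exercised and validated without access-controlled cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
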