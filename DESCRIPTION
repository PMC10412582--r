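Package: chemoscore
Title: Four-Chemokine Expression Score Analysis for Immune Checkpoint
    Inhibitor Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a four-chemokine expression score (the mean
    log2(TPM + 0.001) expression of CCL4, CCL5, CXCL9 and CXCL10) across
    bulk tumor transcriptomes, stratifies cohorts into score-high,
    -intermediate and -low groups by global quartiles, and relates the
    groups to tumor mutational burden, microsatellite-instability and
    homologous-recombination-deficiency subtypes, single-sample gene-set
    enrichment of immune programs, and immune checkpoint inhibitor
    outcomes (durable clinical benefit, time to progression, overall
    survival).  Includes readers for expression, MAF-style mutation,
    clinical and GMT gene-set tables, and a seeded synthetic multi-tumor-
    type cohort generator used to exercise and validate every stage of
    the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
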