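Package: sclcTME
Title: Compartment-Resolved Tumor-Microenvironment Profiling for Small Cell Lung Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for compartment-resolved immune profiling of
    small cell lung cancer cohorts. Converts per-core, per-compartment immune
    cell counts into area-adjusted densities and ordinal scores, dichotomizes
    biomarkers with a median-absolute-deviation cutoff, classifies samples into
    immune-oasis and immune-desert phenotypes, computes rank correlations and
    nonparametric group comparisons between marker densities, runs preranked
    gene-set enrichment (running-sum enrichment score with a gene-label
    permutation null) on a targeted expression panel, derives Bonferroni-adjusted
    differential-expression target lists with volcano categorization, and scores
    the connectivity of interaction networks induced by the selected targets.
    Includes a seeded synthetic-cohort generator emulating the statistical
    structure of a neuroendocrine-high/-low cohort with matched lymph-node
    metastases, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
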