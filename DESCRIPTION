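Package: pgrpipe
Title: Proactive Genomic Reanalysis with Phenotype-Aware Variant Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-automated reanalysis pipeline for clinical exome and
    genome cohorts. Candidate variants are nominated by an inheritance- and
    frequency-aware cohort family analysis (CFA) filter cascade, matched
    against patient phenotypes through a Human Phenotype Ontology style
    information-content model, scored by a 43-feature feed-forward neural
    network, and screened by codified first- and second-pass review rules
    including ACMG criteria combined under a Bayesian points framework.
    A seeded synthetic-cohort generator with planted causal variants
    provides ground truth for every stage, and a branch-pruning experiment
    quantifies the sensitivity of variant scores to missing phenotype
    clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    nnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
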