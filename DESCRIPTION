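Package: cnvdrive
Title: Integrative Copy-Number and Expression Screening for Candidate
    Driver Genes in Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate driver genes in tumor cohorts with complex
    genomics by integrating probe-level copy-number calls with expression
    profiles. Probes are filtered (constitutional copy-number polymorphism
    regions, sex chromosomes, intergenic probes, probes unstable in normal
    controls), aggregated to a per-gene copy-number status, and combined
    with a representative expression probe (maximum interquartile range) to
    call concordant alterations relative to the quartiles of a copy-normal
    control group. Pathways altered in every tumor are selected from a flat
    catalog, gene and pathway alterations are tested for subgroup enrichment
    (Fisher's exact test), and candidate drivers are genes enriched together
    with at least one of their pathways. Expression is dichotomized at the
    intersection of kernel density curves (deleted versus copy-normal) and
    strata are compared by Kaplan-Meier estimates, the log-rank test and
    observed/expected hazard ratios on metastasis-free survival. A
    synthetic-cohort generator with planted truth makes every stage
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    survival,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
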