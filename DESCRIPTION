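Package: crossomics
Title: Cross-Omics Candidate Gene Discovery, Two-Point Linkage and Assay
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for candidate-gene discovery that combines
    bulk RNA-Seq differential expression with isobaric-label (iTRAQ/TMT)
    reporter-ion proteome quantification.  Transcript hits are called by a
    consensus of three routes (background-subtracted fold change with a
    replicate t-test, a standard-deviation-about-zero log2 fold-change
    threshold, and a negative-binomial two-step count test), protein hits by
    interference-filtered median spectrum aggregation, quantile
    normalization and a 3 s.d. threshold, and the two screens are
    intersected into a direction-consistent candidate list.  Also provides
    parametric two-point LOD scoring of pedigrees by Elston-Stewart peeling,
    delta-delta Ct relative quantification, dual-reporter normalization,
    sequencing QC summaries, and synthetic-data generators with planted
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
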