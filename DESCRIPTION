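Package: gprelate
Title: Genomic Prediction Accuracy from Relatedness and Effective Chromosome Segments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links effective population size (Ne) and the effective number of
    independent chromosome segments (Me) to the expected accuracy of genomic
    prediction. Provides closed-form and numeric calculators for Me from
    population parameters, empirical Me from the discovery-by-target block of
    a genomic relationship matrix (GRM), expected prediction accuracy for
    quantitative traits and for case-control designs under the liability
    threshold model (correlation, AUC and percentile odds ratios), a GBLUP /
    SNP-BLUP predictor of genetic profile scores, and two validation
    simulators: a forward-in-time gene-dropping simulator producing
    equilibrium-LD genotypes, and an independent-SNP liability-threshold
    case-control simulator with case over-ascertainment. Includes observed
    counterparts (AUC, percentile odds ratios) so theoretical expectations and
    simulation or data results can be compared end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, yaml, knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'liability.R'
    'me-theory.R'
    'grm.R'
    'accuracy.R'
    'gblup.R'
    'sim-genedrop.R'
    'sim-casecontrol.R'
    'metrics.R'
    'workflows.R'
    'gprelate-package.R'
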