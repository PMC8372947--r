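Package: hscrcnv
Title: Rare CNV Burden and Candidate Gene Prioritization for Hirschsprung Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for candidate-gene prioritization in a rare
    copy-number-variant (CNV) case/control study of Hirschsprung disease.
    Classifies case CNVs as rare against a control cohort by fractional
    overlap, annotates gene content and gene constraint (constrained coding
    regions), calls enteric-nervous-system (ENS) enriched genes from labeled
    expression data with a random-variance-model moderated t-test and
    permutation p-values, computes a weighted non-coding polygenic risk
    score from risk-haplotype SNPs, runs the group burden and zebrafish
    phenotype statistics, and assembles the final candidate-gene report.
    Includes a synthetic-data generator with planted structure so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
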