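Package: droughtprime
Title: Priming-Oriented Differential Expression Analysis for Two-Genotype
    Stress Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for single-channel expression experiments
    contrasting a stress-tolerant and a stress-sensitive genotype across two
    organs and two watering conditions. Implements percentile-shift
    normalization with median baselining, per-organ two-factor cell-means
    ANOVA contrasts with Benjamini-Hochberg correction and fold-change
    thresholds, probe-to-gene collapse, genotype- and organ-exclusivity
    partitioning of differentially expressed genes, selection of
    "stressed-like readiness" priming candidates, hypergeometric GO term
    enrichment with true-path annotation propagation, Ward hierarchical
    sample clustering, and an efficiency-corrected qPCR validation stack
    (amplification-curve efficiency estimation, Pfaffl ratios, randomization
    significance, cross-platform Spearman concordance). A synthetic-data
    generator with planted ground truth makes every stage testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    ape,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
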