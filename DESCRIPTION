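Package: sorghet
Title: Heterotic Group Classification and Heterosis Analysis for Sorghum
    Line x Tester Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying heterotic groups of sorghum inbred lines
    from genome-wide SNP genotypes and for analysing heterosis in incomplete
    diallel (line x tester) field trials.  Computes identity-by-state genetic
    distances, neighbor-joining trees with bootstrap support and tree-based
    group assignment, per-locus allele-frequency differentiation scans and
    FST (Weir-Cockerham and Nei GST), general and specific combining ability
    with ANOVA variance components and heritabilities via a classed
    'linetester' model, mid-parent/high-parent heterosis and heterosis
    indices, phenotypic genetic distance, and correlation of heterosis with
    genetic distance and combining ability.  Includes a seeded
    Balding-Nichols simulator of two-group inbred genotypes and
    additive-plus-dominance diallel phenotypes with stored ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
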