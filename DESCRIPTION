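Package: sweepqtl
Title: Deficiency Mapping and Selective-Sweep Analysis of a Cold-Tolerance QTL
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable pipeline for dissecting a quantitative trait locus with
    combined quantitative and population genetics: quantitative complementation
    (deficiency) mapping by two-way ANOVA on log chill-coma recovery times with
    a directional failure-to-complement decision rule and overlapping-deletion
    interval refinement; missing-data-aware windowed diversity statistics
    (theta-pi, Watterson's theta, Dxy, Tajima's D, Nei-normalized FST); a
    SweepFinder-style composite likelihood ratio scan over an extended site
    frequency spectrum with a simulation-calibrated significance threshold; a
    per-SNP multi-population FST differentiation scan with latitudinal cline
    regression; and qPCR relative-expression analysis via calibrated normalized
    relative quantities (CNRQ). A synthetic-data module (coalescent simulator
    with recombination under piecewise-constant demography, sweep-spectrum site
    sampler, phenotype and Cq generators) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
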