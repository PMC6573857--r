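Package: depcr
Title: Primer Utilization Profiling for Deconstructed PCR Amplicon Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing primer utilization profiles (PUPs) from
    deconstructed PCR (DePCR) and standard targeted amplicon sequencing (TAS)
    experiments with degenerate 16S rRNA gene primers. Provides degenerate
    primer expansion with nearest-neighbor melting temperatures, a synthetic
    merged-read generator with an annealing-temperature-dependent primer
    choice model and ground-truth records, exact primer-variant counting with
    quality trimming and rarefaction, alpha diversity and Bray-Curtis
    dissimilarity, classical MDS ordination, one-way and two-way crossed
    ANOSIM permutation tests, per-feature Kruskal-Wallis testing, regression
    helpers, reference-based two-parent chimera detection, barcode design and
    demultiplexing, and an end-to-end annealing-temperature-gradient driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
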