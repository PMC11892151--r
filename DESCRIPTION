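Package: PanScreen
Title: High-Throughput Heterologous Enzyme Production Screening Across a
    Yeast Pan-Genome
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput screens of secreted
    heterologous enzyme production across large Saccharomyces cerevisiae
    strain libraries. Quantifies enzyme activity from microplate kinetic
    absorbance traces (linear-range detection and Beer-Lambert conversion),
    calls producer-strain hits with a robust median-absolute-deviation
    threshold, confirms hits against a reference strain with replicate
    tests, associates hits with pan-genome ORF presence/absence via exact
    tests (including compensated homolog pairs), builds neighbour-joining
    trees from strain distance matrices, computes comparative-Ct relative
    expression, and post-processes data-independent-acquisition proteome
    intensity matrices (replicate QC, median-scaling normalization,
    left-censored imputation, differential abundance, recurrence
    filtering). Includes seeded synthetic-data generators with planted
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
biocViews: Proteomics, Phylogenetics, QualityControl, Normalization,
    GenePrediction, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
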