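Package: ligrec
Title: Ligand-Receptor Co-Expression Shifts and Cell-Cell Communication
    Networks from Bulk and Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects altered intercellular (ligand-receptor) signaling from
    bulk tumor-versus-normal transcriptomes and extracts a directed
    cell-type-to-cell-type communication network from annotated single-cell
    expression. Provides a curated ligand-receptor pair database container
    with random-pair null sampling, an empirical-Bayes moderated
    t-statistic differential-expression stage with four-scenario pair
    classification, per-pair Spearman correlation analysis within each
    condition (with sum-over-receptors handling of non-bijective pairs),
    Kolmogorov-Smirnov distribution comparisons, classification of
    normal-to-cancer correlation shifts into gained/lost-correlation
    categories with a randomized-split noise-band calibration, infiltration
    quantile stratification, a mean-plus-k-sigma high-expression rule for
    calling directed communication edges with exclusiveness scoring, and a
    synthetic-data generator (Gaussian-copula bulk cohorts, negative-binomial
    single cells) with known planted structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    limma,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
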