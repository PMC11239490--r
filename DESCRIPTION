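Package: glycrunch
Title: Glycan Structure Prediction and Fragment Annotation for LC-MS/MS Glycomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated glycan structure elucidation from LC-MS/MS data.
    Glycans are modeled as rooted labeled trees parsed from IUPAC-condensed strings;
    theoretical fragment ions (Domon-Costello B/C/Y/Z and cross-ring A/X series) are
    enumerated exhaustively over all induced connected subgraphs and matched against
    observed MS/MS peaks with a tiered prioritization scheme. Spectra are binned into
    fixed-width m/z windows with per-bin remainder channels and classified by a dilated
    residual convolutional network trained with PolyLoss plus structure- and
    composition-distance losses. An inference pipeline groups precursors and retention
    time isomers, calibrates and filters predictions with domain rules, rescores them
    against a biosynthetic network, and extends them zero-shot to unseen structures.
    A synthetic-data module simulates in-silico fragmented spectra so the full stack
    runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    mzR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
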