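Package: clonotrack
Title: Longitudinal T-Cell Receptor Repertoire Analysis with Generation
    and Selection Probability Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of TCR-beta clonal repertoires
    from sorted T-cell subsets: UMI-based clonotype quantification from
    structured reads, dominant-clone tracking and persistence kinetics,
    Shannon-entropy diversity trends, public-clonotype detection with
    convergent-recombination counting and HLA stratification, antigen-database
    annotation, CDR3 k-mer motif enrichment, and a parameterised V(D)J
    recombination model with generation probabilities (P_GEN) plus a
    log-linear thymic-selection model (P_POST) with ratio-based flagging of
    putative escapees of negative selection. A synthetic cohort generator
    with full ground truth makes every stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
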