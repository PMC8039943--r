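Package: scganchor
Title: Anchor-Gene Co-Expression Discovery and Signature Scoring in
    Single-Cell and Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers genes co-expressed with an anchor gene in annotated
    single-cell transcriptomes using Tweedie exponential-dispersion
    generalized linear models with per-patient fixed-effect meta-analysis,
    builds dropout-robust anchor signature scores by binned-control
    centralization, projects the scores into bulk tissue, and runs the
    downstream association stages: modified-jackstraw permutation tests,
    minimum-hypergeometric ranked-list enrichment, over-representation
    analysis, tumor-microenvironment metagenes, ligand-receptor crosstalk
    mapping, and survival or response association. Includes a synthetic-data
    generator that emulates multi-patient single-cell structure with planted
    co-expression modules, magnitude-dependent dropout, housekeeping genes,
    bulk mixtures with tumor purity, and survival outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    fgsea,
    jsonlite,
    metafor,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
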