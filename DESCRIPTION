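Package: protrankr
Title: Rank-Based Differential Expression Analysis for Proteomic Data
    with Missing Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential expression analysis of proteomic and
    phosphoproteomic count tables that contain missing (zero) values.
    Implements the ProtRank approach: per-comparison log2 fold changes are
    converted to rank scores, comparisons involving a missing value receive
    a fixed virtual rank score instead of an imputed intensity, and scores
    are aggregated across groups of comparisons by a product of negative
    log rank scores optimised over all per-group direction assignments.
    Significance is assessed with a nonparametric bootstrap false discovery
    rate. Also provides a shift/scale log-normal imputation baseline, a
    zero-inflated synthetic count generator with planted differentially
    expressed genes, random-zero perturbation, and ranking evaluation
    utilities (precision/recall, ROC and precision-recall curves,
    zero-fraction and count-bin representation diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
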