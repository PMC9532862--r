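Package: spongenet
Title: Competing-Endogenous-RNA (ceRNA) Network Inference from Three-Layer
    RNA-Seq Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers circRNA-miRNA-mRNA competing-endogenous-RNA (ceRNA)
    networks from matched three-layer RNA-seq count matrices. Provides
    per-layer abundance normalization (RPM, TPM, FPKM), an exact
    conditional negative-binomial differential-expression test with
    layer-specific decision rules, canonical miRNA seed-site prediction
    that treats circRNAs as circular sequences (junction-spanning sites),
    correlation-based coexpression filtering (Spearman and Pearson),
    a hypergeometric shared-miRNA-sponge test, network assembly with
    degree-based hub ranking and top-k sub-network extraction, generic
    hypergeometric over-representation analysis, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
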