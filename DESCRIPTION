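Package: pathT2
Title: Knowledge-Based Hotelling-Type T2 Pathway Tests for Quantitative
    Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Self-contained multivariate pathway testing for quantitative
    proteomic expression ratios when only one (or very few) experiments are
    available. Instead of a sample covariance, a per-pathway covariance matrix
    is assembled from protein-protein interaction confidence scores (STRING or
    HitPredict style), signed by the observed expression directions; the
    Hotelling-type statistic T2 = x' S^-1 x is referred to a chi-squared
    distribution with degrees of freedom equal to the rank of S, using a
    Moore-Penrose pseudoinverse when S is degenerate. Includes ratio
    preprocessing (log2 transform, winsorization, multi-identifier median
    resolution, standardization, fold-change qualification), readers for GMT,
    KEGG KGML and Reactome gene-set dialects and scored interaction tables,
    delegate-based pathway-group integration to remove redundant subset
    pathways, permuted and purged-score robustness experiments, and synthetic
    fixture generators for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    xml2,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
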