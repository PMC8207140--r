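Package: crelearn
Title: Discovery and Modeling of Cis-Regulatory Elements from
    Co-Expression Regulons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for linking promoter cis-regulatory elements (CREs)
    to stress-responsive gene expression programs. Genes are clustered into
    co-expression regulons from log2-ratio expression matrices using a
    signed weighted correlation network and topological overlap; candidate
    motifs are discovered in TSS-anchored promoter windows by exhaustive
    k-mer enumeration scored with a length-normalized enrichment ratio and
    an upper-tail binomial test against genome-wide or random backgrounds;
    expression type is then modeled from binary motif presence/absence
    features using shadow-feature all-relevant selection and gradient
    boosted trees, and summarized with positional motif profiles,
    fold-change coverage ratios, and an interpretable YES/NO flowchart
    tree over motif presence. A synthetic data generator with planted
    class-specific promoter motifs and class-structured expression
    templates supports calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    pROC,
    rpart,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
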