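Package: coexdev
Title: Developmental Weighted Gene Coexpression Networks with Module
    Enrichment and Bootstrap Overlap Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds weighted gene coexpression networks per developmental
    age interval from log2 expression matrices: soft-threshold power
    selection by scale-free topology fit, topological overlap, dynamic
    tree cut module detection, module eigengenes and eigengene-trait
    correlations, cross-interval module label matching, hypergeometric
    gene-set (cell-type marker) enrichment with Bonferroni correction,
    and a bootstrap empirical-null overlap test of a gene-of-interest
    module against a disease risk-gene list. Includes a seeded synthetic
    data generator with planted module structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), mclust, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
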