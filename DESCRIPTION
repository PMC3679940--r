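Package: gilnet
Title: Gene Interaction Layer Compendia from Pre-Clustered Expression Samples
Version: 0.1.0
Authors@R:
    person("gilnet", "maintainers", email = "gilnet@example.org", role = c("aut", "cre"))
Description: Builds compendia of gene co-expression networks by pre-clustering
    expression samples with K-means, constructing one Pearson correlation
    network per sample cluster, choosing each network's hard threshold with a
    Random Matrix Theory scan of the eigenvalue nearest-neighbor spacing
    distribution, and detecting modules with Markov clustering and
    link-community detection. Includes per-cluster preprocessing (quantile
    normalization, control-probe, outlier-sample and ambiguous-probe removal),
    scale-free topology statistics, Fisher exact functional enrichment with
    Bonferroni control, keyword annotation of network layers, and a synthetic
    compendium generator with planted condition-specific modules for fully
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
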