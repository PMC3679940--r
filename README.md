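# gilnet

Gene co-expression network compendia from pre-clustered expression samples.

## The problem

Co-expression networks connect genes whose expression correlates across
samples. Public expression compendia mix thousands of samples from many
unlabeled conditions, and mixing dilutes condition-specific correlations: a
module co-regulated only in root tissue loses roughly a factor
`f` of its covariance when only a fraction `f` of samples come from root.
Under a single hard threshold the resulting "global" network is small and
blind to most condition-specific biology.

`gilnet` implements the pre-clustering answer: partition the samples by
K-means on their expression profiles (an unsupervised surrogate for condition
labels), then build one network per cluster — a **gene interaction layer
(GIL)** — each thresholded independently by Random Matrix Theory. The RMT
scan lowers the cutoff `t` on `|r|` until the eigenvalue nearest-neighbor
spacing distribution of the thresholded correlation matrix transitions from
Poisson (modular signal, `P(s) = e^-s`) to Gaussian-Orthogonal-Ensemble
statistics (noise, Wigner surmise `P(s) = (pi s/2) e^(-pi s^2/4)`); the
threshold is the last Poisson-like scan point. Each layer gets modules by
Markov clustering (MCL) and link-community detection, Fisher-exact/Bonferroni
functional enrichment, scale-free topology statistics
(`gamma_hat = 1 + n / sum(log(x / (xmin - 0.5)))`), and keyword annotation
from sample descriptions. A synthetic-compendium generator with planted
condition-specific modules (expected within-module correlation exactly
`b^2/(b^2 + sigma^2)`) makes the whole pipeline testable offline.

## Worked example

```r
library(gilnet)

sim <- simulate_compendium(seed = 42)   # 600 genes x 150 samples, 3 conditions
ann <- annotation_set("planted",
                      unlist(sim$truth$planted_modules, recursive = FALSE))

cp3 <- build_compendium(sim$expression, K = 3, seed = 42,
                        annotations = ann, config = list(modules = "mcl"))
cp1 <- build_compendium(sim$expression, K = 1, seed = 42,
                        annotations = ann, config = list(modules = "mcl"))
cp3
#> GILCompendium: K = 3, 3/3 layers built
capture_curve(list(cp1, cp3))
#>   K n_built success_rate unique_nodes unique_edges
#> 1 1       0            0            0            0
#> 2 3       3            1          396         2989
```

With `K = 3` the three layers recover the planted condition-specific
structure (396 unique genes, 2,989 unique co-expression edges, all 9 planted
modules enriched); the `K = 1` global network finds nothing, because the
3-fold condition dilution pushes within-module correlations (0.59 inside a
condition) down to ~0.27, below any Poisson-like threshold. One layer in
detail:

```r
g <- cp3$gils[[1]]
sprintf("t* = %.3f, n = %d, m = %d, <k> = %.2f", g$network$threshold,
        g$topology$n_nodes, g$topology$n_edges, g$topology$avg_degree)
#> "t* = 0.576, n = 118, m = 645, <k> = 10.93"
length(unique_enriched_terms(cp3, "mcl"))   # 9
length(unique_enriched_terms(cp1, "mcl"))   # 0
```

`t*` is the RMT-chosen correlation threshold for that layer; `n`, `m` and
`<k> = 2m/n` are its node count, edge count and average degree; the enriched
term counts show that every planted module is rediscovered as significantly
enriched (Bonferroni p < 0.001) somewhere in the K = 3 compendium and nowhere
in the global network.

A command-line interface wrapping the same pipeline lives in
`inst/cli/gilnet.R` (subcommands `simulate`, `partition`, `build`, `sweep`).

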