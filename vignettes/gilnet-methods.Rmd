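---
title: "Gene interaction layers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene interaction layers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the method

A gene co-expression network connects genes whose expression profiles are
strongly correlated across a set of samples. When the samples span many
biological conditions (tissues, genotypes, treatments), mixing them attenuates
condition-specific correlations toward zero: a module that is tightly
co-regulated in root tissue contributes nothing in the leaf samples, so its
mixed-sample correlation is diluted roughly by the fraction of samples in
which the module is active. A single hard threshold applied to the mixed
correlation matrix therefore discards most condition-specific structure and
yields a small network.

`gilnet` implements the pre-clustering strategy: samples are first partitioned
into `K` groups by K-means on their expression profiles (a knowledge-free
surrogate for condition labels), and one network — a *gene interaction layer*
(GIL) — is built per group, each with its own threshold chosen by Random
Matrix Theory (RMT). The union of layers captures far more genes and edges
than the single global network, and each layer's threshold adapts to its own
signal level ("dynamic thresholding").

The per-cluster pipeline is: control-probe removal, outlier-sample removal
(fail 2 of 3 tests), ambiguous-probe removal, quantile normalization, Pearson
correlation, RMT thresholding, network extraction, probe-to-gene collapse,
and module detection by Markov clustering (MCL, a node partition) and
link-community detection (LCM, overlapping gene sets).

## RMT thresholding

The threshold scan relies on a universality result: eigenvalue
nearest-neighbor spacings of a matrix dominated by uncorrelated noise follow
Gaussian-Orthogonal-Ensemble statistics (level repulsion, Wigner surmise
`P(s) = (pi s / 2) exp(-pi s^2 / 4)`), while a matrix whose surviving entries
encode modular, near-block-diagonal signal has uncorrelated spectra with
Poisson (exponential) spacings. Scanning the cutoff `t` downward from 0.99,
the spectrum of the thresholded matrix stays Poisson-like while only signal
survives and turns GOE-like once noise correlations flood in; the chosen
threshold `t*` is the last scan point before the first chi-square exceedance.

Numerical choices, all exposed as arguments:

* scan 0.99 to 0.50 in steps of 0.001; spectra are computed on the submatrix
  of rows with at least one off-diagonal `|r| >= t`;
* spectra are *unfolded* (monotone cubic spline through every 10th point of
  the cumulative spectral count, rescaled to unit mean spacing) so that only
  fluctuation statistics remain;
* eigenvalues are deduplicated at `1e-8` — degenerate eigenvalues would
  contribute spurious zero spacings;
* the spacing histogram uses 60 bins on `[0, 3]` and is tested against the
  exponential law with a chi-square cutoff of 99.607 (the 0.001 upper-tail
  point at 60 degrees of freedom);
* at least 100 distinct eigenvalues and 10 samples are required; clusters
  below these minimums are reported `"n.a."`, mirroring layers that "did not
  construct" on real data. A cluster whose very first testable scan point is
  already GOE-like fails with `"never Poisson-like"`.

The threshold is applied to `|r|`: RMT operates on magnitude structure, and
the signed correlation is preserved on the retained edges.

With about 100 eigenvalues the chi-square statistic is noisy, so the scan
sometimes stops one step after its first testable point, giving a
conservative (high) threshold; on planted-signal benchmarks this costs some
edge recall but never admits noise edges. This variability is inherent to the
small-matrix regime, not to the implementation.

## Module detection

**MCL** alternates expansion (matrix squaring) and inflation (entrywise power
2.0, column renormalization, pruning below `1e-5`) on the column-stochastic
flow matrix built from `|r|` weights plus unit self-loops, until idempotence;
clusters are connected components of the attractor support and partition the
node set. The inflation and pruning defaults are the conventional ones of the
standalone MCL tool this re-implements.

**Link communities** cluster *edges*: for two edges sharing node `k`, the
similarity of the non-shared endpoints' inclusive neighborhoods
(`Jaccard({i} + N(i), {j} + N(j))`) feeds single-linkage hierarchical
clustering on `1 - S`; the dendrogram is cut at the height maximizing the
partition density

`D = (2/M) * sum_c m_c (m_c - (n_c - 1)) / ((n_c - 2)(n_c - 1))`,

with communities of `n_c <= 2` contributing zero and ties resolved toward the
lower height. Edge communities partition the edge set while genes may appear
in many modules — the representation suited to genes shared between pathways.
Single-edge communities are kept in the edge partition but excluded from
module-count and coverage summaries.

## Enrichment and topology

Functional enrichment is the one-sided hypergeometric upper tail
`P(X >= k)` for the overlap `k` between a module (size `n`) and a term
(size `K` within the background `N`), Bonferroni-corrected within each
module's family of tested terms (per-module, DAVID-style; a global
modules-by-terms family is available via `family = "global"`) and called
significant below adjusted `p < 0.001`. Modules with fewer than 3 genes are
skipped: a 2-gene Fisher table cannot reach meaningful significance, even
though 2-gene modules are themselves reported.

The scale-free exponent uses the continuous-approximation maximum-likelihood
estimator `gamma_hat = 1 + n / sum(log(x / (xmin - 0.5)))` on the degree tail
`x >= xmin`. This approximation is only consistent when `xmin` is well above
1 (at `xmin = 1` on discrete data its bias reaches -0.8 at `gamma = 3`, which
we verified against the exact discrete MLE); recovery tests therefore use
`xmin = 10`, where measured bias is below 0.015 and RMSE below 0.04.

## The synthetic compendium

`simulate_compendium()` generates the world every test runs against:

* `n_samples` split evenly across `n_conditions`; per-gene baselines
  `mu_g ~ N(8, 2)` on the log2 scale of summarized microarray data;
* each condition owns `modules_per_condition` disjoint planted modules of
  `module_size` genes; for module genes in their condition's samples,
  `x = mu + eta + b z_s + eps` with a per-sample standard-normal factor
  `z_s`, noise `eps ~ N(0, sigma^2)`, giving expected within-module,
  within-condition correlation exactly `b^2 / (b^2 + sigma^2)`;
* every gene additionally carries a condition signature
  `eta_gc ~ N(0, tau^2)` (`condition_sd`, default 0.5) — the
  tissue/treatment-specific baseline that makes samples of a condition
  resemble each other. A pure latent-factor model is *not* clusterable: with
  a mean-zero per-sample factor, same-condition and cross-condition sample
  pairs have identical expected Euclidean distance, so K-means could never
  recover conditions. The signature is constant within a condition, so it
  leaves within-cluster correlations (and the closed form above) untouched,
  while its mixed-sample correlations are attenuated by
  `tau^2 / (tau^2 + sigma^2)` (0.2 at the defaults), far below any hard
  threshold;
* sample descriptions embed one condition keyword ("root", "leaf", ...) so
  the keyword-annotation path is testable end to end.

Defaults — 600 genes, 150 samples, 3 conditions, 3 modules of 40 genes per
condition, `b = 1.2`, `sigma = 1`, `tau = 0.5` — are chosen so the world
actually exhibits the phenomenon the method addresses: within-condition
module correlation is `1.44/2.44 = 0.59`, above the scan floor of 0.50,
while the 3-fold-diluted mixed-condition correlation
`(b^2/3)/(b^2/3 + sigma^2 + 2tau^2/3) ~ 0.27` falls below it. Pure-condition
clusters therefore yield networks, while randomized or unpartitioned sample
sets lose the planted modules. The module count and size ensure one
condition's 120 planted genes exceed the 100-eigenvalue minimum of the RMT
test. The generator does not emulate probe-level intensity distributions,
batch effects, or heavy-tailed expression noise; a green end-to-end test
establishes that the pipeline recovers planted linear-correlation structure
under Gaussian noise, not that it handles every artifact of real arrays.

## Randomization control and ordering

`randomize_partition()` re-assigns a fraction of samples by permuting their
cluster labels among themselves, preserving the cluster-size multiset
exactly. On the synthetic world, 100% randomization turns every cluster into
a condition mixture; the count of unique significantly enriched terms at 0%
randomization is at least the count at 100% in the large majority of seeds
(the end-to-end acceptance test asserts at least 8 of 10), reproducing the
homogenization effect of destroying condition grouping. Layers are ordered by
average-linkage clustering on shared link-community gene counts, and a
permutation test (statistic: adjacent layer pairs sharing a keyword; 1,000
permutations) checks whether keyword placement along the ordering is
non-random; the statistic and permutation count are this package's choices,
as no standard test exists for this question.

## Known limitations

* The outlier battery is a stand-in for the original array-quality tool's
  three tests (inter-array distance, distribution shift via
  Kolmogorov-Smirnov, deviation from a row-median pseudo-reference, Tukey
  fences, fail-2-of-3); the original tool's exact tests and versions are not
  reproducible from the publication.
* Quantile normalization of the summarized matrix replaces probe-level RMA:
  this package consumes expression matrices, not CEL files.
* K-means is Lloyd's algorithm with 10 random restarts and farthest-point
  re-seeding of empty clusters — a deliberately simple, fully deterministic
  variant (Hartigan-Wong typically reaches slightly lower inertia).
* The RMT scan bounds, histogram and critical value are the conventional
  defaults of the method's reference implementations; all are arguments and
  can be tightened for larger matrices.
* Sequential scan points share most of their spectrum, so the chi-square
  trajectory is autocorrelated; the first-exceedance rule can be triggered by
  a single noisy point (conservative thresholds on small matrices).
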