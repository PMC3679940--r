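#' One-sided Fisher exact (hypergeometric) enrichment p-value
#'
#' Upper-tail probability `P(X >= k)` of drawing at least `k` term genes when
#' sampling `n = |module|` genes without replacement from a background of
#' `N` genes containing `K = |term in background|` term genes. The term is
#' restricted to the background before testing; the module is expected to be
#' a subset of the background (genes outside it are ignored).
#'
#' @param module_genes,term_genes,background character vectors of gene ids.
#' @return The p-value in (0, 1]; an empty module or empty term-in-background
#'   returns 1 with a warning.
#' @export
#' @examples
#' # 3 of 4 term genes inside a module of 5 drawn from 20: 496/15504
#' fisher_enrichment(paste0("g", 1:5), paste0("g", c(1:3, 6)), paste0("g", 1:20))
fisher_enrichment <- function(module_genes, term_genes, background) {
  background <- unique(background)
  module <- intersect(unique(module_genes), background)
  term <- intersect(unique(term_genes), background)
  if (length(module) == 0 || length(term) == 0) {
    warning("empty module or term within background: p = 1")
    return(1)
  }
  k <- length(intersect(module, term))
  phyper(k - 1, length(term), length(background) - length(term),
         length(module), lower.tail = FALSE)
}

#' Bonferroni adjustment
#' @param p p-value(s).
#' @param family_size number of tests in the family (>= 1).
#' @return `min(1, p * family_size)`, vectorized over `p`.
#' @export
bonferroni <- function(p, family_size) {
  stopifnot(family_size >= 1)
  pmin(1, p * family_size)
}

#' Functional term enrichment of every module against a background
#'
#' Fisher exact upper-tail test of each annotation term in each module versus
#' the gene background, Bonferroni-adjusted. By default the family is the
#' number of terms tested for a module within one vocabulary (the per-module
#' correction of DAVID-style tools); `family = "global"` multiplies by
#' modules x terms instead. Modules below `min_module_size` genes are skipped
#' (Fisher tables on 1-2 genes are uninformative).
#'
#' @param ms a `ModuleSet`.
#' @param annotations an `AnnotationSet` ([read_annotations_gmt()]).
#' @param background character vector: the measurable-gene universe.
#' @param alpha significance level on the adjusted p-value (default 0.001).
#' @param min_module_size smallest module tested (default 3).
#' @param family `"per_module"` (default) or `"global"`.
#' @return Data frame with one row per (module, term) test: `module_id`,
#'   `term_id`, `vocabulary`, `description`, `k`, `K`, `n`, `N`, `p`,
#'   `p_adj`, `significant`.
#' @export
enrich_modules <- function(ms, annotations, background, alpha = 0.001,
                           min_module_size = 3L,
                           family = c("per_module", "global")) {
  family <- match.arg(family)
  background <- unique(background)
  N <- length(background)
  terms <- lapply(annotations$genes, intersect, y = background)
  terms <- terms[lengths(terms) > 0]
  modules <- lapply(ms$modules, intersect, y = background)
  modules <- modules[lengths(modules) >= min_module_size]
  n_family <- if (family == "global") {
    length(terms) * length(modules)
  } else {
    length(terms)
  }
  rows <- vector("list", length(modules) * length(terms))
  ri <- 0L
  for (mid in names(modules)) {
    mod <- modules[[mid]]
    n <- length(mod)
    for (tid in names(terms)) {
      tg <- terms[[tid]]
      k <- length(intersect(mod, tg))
      p <- phyper(k - 1, length(tg), N - length(tg), n, lower.tail = FALSE)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        module_id = mid, term_id = tid,
        vocabulary = annotations$vocabulary,
        description = unname(annotations$descriptions[tid]),
        k = k, K = length(tg), n = n, N = N, p = p,
        stringsAsFactors = FALSE
      )
    }
  }
  if (ri == 0L) {
    return(data.frame(module_id = character(), term_id = character(),
                      vocabulary = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), p_adj = numeric(),
                      significant = logical()))
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  out$p_adj <- bonferroni(out$p, max(1L, n_family))
  out$significant <- out$p_adj < alpha
  out
}
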