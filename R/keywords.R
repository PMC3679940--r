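tokenize_descriptions <- function(descriptions, stoplist = character(),
                                  min_length = 3L) {
  words <- unlist(strsplit(gsub("[^a-z0-9]+", " ",
                                tolower(descriptions)), " +"))
  words <- words[nchar(words) >= min_length]
  words[!(words %in% tolower(stoplist))]
}

#' Assign descriptive keywords to each layer from sample descriptions
#'
#' Tokenizes the free-text experiment descriptions of the samples in each
#' layer (ASCII lowercase, split on non-alphanumerics, words shorter than 3
#' characters dropped), removes stoplist words (the "uninformative word"
#' custom dictionary), and returns the `top_n` most frequent words per layer,
#' ties broken alphabetically.
#'
#' @param descriptions_by_gil named list: layer id -> character vector of
#'   sample descriptions.
#' @param stoplist words to drop (case-insensitive).
#' @param top_n keywords per layer (default 10).
#' @return Named list of character vectors (possibly shorter than `top_n`).
#' @export
assign_keywords <- function(descriptions_by_gil, stoplist = character(),
                            top_n = 10L) {
  lapply(descriptions_by_gil, function(desc) {
    words <- tokenize_descriptions(desc, stoplist)
    if (length(words) == 0) return(character(0))
    counts <- table(words)
    ord <- order(-as.integer(counts), names(counts))
    head(names(counts)[ord], top_n)
  })
}

#' Keyword lists for the layers of a compendium
#'
#' Convenience wrapper around [assign_keywords()] using the sample metadata
#' and each built layer's sample membership.
#'
#' @param compendium a `GILCompendium`.
#' @param metadata sample metadata ([read_sample_metadata()]).
#' @param stoplist,top_n see [assign_keywords()].
#' @return Named list (built layers only).
#' @export
compendium_keywords <- function(compendium, metadata,
                                stoplist = character(), top_n = 10L) {
  gils <- built_gils(compendium)
  descs <- lapply(gils, function(g) {
    metadata$description[match(g$sample_ids, metadata$sample_id)]
  })
  assign_keywords(descs, stoplist = stoplist, top_n = top_n)
}

#' Ratio of pattern-matching enriched terms between keyword and non-keyword layers
#'
#' Layers are split by whether `keyword` appears in their assigned keyword
#' list; the number of significant enriched-term descriptions matching
#' `pattern` (case-insensitive substring) is counted in each group. The
#' default ratio is normalized per layer:
#' `(count_kw / n_kw) / (count_non / n_non)`; `raw = TRUE` returns the plain
#' count ratio. A zero non-keyword count with a positive keyword count is
#' reported as `Inf`; an empty group is an error.
#'
#' @param keywords_by_gil named list of keyword vectors per layer.
#' @param enriched_descriptions_by_gil named list (same names): character
#'   vector of significant enriched-term descriptions per layer.
#' @param keyword the grouping keyword.
#' @param pattern substring counted in the term descriptions.
#' @param raw use raw counts instead of per-layer normalization.
#' @return Single number (possibly `Inf`).
#' @export
keyword_enrichment_ratio <- function(keywords_by_gil,
                                     enriched_descriptions_by_gil,
                                     keyword, pattern, raw = FALSE) {
  ids <- names(keywords_by_gil)
  stopifnot(!is.null(ids), setequal(ids, names(enriched_descriptions_by_gil)))
  has_kw <- vapply(keywords_by_gil, function(k) keyword %in% k, logical(1))
  if (!any(has_kw) || all(has_kw)) {
    stop("both keyword and non-keyword groups must be non-empty")
  }
  count_group <- function(sel) {
    sum(vapply(enriched_descriptions_by_gil[sel], function(d) {
      sum(grepl(pattern, d, ignore.case = TRUE, fixed = FALSE))
    }, numeric(1)))
  }
  c_kw <- count_group(has_kw)
  c_non <- count_group(!has_kw)
  if (c_non == 0) return(if (c_kw > 0) Inf else NaN)
  if (raw) c_kw / c_non else
    (c_kw / sum(has_kw)) / (c_non / sum(!has_kw))
}

#' Order layers by shared link-community gene content
#'
#' Similarity between two layers is the number of genes covered by both
#' layers' link-community modules; layers are ordered by average-linkage
#' hierarchical clustering on `max(similarity) - similarity`.
#'
#' @param lcm_genes_by_gil named list: layer id -> character vector of genes
#'   covered by that layer's link communities (>= 2 layers).
#' @return List with `order` (layer ids in leaf order), `similarity`
#'   (symmetric matrix; diagonal is each layer's own covered-gene count) and
#'   `hclust` (the tree).
#' @export
order_gils <- function(lcm_genes_by_gil) {
  ids <- names(lcm_genes_by_gil)
  stopifnot(length(ids) >= 2)
  n <- length(ids)
  sim <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- length(intersect(lcm_genes_by_gil[[i]], lcm_genes_by_gil[[j]]))
      sim[i, j] <- s
      sim[j, i] <- s
    }
  }
  d <- max(sim) - sim
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  list(order = ids[hc$order], similarity = sim, hclust = hc)
}

#' Permutation test for non-random keyword placement along a layer ordering
#'
#' Statistic: number of adjacent leaf pairs sharing at least one keyword.
#' The p-value compares the observed ordering with `n_perm` uniform
#' permutations of the layers (add-one correction).
#'
#' @param order layer ids in leaf order.
#' @param keywords_by_gil named list of keyword vectors.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return List with `statistic` and `p_value`.
#' @export
keyword_order_test <- function(order, keywords_by_gil, n_perm = 1000L,
                               seed = 1L) {
  stat <- function(ord) {
    sum(vapply(seq_len(length(ord) - 1L), function(i) {
      length(intersect(keywords_by_gil[[ord[i]]],
                       keywords_by_gil[[ord[i + 1L]]])) > 0
    }, logical(1)))
  }
  obs <- stat(order)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(order)), numeric(1))
  list(statistic = obs, p_value = (1 + sum(perm >= obs)) / (n_perm + 1))
}
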