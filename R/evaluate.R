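default_config <- function() {
  list(
    control_prefixes = "AFFX",
    remove_outliers = TRUE,
    min_samples = 10L,
    n_init = 10L,
    max_iter = 300L,
    t_start = 0.99, t_stop = 0.50, step = 0.001,
    chi_crit = 99.607, min_eigenvalues = 100L,
    inflation = 2, pruning = 1e-5,
    modules = c("mcl", "lcm"),
    alpha = 0.001, min_module_size = 3L
  )
}

# one cluster -> one gene interaction layer; classed unbuildable conditions
# become "n.a." entries upstream.
build_gil <- function(Xc, cfg, probe_map, annotations, background,
                      provenance) {
  if (cfg$remove_outliers && ncol(Xc) >= 4) {
    Xc <- drop_outlier_samples(Xc)
  }
  if (!is.null(probe_map)) {
    Xc <- drop_ambiguous_probes(Xc, probe_map)
    if (nrow(Xc) == 0) unbuildable("no unambiguous probes")
  }
  if (ncol(Xc) < 2) unbuildable("too few samples (< 2)")
  Xc <- quantile_normalize(Xc)
  S <- pearson_matrix(Xc, min_samples = cfg$min_samples)
  rmt <- rmt_threshold(S, t_start = cfg$t_start, t_stop = cfg$t_stop,
                       step = cfg$step, chi_crit = cfg$chi_crit,
                       min_eigenvalues = cfg$min_eigenvalues)
  if (!rmt$success) unbuildable(rmt$failure_reason)
  net <- extract_network(S, rmt$threshold, provenance = provenance)
  if (!is.null(probe_map)) net <- collapse_probes_to_genes(net, probe_map)
  if (nrow(net$edges) == 0) unbuildable("no edges at the chosen threshold")
  gil <- list(status = "built", reason = NA_character_, network = net,
              rmt = rmt, sample_ids = colnames(Xc),
              topology = degree_stats(net))
  if ("mcl" %in% cfg$modules) {
    gil$mcl <- mcl(net, inflation = cfg$inflation, pruning = cfg$pruning)
    if (!is.null(annotations)) {
      gil$enrichment_mcl <- enrich_modules(
        gil$mcl, annotations, background,
        alpha = cfg$alpha, min_module_size = cfg$min_module_size)
    }
  }
  if ("lcm" %in% cfg$modules) {
    gil$lcm <- link_communities(net)
    if (!is.null(annotations)) {
      gil$enrichment_lcm <- enrich_modules(
        gil$lcm$module_set, annotations, background,
        alpha = cfg$alpha, min_module_size = cfg$min_module_size)
    }
  }
  gil
}

#' Build a gene interaction layer compendium for one K
#'
#' Runs the whole pipeline: control-probe removal, K-means partitioning of
#' samples (or a supplied partition), then per cluster — outlier-sample
#' removal, ambiguous-probe removal, quantile normalization, Pearson
#' similarity, RMT threshold detection, network extraction, probe-to-gene
#' collapse, module detection and enrichment. Clusters that fail any size
#' minimum or the RMT scan are recorded `"n.a."` with their reason; a failed
#' cluster never aborts the compendium. Fully deterministic given `seed`.
#'
#' `K = 1` reduces to the classical global network built from all samples.
#'
#' @param X an [expression_matrix()].
#' @param K number of sample clusters.
#' @param seed integer seed (drives K-means).
#' @param partition optional pre-computed `SamplePartition` (e.g. a
#'   randomized control); overrides K-means.
#' @param probe_map optional probe-to-gene map; when given, networks are
#'   collapsed to gene level and ambiguous probes dropped.
#' @param annotations optional `AnnotationSet` for per-module enrichment.
#' @param background gene universe for enrichment; defaults to all (mapped)
#'   row identifiers.
#' @param config named list overriding entries of the default configuration
#'   (scan bounds, minimum sizes, module methods, ...).
#' @return A `GILCompendium`: list with `K`, `seed`, `partition`, `gils`
#'   (one entry per cluster: `status`, `reason`, `network`, `rmt`, `mcl`,
#'   `lcm`, enrichment tables, `topology`, `sample_ids`) and `config`.
#' @export
build_compendium <- function(X, K, seed = 1L, partition = NULL,
                             probe_map = NULL, annotations = NULL,
                             background = NULL, config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  X <- drop_control_probes(X, cfg$control_prefixes)
  if (is.null(partition)) {
    partition <- kmeans_partition(X, K, seed = seed, n_init = cfg$n_init,
                                  max_iter = cfg$max_iter)
  }
  stopifnot(partition$K == K)
  if (is.null(background)) {
    background <- if (is.null(probe_map)) {
      rownames(X)
    } else {
      unique(unlist(probe_map[rownames(X)], use.names = FALSE))
    }
  }
  gils <- vector("list", K)
  names(gils) <- sprintf("GIL%03d", seq_len(K))
  for (k in seq_len(K)) {
    cols <- names(partition$assignment)[partition$assignment == k]
    prov <- list(cluster = k, K = K, seed = seed, samples = cols)
    gils[[k]] <- tryCatch(
      build_gil(expression_matrix(unclass(X)[, cols, drop = FALSE],
                                  rownames(X), cols),
                cfg, probe_map, annotations, background, prov),
      gilnet_unbuildable = function(e) {
        list(status = "n.a.", reason = conditionMessage(e), network = NULL,
             sample_ids = cols)
      }
    )
  }
  structure(list(K = as.integer(K), seed = as.integer(seed),
                 partition = partition, gils = gils, config = cfg,
                 background = background),
            class = "GILCompendium")
}

#' @export
print.GILCompendium <- function(x, ...) {
  built <- sum(vapply(x$gils, function(g) g$status == "built", logical(1)))
  cat(sprintf("GILCompendium: K = %d, %d/%d layers built\n",
              x$K, built, x$K))
  invisible(x)
}

built_gils <- function(compendium) {
  Filter(function(g) identical(g$status, "built"), compendium$gils)
}

#' Unique node and edge unions of a compendium
#'
#' Unions are taken over built layers only; edges are canonical unordered
#' pairs so equality is independent of construction order.
#'
#' @param compendium a `GILCompendium`.
#' @return List with `nodes` (character) and `edges` (character keys
#'   `"a|b"`).
#' @export
compendium_capture <- function(compendium) {
  nets <- lapply(built_gils(compendium), `[[`, "network")
  nodes <- sort(unique(unlist(lapply(nets, `[[`, "nodes"))))
  edges <- sort(unique(unlist(lapply(nets, function(n) {
    if (nrow(n$edges) == 0) character(0) else
      paste(n$edges$a, n$edges$b, sep = "|")
  }))))
  list(nodes = nodes, edges = edges)
}

#' Node/edge capture curve across compendia
#'
#' @param compendia list of `GILCompendium` objects (one per K).
#' @return Data frame with one row per compendium: `K`, `n_built`,
#'   `success_rate`, `unique_nodes`, `unique_edges`.
#' @export
capture_curve <- function(compendia) {
  stopifnot(length(compendia) >= 1)
  do.call(rbind, lapply(compendia, function(cp) {
    cap <- compendium_capture(cp)
    built <- length(built_gils(cp))
    data.frame(K = cp$K, n_built = built, success_rate = built / cp$K,
               unique_nodes = length(cap$nodes),
               unique_edges = length(cap$edges))
  }))
}

#' Percent of a measurable-gene universe captured
#' @param n_captured,n_measurable counts.
#' @return Percentage rounded to one decimal.
#' @export
#' @examples
#' coverage_percent(19588, 20677)  # 94.7
coverage_percent <- function(n_captured, n_measurable) {
  stopifnot(n_measurable > 0)
  round(100 * n_captured / n_measurable, 1)
}

#' Mean arrays per cluster
#' @param n_samples,K counts.
#' @return `n_samples / K` rounded to one decimal.
#' @export
#' @examples
#' mean_cluster_size(7105, 90)  # 78.9
mean_cluster_size <- function(n_samples, K) round(n_samples / K, 1)

#' Fold improvement in unique enriched terms
#' @param n_layered,n_global unique significant term counts for the layered
#'   compendium and the global network.
#' @return The unrounded ratio.
#' @export
term_fold_improvement <- function(n_layered, n_global) {
  stopifnot(n_global > 0)
  n_layered / n_global
}

#' Summary record for one compendium
#'
#' @param compendium a `GILCompendium`.
#' @param n_measurable size of the measurable-gene universe (the coverage
#'   denominator, e.g. the number of genes the platform interrogates; taken
#'   as an explicit parameter since reasonable tallies differ).
#' @param metadata optional sample metadata (for series statistics).
#' @return List with capture counts, `coverage_percent`,
#'   `mean_arrays_per_cluster`, success rate, and per-layer array/series
#'   means and standard deviations.
#' @export
compendium_summary <- function(compendium, n_measurable, metadata = NULL) {
  stopifnot(n_measurable > 0)
  cap <- compendium_capture(compendium)
  built <- built_gils(compendium)
  m <- length(compendium$partition$assignment)
  arrays <- vapply(built, function(g) length(g$sample_ids), numeric(1))
  series <- if (!is.null(metadata)) {
    vapply(built, function(g) {
      length(unique(metadata$series_id[match(g$sample_ids,
                                             metadata$sample_id)]))
    }, numeric(1))
  } else {
    NULL
  }
  list(
    K = compendium$K,
    n_built = length(built),
    success_rate = length(built) / compendium$K,
    unique_nodes = length(cap$nodes),
    unique_edges = length(cap$edges),
    coverage_percent = coverage_percent(length(cap$nodes), n_measurable),
    mean_arrays_per_cluster = mean_cluster_size(m, compendium$K),
    arrays_mean = if (length(arrays)) mean(arrays) else NA_real_,
    arrays_sd = if (length(arrays) > 1) sd(arrays) else NA_real_,
    series_mean = if (!is.null(series)) mean(series) else NA_real_,
    series_sd = if (!is.null(series) && length(series) > 1) sd(series)
                else NA_real_
  )
}

#' Linear extrapolation of the interactome beyond measured genes
#'
#' `floor(unique_edges * measurable_genes / captured_genes)` — the simple
#' scaling used to extend an edge count to genes the platform does not
#' measure.
#'
#' @param unique_edges,captured_genes,measurable_genes counts.
#' @return Integer-valued count.
#' @export
#' @examples
#' extrapolate_interactome(558022, 19588, 20677)  # 589045
extrapolate_interactome <- function(unique_edges, captured_genes,
                                    measurable_genes) {
  stopifnot(captured_genes > 0)
  floor(unique_edges * measurable_genes / captured_genes)
}

#' Overlap of two canonical edge sets
#'
#' @param a,b character vectors of canonical edge keys (e.g. `"g1|g2"` with
#'   `g1 < g2`).
#' @return List with `count` = `|a & b|` and `percent_of_b` =
#'   `100 |a & b| / |b|` to one decimal (`NA` when `b` is empty).
#' @export
#' @examples
#' edge_overlap(paste0("e", 1:237), paste0("e", 1:11374))$percent_of_b  # 2.1
edge_overlap <- function(a, b) {
  count <- length(intersect(unique(a), unique(b)))
  list(count = count,
       percent_of_b = if (length(b) == 0) NA_real_ else
         round(100 * count / length(unique(b)), 1))
}

#' Unique significant enriched terms across a compendium
#'
#' @param compendium a `GILCompendium` built with annotations.
#' @param method `"mcl"` or `"lcm"` enrichment tables.
#' @return Character vector of unique significant term ids.
#' @export
unique_enriched_terms <- function(compendium, method = c("mcl", "lcm")) {
  method <- match.arg(method)
  field <- paste0("enrichment_", method)
  sort(unique(unlist(lapply(built_gils(compendium), function(g) {
    tab <- g[[field]]
    if (is.null(tab)) character(0) else tab$term_id[tab$significant]
  }))))
}
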