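#' Construct an expression matrix
#'
#' A genes-by-samples numeric matrix (log-scale expression) with unique row
#' (gene/probe) and column (sample) identifiers. Missing values are allowed
#' and must be handled explicitly downstream.
#'
#' @param values numeric matrix.
#' @param gene_ids,sample_ids identifiers; default to existing dimnames.
#' @return The matrix with class `ExpressionMatrix` and dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required")
  }
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier length does not match matrix dimensions")
  }
  check_unique(gene_ids, "gene")
  check_unique(sample_ids, "sample")
  if (any(is.infinite(values))) stop("expression values must be finite or NA")
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("ExpressionMatrix", "matrix", "array")
  values
}

check_unique <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(unique(dup), collapse = ", ")))
  }
  invisible(ids)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene or
#' probe identifiers. Cells equal to `missing_token` become `NA`. Duplicate
#' identifiers and ragged rows are hard errors.
#'
#' @param path file path.
#' @param missing_token text that marks a missing value (default `"NA"`).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, missing_token = "NA") {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty expression file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  sample_ids <- header[-1]
  body <- fields[-1]
  widths <- lengths(body)
  bad <- which(widths != n_col)
  if (length(bad) > 0) {
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad[1] + 1L, widths[bad[1]], n_col))
  }
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1L)
  for (i in seq_along(body)) {
    cells <- body[[i]][-1]
    cells[cells == missing_token] <- NA
    vals[i, ] <- suppressWarnings(as.numeric(cells))
    notnum <- which(!is.na(cells) & is.na(vals[i, ]))
    if (length(notnum) > 0) {
      stop(sprintf("non-numeric value '%s' at line %d", cells[notnum[1]], i + 1L))
    }
  }
  expression_matrix(vals, gene_ids, sample_ids)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; values are printed with full
#' precision so a read round-trip reproduces them exactly.
#'
#' @param X an [expression_matrix()].
#' @param path file path.
#' @param missing_token text to print for `NA` cells.
#' @export
write_expression_matrix <- function(X, path, missing_token = "NA") {
  vals <- format(unclass(X), digits = 17, trim = TRUE, scientific = FALSE)
  vals[is.na(unclass(X))] <- missing_token
  lines <- c(
    paste(c("gene_id", colnames(X)), collapse = "\t"),
    paste(rownames(X), apply(vals, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' TSV with columns `probe<TAB>gene`, one row per mapping; a probe may map to
#' zero (absent) or several genes (ambiguous).
#'
#' @param path file path.
#' @return Named list: probe id -> character vector of gene ids.
#' @export
read_probe_gene_map <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   col.names = c("probe", "gene"))
  map <- lapply(split(df$gene, df$probe), unique)
  map[order(names(map))]
}

#' Read gene annotation sets in GMT format
#'
#' Each line is `term<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within one term are deduplicated; a line with fewer than three fields is an
#' error naming the line number. An empty file yields an empty set.
#'
#' @param path file path.
#' @param vocabulary label for the source vocabulary (e.g. `"GO"`).
#' @return A list with elements `vocabulary`, `descriptions` (named character)
#'   and `genes` (named list of character vectors), class `AnnotationSet`.
#' @export
read_annotations_gmt <- function(path, vocabulary) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  genes <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("GMT line %d has %d field(s), expected at least 3",
                   i, length(f)))
    }
    if (f[1] %in% names(genes)) {
      stop("duplicate term identifier: ", f[1])
    }
    g <- unique(f[-(1:2)])
    g <- g[nzchar(g)]
    if (length(g) == 0) stop(sprintf("GMT line %d: term %s has no genes", i, f[1]))
    genes[[f[1]]] <- g
    descriptions[f[1]] <- f[2]
  }
  structure(list(vocabulary = vocabulary, descriptions = descriptions,
                 genes = genes),
            class = "AnnotationSet")
}

#' Construct an annotation set in code
#'
#' @param vocabulary vocabulary label.
#' @param genes named list: term id -> character vector of gene ids
#'   (deduplicated; must be non-empty).
#' @param descriptions optional named character vector of term descriptions
#'   (defaults to the term ids).
#' @return An `AnnotationSet` as returned by [read_annotations_gmt()].
#' @export
annotation_set <- function(vocabulary, genes, descriptions = NULL) {
  stopifnot(!is.null(names(genes)), all(nzchar(names(genes))))
  check_unique(names(genes), "term")
  genes <- lapply(genes, unique)
  if (any(lengths(genes) == 0)) stop("term gene sets must be non-empty")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(genes), names(genes))
  }
  structure(list(vocabulary = vocabulary,
                 descriptions = descriptions[names(genes)],
                 genes = genes),
            class = "AnnotationSet")
}

#' Write gene annotation sets in GMT format
#' @param ann an `AnnotationSet`.
#' @param path file path.
#' @export
write_annotations_gmt <- function(ann, path) {
  lines <- vapply(names(ann$genes), function(tm) {
    paste(c(tm, ann$descriptions[[tm]], ann$genes[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id<TAB>series_id<TAB>description`; descriptions
#' may be empty, sample ids must be unique.
#'
#' @param path file path.
#' @return A data frame with those three character columns.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character")
  names(df) <- c("sample_id", "series_id", "description")[seq_len(ncol(df))]
  check_unique(df$sample_id, "sample")
  df
}

#' Write sample metadata as TSV
#' @param metadata data frame with `sample_id`, `series_id`, `description`.
#' @param path file path.
#' @export
write_sample_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a co-expression network as a from-to edge list
#'
#' TSV `gene_a<TAB>gene_b<TAB>r` with pairs canonicalized so `gene_a < gene_b`
#' lexicographically, one row per unique unordered pair, correlation printed
#' with at least six significant digits. An empty network yields a header-only
#' file (readable back as an empty network).
#'
#' @param network a [coexpression_network()].
#' @param path file path.
#' @export
write_edge_list <- function(network, path) {
  e <- network$edges
  lines <- "gene_a\tgene_b\tr"
  if (nrow(e) > 0) {
    canon <- canonical_pairs(e$a, e$b)
    ord <- order(canon$a, canon$b)
    lines <- c(lines, paste(canon$a[ord], canon$b[ord],
                            sprintf("%.6g", e$r[ord]), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a from-to edge list written by [write_edge_list()]
#' @param path file path.
#' @param threshold correlation threshold to attach (optional).
#' @return A [coexpression_network()].
#' @export
read_edge_list <- function(path, threshold = NA_real_) {
  df <- read.delim(path, header = TRUE,
                   colClasses = c("character", "character", "numeric"))
  names(df) <- c("a", "b", "r")
  coexpression_network(df, threshold = threshold)
}

#' Write module assignments as TSV (`module_id<TAB>gene_id`)
#' @param modules a `ModuleSet` (see [mcl()]).
#' @param path file path.
#' @export
write_module_assignments <- function(modules, path) {
  ids <- rep(names(modules$modules), lengths(modules$modules))
  genes <- unlist(modules$modules, use.names = FALSE)
  write.table(data.frame(module_id = ids, gene_id = genes),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
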