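#' Construct an expression table
#'
#' Container for a circRNA-by-dataset matrix of junction-read counts (CCR
#' or BSJ counts), with the per-dataset library sizes (uniquely mapped
#' reads) used for per-million scaling and the batch structure (species,
#' tissue, batch) of each dataset.
#'
#' @param counts Numeric matrix, rows = circRNA ids, columns = dataset ids.
#' @param library_sizes Named numeric vector covering every column.
#' @param batch_map Data frame with columns `dataset_id`, `species`,
#'   `tissue`, `batch_id` covering every column.
#' @return An `expression_table` object.
#' @export
expression_table <- function(counts, library_sizes, batch_map) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (is.null(colnames(counts))) stop("counts must have dataset column names")
  miss <- setdiff(colnames(counts), names(library_sizes))
  if (length(miss)) stop("missing library size for: ", paste(miss, collapse = ", "))
  if (any(library_sizes[colnames(counts)] <= 0)) {
    stop("library sizes must be positive")
  }
  need <- c("dataset_id", "species", "tissue", "batch_id")
  if (!all(need %in% names(batch_map))) {
    stop("batch_map needs columns: ", paste(need, collapse = ", "))
  }
  miss <- setdiff(colnames(counts), batch_map$dataset_id)
  if (length(miss)) stop("batch_map does not cover: ", paste(miss, collapse = ", "))
  structure(list(counts = counts,
                 library_sizes = library_sizes[colnames(counts)],
                 batch_map = batch_map),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$counts), "circRNAs x", ncol(x$counts),
      "datasets,", length(unique(x$batch_map$batch_id)), "batches\n")
  invisible(x)
}

#' Per-million scaling
#'
#' Scales a count (number of circRNAs detected, or junction reads) by the
#' dataset's uniquely mapped read count, expressed per million reads.
#'
#' @param x Count(s).
#' @param library_size Uniquely mapped reads of the dataset.
#' @return `x * 1e6 / library_size`.
#' @export
per_million <- function(x, library_size) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  x * 1e6 / library_size
}

#' TMM normalization factors
#'
#' Between-dataset scaling factors by the trimmed mean of M-values, the
#' standard count normalization for junction-read matrices, computed by
#' edgeR. The reference column is the one whose library-size-scaled upper
#' quartile is closest to the mean upper quartile; per column, log ratios
#' (M) and average log abundances (A) over features positive in both
#' columns are doubly trimmed (`trim_m` on M, `trim_a` on A) and the
#' factor is two to the precision-weighted mean of the retained M values;
#' factors are rescaled to have zero log mean.
#'
#' @param table An [expression_table()] (or bare counts matrix).
#' @param trim_m Trim fraction on the M values (default 0.30).
#' @param trim_a Trim fraction on the A values (default 0.05).
#' @param library_sizes Optional explicit library sizes; defaults to the
#'   table's, or to column sums for a bare matrix.
#' @return Named vector of normalization factors, one per dataset.
#' @export
tmm_factors <- function(table, trim_m = 0.30, trim_a = 0.05,
                        library_sizes = NULL) {
  if (inherits(table, "expression_table")) {
    counts <- table$counts
    if (is.null(library_sizes)) library_sizes <- table$library_sizes
  } else {
    counts <- as.matrix(table)
    if (is.null(library_sizes)) library_sizes <- colSums(counts)
  }
  if (ncol(counts) < 2L) stop("TMM needs at least two datasets")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("all-zero count column(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts, lib.size = library_sizes,
                              method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  stats::setNames(as.numeric(f), colnames(counts))
}

normalized_counts <- function(table, factors = NULL) {
  if (is.null(factors)) {
    factors <- if (ncol(table$counts) >= 2L) tmm_factors(table)
               else stats::setNames(1, colnames(table$counts))
  }
  eff <- table$library_sizes * factors[colnames(table$counts)]
  sweep(table$counts, 2L, eff, "/") * 1e6
}

#' Batch-level circRNA expression
#'
#' Normalizes each dataset column (per-million by library size times TMM
#' factor) and averages the normalized values over the batch's datasets,
#' yielding one expression value per circRNA for the batch. The mean is
#' used rather than the sum so batches of different sizes stay comparable;
#' within a batch the two are rank-equivalent.
#'
#' @param table An [expression_table()].
#' @param batch_id Batch to aggregate.
#' @param factors Optional precomputed TMM factors (computed across all of
#'   the table's datasets when omitted).
#' @return Named numeric vector, one value per circRNA.
#' @export
batch_expression <- function(table, batch_id, factors = NULL) {
  ds <- table$batch_map$dataset_id[table$batch_map$batch_id == batch_id]
  ds <- intersect(colnames(table$counts), ds)
  if (length(ds) == 0L) stop("unknown or empty batch: ", batch_id)
  norm <- normalized_counts(table, factors)
  rowMeans(norm[, ds, drop = FALSE])
}

#' Aggregate circRNA expression to parent genes
#'
#' The expression of a parent gene is the sum of the expression of the
#' circRNAs it produces. CircRNAs without a parent (unannotated or
#' size-excluded) are left out of the gene table; their summed mass is
#' reported separately so nothing is silently dropped.
#'
#' @param annotated Annotated catalog ([annotate_catalog()]) providing the
#'   circRNA-to-gene map; circ ids are `chrom:strand:start:end`.
#' @param table An [expression_table()] whose rownames are circ ids.
#' @return List with `genes` (matrix gene x dataset), `residual` (named
#'   vector: per-dataset mass of parentless circRNAs), class
#'   `gene_expression_table`.
#' @export
gene_expression <- function(annotated, table) {
  ids <- circ_id(annotated)
  parent <- stats::setNames(annotated$parent_gene_id, ids)
  row_parent <- parent[rownames(table$counts)]
  has_parent <- !is.na(row_parent)
  genes <- if (any(has_parent)) {
    rowsum(table$counts[has_parent, , drop = FALSE],
           group = row_parent[has_parent])
  } else {
    matrix(numeric(), nrow = 0L, ncol = ncol(table$counts),
           dimnames = list(NULL, colnames(table$counts)))
  }
  residual <- colSums(table$counts[!has_parent, , drop = FALSE])
  structure(list(genes = genes, residual = residual),
            class = "gene_expression_table")
}

#' Top-N ranking of an expression vector
#'
#' Ids of the `n` most expressed entries, descending; ties are broken by
#' lexicographic id so rankings are reproducible. Zero-expression entries
#' never enter the list; if fewer than `n` nonzero entries exist the list
#' is shorter and a message says so.
#'
#' @param expression Named numeric vector.
#' @param n List length (default 100).
#' @return Character vector of ids, length at most `n`.
#' @export
top_n <- function(expression, n = 100L) {
  expression <- expression[expression > 0]
  ord <- order(-expression, names(expression))
  ids <- names(expression)[ord]
  if (length(ids) < n) {
    message("only ", length(ids), " nonzero entries for a Top-", n, " list")
  }
  utils::head(ids, n)
}

#' Percent overlap of two Top-N lists
#'
#' @param top_a,top_b Equal-length id vectors.
#' @return `100 * |A intersect B| / N`.
#' @export
overlap_pct <- function(top_a, top_b) {
  if (length(top_a) != length(top_b)) {
    stop("Top-N lists differ in length (", length(top_a), " vs ",
         length(top_b), ")")
  }
  100 * length(intersect(top_a, top_b)) / length(top_a)
}

#' Circular isoform balance of a gene
#'
#' For the set of circRNAs produced by one gene: the number of distinct
#' isoforms, the dominance ratio (highest / second-highest expression;
#' `Inf` for a single isoform) and the max/min ratio.
#'
#' @param values Expression values of the gene's circRNAs.
#' @return List `n_isoforms`, `dominance_ratio`, `max_min_ratio`.
#' @export
isoform_balance <- function(values) {
  if (length(values) == 0L) stop("gene has no circRNAs")
  s <- sort(values, decreasing = TRUE)
  list(n_isoforms = length(s),
       dominance_ratio = if (length(s) == 1L) Inf else s[[1L]] / s[[2L]],
       max_min_ratio = s[[1L]] / s[[length(s)]])
}

#' Cross-species expression correlation
#'
#' Correlates the expression of paired rows (orthologous circRNAs or
#' genes) of two tables on the log10 scale, after keeping only pairs with
#' substantial expression on both sides (`log10(value) > min_log10`,
#' default 1.2).
#'
#' @param expr_a,expr_b Named expression vectors.
#' @param id_map Data frame with columns `id_a`, `id_b` pairing rows.
#' @param min_log10 Expression floor on the log10 scale.
#' @param method `"pearson"` (default, matching log-scale scatter plots)
#'   or `"spearman"`.
#' @return List `n_pairs`, `r`.
#' @export
cross_expression_correlation <- function(expr_a, expr_b, id_map,
                                         min_log10 = 1.2,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- expr_a[id_map$id_a]
  b <- expr_b[id_map$id_b]
  ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0 &
    log10(a) > min_log10 & log10(b) > min_log10
  if (sum(ok) < 3L) {
    stop("fewer than 3 pairs above the expression floor; correlation undefined")
  }
  list(n_pairs = sum(ok),
       r = stats::cor(log10(a[ok]), log10(b[ok]), method = method))
}

#' Compare per-dataset circRNA summaries between two groups
#'
#' Two-sided rank-sum (Mann-Whitney) comparison of two groups of scalar
#' per-dataset summaries, e.g. exonic circRNAs per million reads. The
#' p-value is exact for small untied samples; with ties and at most 10
#' values per group, an exact midrank enumeration over all group
#' assignments is used instead of the normal approximation.
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each).
#' @return List `statistic` (rank sum W of group A minus its minimum, the
#'   Mann-Whitney U), `p_value`.
#' @export
compare_batch_counts <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  if (!ties) {
    wt <- stats::wilcox.test(values_a, values_b, exact = TRUE)
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value))
  }
  if (length(values_a) <= 10L && length(values_b) <= 10L) {
    return(ranksum_exact_midrank(values_a, values_b))
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b, exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

# exact two-sided rank-sum with midranks, by enumerating all assignments
ranksum_exact_midrank <- function(a, b) {
  n_a <- length(a); pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n_a)])
  e <- n_a * (length(pooled) + 1) / 2
  combs <- utils::combn(length(pooled), n_a)
  sums <- colSums(matrix(r[combs], nrow = n_a))
  p <- mean(abs(sums - e) >= abs(obs - e) - 1e-9)
  list(statistic = obs - n_a * (n_a + 1) / 2, p_value = min(1, p))
}
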