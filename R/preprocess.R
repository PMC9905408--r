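#' Filter spots by total UMI count
#'
#' Retains exactly the spots whose total UMI count is at least `min_umi`
#' (default 163); the gene list is unchanged. The operation is idempotent at
#' a fixed threshold and an empty result is allowed.
#'
#' @param counts Gene-by-spot count matrix with dimnames.
#' @param min_umi Minimum total UMI per spot (>= 0).
#' @return The filtered count matrix.
#' @export
filter_spots <- function(counts, min_umi = 163L) {
  if (!is.numeric(min_umi) || length(min_umi) != 1L || min_umi < 0) {
    stop_invalid("min_umi must be a single nonnegative number")
  }
  counts <- as_gene_spot_matrix(counts, "counts")
  counts[, Matrix::colSums(counts) >= min_umi, drop = FALSE]
}

#' Log-normalize a count matrix
#'
#' Per-spot expression abundance `Ei = log(UMI + 1)` (natural log), applied
#' elementwise. Zeros map to zeros, so the sparsity pattern is preserved
#' exactly.
#'
#' @param counts Nonnegative gene-by-spot matrix with dimnames.
#' @return Sparse matrix of the same shape with `log1p`-transformed values.
#' @export
log_normalize <- function(counts) {
  counts <- as_gene_spot_matrix(counts, "counts")
  if (length(counts@x) > 0L && any(counts@x < 0)) {
    stop_invalid("counts must be nonnegative")
  }
  log1p(counts)
}

#' Select highly-variable genes
#'
#' Returns the `n` genes of largest sample variance of normalized expression
#' across spots, in descending variance order; ties are broken by gene-name
#' lexicographic order (C collation), so the selection is invariant to the
#' input gene order.
#'
#' @param norm Normalized gene-by-spot matrix with dimnames.
#' @param n Number of genes to return (<= number of genes).
#' @return Character vector of `n` gene names.
#' @export
select_hvg <- function(norm, n = 2000L) {
  norm <- as_gene_spot_matrix(norm, "norm")
  if (n > nrow(norm)) {
    stop_invalid("n (%d) exceeds the number of genes (%d)", n, nrow(norm))
  }
  v <- row_vars(norm)
  genes <- rownames(norm)
  old <- Sys.getlocale("LC_COLLATE"); Sys.setlocale("LC_COLLATE", "C")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  ord <- order(-v, genes)
  genes[ord][seq_len(n)]
}

#' Embed spots and label domains
#'
#' Plumbing domain labeler: projects the (typically HVG-restricted)
#' normalized matrix onto its top principal components and partitions the
#' spots by k-means. This stands in for graph-based clustering when no
#' external label table is supplied; externally produced labels are
#' first-class inputs everywhere else in the package.
#'
#' @param norm Normalized gene-by-spot matrix.
#' @param k Number of domains (>= 2, <= number of spots).
#' @param n_components Number of principal components (default 30; clamped
#'   to the matrix rank).
#' @param seed Integer seed; identical input and seed give identical labels.
#' @param genes Optional gene subset (e.g. from [select_hvg()]) to embed on.
#' @param nstart k-means restarts (best inertia kept).
#' @param center_spots If `TRUE` (default) each spot's profile is centered
#'   to its own mean before PCA, absorbing library-size shifts (spots hold
#'   1-6 cells, so total UMI varies several-fold and would otherwise
#'   dominate the leading component).
#' @return Named character vector: spot barcode -> cluster label
#'   `"1"`..`"k"`.
#' @export
embed_and_label <- function(norm, k, n_components = 30L, seed = 1L,
                            genes = NULL, nstart = 10L, center_spots = TRUE) {
  norm <- as_gene_spot_matrix(norm, "norm")
  if (!is.null(genes)) norm <- norm[genes, , drop = FALSE]
  n_spots <- ncol(norm)
  if (k < 2L) stop_invalid("k must be >= 2")
  if (k > n_spots) stop_invalid("k (%d) exceeds the number of spots (%d)", k, n_spots)
  if (k == n_spots) {  # trivial partition: every spot its own label
    return(stats::setNames(as.character(seq_len(n_spots)), colnames(norm)))
  }
  x <- t(as.matrix(norm))
  if (center_spots) x <- x - rowMeans(x)
  rank_max <- min(nrow(x) - 1L, ncol(x))
  n_components <- min(n_components, rank_max)
  pcs <- stats::prcomp(x, center = TRUE, scale. = FALSE,
                       rank. = n_components)$x
  km <- with_seed(seed, stats::kmeans(pcs, centers = k, nstart = nstart,
                                      iter.max = 100L))
  stats::setNames(as.character(km$cluster), colnames(norm))
}
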