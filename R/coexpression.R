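# Unbiased co-expression module detection: Pearson correlation of HVGs,
# k-means modules, spatiotemporal module maps, hierarchical submodules.

#' Gene-gene Pearson correlation matrix
#'
#' Pearson correlation of each gene pair across spots. Zero-variance genes
#' get correlation 0 to every other gene (with a warning naming them) and
#' keep a unit diagonal.
#'
#' @param norm Normalized gene-by-spot matrix (typically restricted to the
#'   HVGs); at least 2 spots.
#' @return Symmetric genes-by-genes matrix with unit diagonal, entries in
#'   `[-1, 1]`.
#' @export
gene_correlation <- function(norm) {
  norm <- as_gene_spot_matrix(norm, "norm")
  if (ncol(norm) < 2L) stop_invalid("need at least 2 spots to correlate genes")
  x <- t(as.matrix(norm))
  v <- apply(x, 2L, stats::var)
  degenerate <- colnames(x)[v == 0]
  cc <- suppressWarnings(stats::cor(x))
  if (length(degenerate) > 0L) {
    warning(sprintf("zero-variance gene(s) set to correlation 0: %s",
                    paste(utils::head(degenerate, 5L), collapse = ", ")),
            call. = FALSE)
    cc[degenerate, ] <- 0
    cc[, degenerate] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Co-expression modules by k-means
#'
#' Partitions genes into `k` co-expression modules by k-means on the rows of
#' the gene-gene correlation matrix (so similarity of correlation profiles
#' drives the clustering; set `use_correlation = FALSE` to cluster raw
#' expression profiles instead). Runs `nstart` restarts and keeps the best
#' inertia. Module ids 1..k are ordered by descending module size (ties by
#' first occurrence).
#'
#' @param x Either a gene-gene correlation matrix from [gene_correlation()]
#'   (default interpretation) or, with `use_correlation = FALSE`, a
#'   gene-by-spot expression matrix.
#' @param k Number of modules (<= number of genes); default 18.
#' @param seed Integer seed.
#' @param nstart k-means restarts; default 10.
#' @param use_correlation Whether `x` is a correlation matrix (default) or
#'   raw profiles.
#' @return A `gene_modules` object: list with `assignment` (named integer,
#'   gene -> module id), `modules` (list of gene vectors, largest first),
#'   `k`, `sizes`, `tot_withinss`.
#' @export
kmeans_modules <- function(x, k = 18L, seed = 1L, nstart = 10L,
                           use_correlation = TRUE) {
  feats <- as.matrix(x)  # genes in rows for both input kinds
  genes <- rownames(feats)
  if (is.null(genes)) stop_invalid("input must carry gene row names")
  if (use_correlation && nrow(feats) != ncol(feats)) {
    stop_invalid("correlation input must be square (got %d x %d); use use_correlation = FALSE for expression profiles",
                 nrow(feats), ncol(feats))
  }
  if (k > nrow(feats)) {
    stop_invalid("k (%d) exceeds the number of genes (%d)", k, nrow(feats))
  }
  if (k == nrow(feats)) {  # trivial partition: singleton modules
    assignment <- stats::setNames(seq_len(k), genes)
    return(structure(
      list(assignment = assignment,
           modules = lapply(seq_len(k), function(m) genes[m]),
           k = as.integer(k), sizes = rep(1L, k), tot_withinss = 0),
      class = "gene_modules"))
  }
  km <- with_seed(seed, stats::kmeans(feats, centers = k, nstart = nstart,
                                      iter.max = 100L))
  sizes <- tabulate(km$cluster, nbins = k)
  new_id <- integer(k)
  new_id[order(-sizes)] <- seq_len(k)
  assignment <- stats::setNames(new_id[km$cluster], genes)
  modules <- lapply(seq_len(k), function(m) genes[assignment == m])
  structure(
    list(assignment = assignment, modules = modules, k = as.integer(k),
         sizes = lengths(modules), tot_withinss = km$tot.withinss),
    class = "gene_modules"
  )
}

#' @export
print.gene_modules <- function(x, ...) {
  cat(sprintf("<gene_modules> %d modules over %d genes (sizes %s)\n",
              x$k, length(x$assignment),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Spatiotemporal module expression map
#'
#' Per spot and time point, the mean normalized expression over the module's
#' genes.
#'
#' @param genes Character vector of module member genes.
#' @param norm_by_time Named list (time as name) of normalized gene-by-spot
#'   matrices; every matrix must contain all module genes.
#' @return Data frame with columns `time_dpi`, `spot_id`, `mean_expr`.
#' @export
module_spatiotemporal_map <- function(genes, norm_by_time) {
  out <- lapply(names(norm_by_time), function(tp) {
    norm <- norm_by_time[[tp]]
    missing <- setdiff(genes, rownames(norm))
    if (length(missing) > 0L) {
      stop_invalid("time %s: module gene(s) absent: %s", tp,
                   paste(utils::head(missing, 3L), collapse = ", "))
    }
    m <- Matrix::colMeans(norm[genes, , drop = FALSE])
    data.frame(time_dpi = tp, spot_id = names(m), mean_expr = as.numeric(m))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Hierarchical submodules within a module
#'
#' Average-linkage hierarchical clustering of the module's genes on the
#' `1 - correlation` distance, cut at a fixed height into flat submodules
#' labeled `"m.1"`, `"m.2"`, ... in decreasing size order.
#'
#' @param genes Module member genes (>= 2).
#' @param correlation Gene-gene correlation matrix covering the module.
#' @param cut_height Dendrogram cut height on the `1 - r` scale; default
#'   0.5.
#' @param module_id Prefix used in submodule labels; default `"m"`.
#' @return List with `hclust` (the dendrogram) and `submodules` (named
#'   character vector, gene -> submodule label).
#' @export
submodule_hierarchy <- function(genes, correlation, cut_height = 0.5,
                                module_id = "m") {
  if (length(genes) < 2L) stop_invalid("module must contain at least 2 genes")
  missing <- setdiff(genes, rownames(correlation))
  if (length(missing) > 0L) {
    stop_invalid("correlation matrix missing gene(s): %s",
                 paste(utils::head(missing, 3L), collapse = ", "))
  }
  d <- stats::as.dist(1 - correlation[genes, genes])
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  new_id <- stats::setNames(seq_along(sizes), names(sort(-sizes)))
  lab <- sprintf("%s.%d", module_id, new_id[as.character(raw)])
  list(hclust = hc, submodules = stats::setNames(lab, names(raw)))
}
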