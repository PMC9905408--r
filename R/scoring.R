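# Per-spot gene-set scoring: control-matched module scores, rank-based
# pathway activity, and distance-resolved layer profiles.

#' Control-matched module score
#'
#' Per-spot mean expression of the signature genes minus the mean of
#' control genes drawn from matched average-expression bins: all genes are
#' binned into `n_bins` equal-occupancy bins of their mean expression across
#' spots, and each signature gene contributes `n_ctrl` control genes sampled
#' without replacement from its own bin (excluding signature genes; the
#' whole remaining bin is used when it is smaller than `n_ctrl`). Because
#' controls are matched on expression level, adding a constant to the whole
#' matrix leaves scores unchanged.
#'
#' @param norm Normalized gene-by-spot matrix.
#' @param gene_set Character vector of signature genes; at least one must be
#'   present in the matrix.
#' @param n_bins Number of average-expression bins (default 25).
#' @param n_ctrl Controls sampled per signature gene (default 100).
#' @param seed Integer seed controlling control sampling.
#' @return Named numeric vector, spot barcode -> score.
#' @export
module_score <- function(norm, gene_set, n_bins = 25L, n_ctrl = 100L,
                         seed = 1L) {
  norm <- as_gene_spot_matrix(norm, "norm")
  if (n_bins < 1L) stop_invalid("n_bins must be >= 1")
  genes <- rownames(norm)
  set <- intersect(gene_set, genes)
  if (length(set) == 0L) {
    stop_invalid("none of the %d signature genes is present in the matrix",
                 length(gene_set))
  }
  avg <- Matrix::rowMeans(norm)
  # equal-occupancy bins of average expression (ties split by rank order)
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / length(avg))
  names(bin) <- genes
  non_set <- setdiff(genes, set)
  pool_by_bin <- split(non_set, bin[non_set])
  ctrl <- with_seed(seed, {
    unlist(lapply(set, function(g) {
      pool <- pool_by_bin[[as.character(bin[[g]])]]
      # a bin can consist entirely of signature genes; fall back to the
      # whole non-signature pool so every signature gene keeps controls
      if (is.null(pool) || length(pool) == 0L) pool <- non_set
      if (length(pool) == 0L) return(character(0))
      if (length(pool) <= n_ctrl) pool else sample(pool, n_ctrl)
    }), use.names = FALSE)
  })
  if (length(ctrl) == 0L) {
    stop_invalid("no control genes available outside the signature")
  }
  sig_mean <- Matrix::colMeans(norm[set, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  sig_mean - ctrl_mean
}

#' Assign cell types to clusters from module scores
#'
#' Each cluster label receives the cell type whose mean module score over
#' the cluster's spots is largest; exact ties are broken by cell-type name
#' order with a warning. The result does not depend on the order in which
#' score maps are supplied (beyond tie-breaking, which uses sorted names).
#'
#' @param score_maps Named list (cell type -> named score vector from
#'   [module_score()]).
#' @param labels Named character vector, spot -> cluster label.
#' @return Named character vector, cluster label -> cell type.
#' @export
assign_cell_types <- function(score_maps, labels) {
  if (length(score_maps) == 0L) stop_invalid("need at least one score map")
  types <- sort(names(score_maps))
  clusters <- sort(unique(labels))
  out <- vapply(clusters, function(cl) {
    spots <- names(labels)[labels == cl]
    means <- vapply(types, function(t) {
      s <- score_maps[[t]][spots]
      if (anyNA(s)) stop_invalid("score map '%s' missing spots of cluster '%s'", t, cl)
      mean(s)
    }, numeric(1))
    top <- which(means == max(means))
    if (length(top) > 1L) {
      warning(sprintf("cluster '%s': tie between cell types %s; keeping '%s'",
                      cl, paste(types[top], collapse = ", "), types[top[1L]]),
              call. = FALSE)
    }
    types[top[1L]]
  }, character(1))
  stats::setNames(out, clusters)
}

#' Rank-based pathway activity
#'
#' Single-sample enrichment of a gene set within each spot, computed from
#' within-spot expression ranks only: the normalized difference between the
#' mean rank of set genes and the mean rank of non-set genes,
#' `(mean_rank_set - mean_rank_rest) / (n_genes / 2)`. This equals the
#' integrated difference between the set and non-set running sums over the
#' expression-ordered gene list (equal step weights), normalized to lie in
#' `[-1, 1]`: +1 when the set occupies the top ranks, -1 at the bottom, and
#' sign-flipped by reversing the ranking. Any strictly monotone per-spot
#' transform of the expression leaves scores unchanged.
#'
#' @param norm Normalized gene-by-spot matrix.
#' @param gene_set Character vector; its intersection with the matrix genes
#'   must be non-empty and must not cover all genes.
#' @return Named numeric vector, spot barcode -> activity in `[-1, 1]`.
#' @export
pathway_activity <- function(norm, gene_set) {
  norm <- as_gene_spot_matrix(norm, "norm")
  genes <- rownames(norm)
  set <- intersect(gene_set, genes)
  if (length(set) == 0L) stop_invalid("no gene of the set is present in the matrix")
  if (length(set) == length(genes)) {
    stop_invalid("gene set covers every gene in the matrix")
  }
  x <- as.matrix(norm)
  n <- nrow(x)
  ranks <- apply(x, 2L, rank, ties.method = "average")  # high expr = high rank
  in_set <- genes %in% set
  mean_in <- colMeans(ranks[in_set, , drop = FALSE])
  mean_out <- colMeans(ranks[!in_set, , drop = FALSE])
  stats::setNames((mean_in - mean_out) / (n / 2), colnames(norm))
}

#' Layer score profile around the scar center
#'
#' Restricts a score map to one layer and profiles it against the signed
#' spot distance from the scar center along the layer's long axis: each spot
#' is binned by `round((coord - center) / pitch_um)` and per-bin mean score
#' and occupancy are reported for every bin from -R to +R. For layers cut as
#' row bands the profile runs along x (the rostrocaudal axis of a
#' horizontally mounted section).
#'
#' @param score_map Named numeric vector, spot -> score.
#' @param layers A `layer_assignment` from [assign_layers()].
#' @param layer_index Which layer to profile.
#' @param lattice The `spot_lattice` (provides coordinates and pitch).
#' @param center Scar center `c(x, y)` from [scar_center()].
#' @return Data frame with columns `bin` (signed spots from center),
#'   `distance_um`, `mean_score` (NA for unoccupied bins), `n_spots`.
#' @export
layer_profile <- function(score_map, layers, layer_index, lattice, center) {
  spots <- names(layers$layers)[layers$layers == layer_index]
  if (length(spots) == 0L) stop_invalid("layer %s is empty", layer_index)
  idx <- match(spots, lattice$spot_id)
  if (anyNA(idx)) stop_invalid("layer contains spots absent from the lattice")
  pitch <- lattice_pitch(lattice)
  coord <- if (layers$axis == "row") lattice$x_um[idx] else lattice$y_um[idx]
  ctr <- if (layers$axis == "row") center[["x"]] else center[["y"]]
  s <- score_map[spots]
  if (anyNA(s)) stop_invalid("score map missing value(s) for layer spots")
  bin <- as.integer(round((coord - ctr) / pitch))
  r <- max(abs(bin))
  all_bins <- seq(-r, r)
  mean_score <- vapply(all_bins, function(b) {
    v <- s[bin == b]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  n_spots <- vapply(all_bins, function(b) sum(bin == b), integer(1))
  data.frame(bin = all_bins, distance_um = all_bins * pitch,
             mean_score = mean_score, n_spots = n_spots)
}
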