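# Boundary-restricted ligand-receptor interaction testing: expression
# fraction filter, mean-of-averages score, label-permutation p-value.

#' Fraction of spots expressing a gene
#'
#' Fraction of the given spots with `Ei > 0` for the gene, i.e. at least one
#' UMI ("expressed" means a nonzero normalized value).
#'
#' @param norm Normalized gene-by-spot matrix.
#' @param gene Gene name.
#' @param spots Non-empty character vector of spot barcodes.
#' @return Value in `[0, 1]`.
#' @export
expression_fraction <- function(norm, gene, spots) {
  if (length(spots) == 0L) stop_invalid("empty spot set")
  if (!gene %in% rownames(norm)) stop_invalid("gene '%s' not in matrix", gene)
  mean(norm[gene, spots] > 0)
}

#' Expression-fraction filter for a ligand-receptor pair
#'
#' A pair is tested only when both the ligand fraction (in the source
#' cluster) and the receptor fraction (in the target cluster) strictly
#' exceed `threshold` (default 0.1).
#'
#' @param ligand_fraction,receptor_fraction Values in `[0, 1]`.
#' @param threshold Strict lower bound; default 0.1.
#' @return `TRUE` iff both fractions exceed the threshold.
#' @export
pair_filter <- function(ligand_fraction, receptor_fraction, threshold = 0.1) {
  stopifnot(ligand_fraction >= 0, ligand_fraction <= 1,
            receptor_fraction >= 0, receptor_fraction <= 1)
  ligand_fraction > threshold && receptor_fraction > threshold
}

#' Mean-of-averages interaction score
#'
#' The mean of the average ligand expression over the ligand-side spots and
#' the average receptor expression over the receptor-side spots:
#' `(mean(Ei[ligand, ligand_spots]) + mean(Ei[receptor, receptor_spots])) / 2`.
#' Swapping ligand with receptor and simultaneously the two spot sets leaves
#' the score unchanged.
#'
#' @param norm Normalized gene-by-spot matrix.
#' @param ligand,receptor Gene names.
#' @param ligand_spots,receptor_spots Non-empty spot barcode vectors.
#' @return Nonnegative real for nonnegative expression.
#' @export
interaction_score <- function(norm, ligand, receptor, ligand_spots,
                              receptor_spots) {
  if (length(ligand_spots) == 0L || length(receptor_spots) == 0L) {
    stop_invalid("both spot sets must be non-empty")
  }
  (mean(norm[ligand, ligand_spots]) + mean(norm[receptor, receptor_spots])) / 2
}

#' Label-permutation p-value for one ligand-receptor pair
#'
#' The observed statistic is the mean-of-averages interaction score on the
#' true role assignment (source spots provide the ligand average, target
#' spots the receptor average). Role labels are then shuffled uniformly over
#' the pooled spots, preserving the two group sizes, and the p-value is the
#' plain proportion of permuted scores greater than or equal to the observed
#' score (so p = 0 is attainable); the conservative estimator
#' `(k + 1) / (n_perm + 1)` is reported alongside.
#'
#' @param norm Normalized gene-by-spot matrix.
#' @param ligand,receptor Gene names.
#' @param source_spots,target_spots Spot barcodes of the two interface
#'   sides; each side needs at least 2 spots.
#' @param n_perm Number of permutations (>= 1); default 1000.
#' @param seed Integer seed; identical seed gives identical p-values.
#' @param pool_spots Optional larger spot universe to draw permuted role
#'   groups from (defaults to the union of the two sides; see
#'   [run_boundary_lr()]'s `permute_over`).
#' @return One-row data frame with `ligand`, `receptor`, `mean_score`,
#'   `p_value`, `p_value_conservative`, `n_permutations`.
#' @export
permutation_pvalue <- function(norm, ligand, receptor, source_spots,
                               target_spots, n_perm = 1000L, seed = 1L,
                               pool_spots = NULL) {
  if (length(source_spots) < 2L || length(target_spots) < 2L) {
    stop_invalid("need at least 2 spots on each interface side")
  }
  if (n_perm < 1L) stop_invalid("n_perm must be >= 1")
  obs <- interaction_score(norm, ligand, receptor, source_spots, target_spots)
  if (is.null(pool_spots)) pool_spots <- c(source_spots, target_spots)
  na <- length(source_spots); nb <- length(target_spots)
  lig_vals <- as.numeric(norm[ligand, pool_spots])
  rec_vals <- as.numeric(norm[receptor, pool_spots])
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pool_spots), na + nb)
      (mean(lig_vals[idx[seq_len(na)]]) +
         mean(rec_vals[idx[na + seq_len(nb)]])) / 2
    }, numeric(1))
  })
  k <- sum(perm >= obs)
  data.frame(ligand = ligand, receptor = receptor, mean_score = obs,
             p_value = k / n_perm,
             p_value_conservative = (k + 1) / (n_perm + 1),
             n_permutations = as.integer(n_perm))
}

#' Boundary-restricted ligand-receptor screen
#'
#' For every ordered pair of lattice-adjacent clusters, extracts the
#' two-spot-wide interface band, filters each candidate ligand-receptor
#' pair by expression fraction on the interface (ligand in the source side,
#' receptor in the target side, both strictly above `threshold`), and
#' computes the mean-of-averages score with a label-permutation p-value for
#' the pairs that pass. Both orderings of each adjacent cluster pair are
#' reported separately (ligand-source A with receptor-target B, and the
#' reverse). Pairs failing the filter are reported with `p_value = NA`.
#'
#' @param norm Normalized gene-by-spot matrix.
#' @param labels Named character vector, spot -> cluster label.
#' @param graph A `spot_graph` over the same spots.
#' @param pairs Data frame with columns `ligand`, `receptor`; pairs whose
#'   genes are absent from the matrix are dropped with a warning.
#' @param width Interface band width in lattice steps; default 2.
#' @param threshold Expression-fraction threshold; default 0.1 (strict).
#' @param n_perm Permutations per tested pair; default 1000.
#' @param seed Integer seed for all permutation draws.
#' @param permute_over `"interface"` (default) shuffles role labels over the
#'   pooled interface spots; `"clusters"` draws the permuted role groups
#'   from all spots of the two clusters while preserving the interface
#'   group sizes.
#' @return Data frame (class `lr_result`), one row per (cluster pair, LR
#'   pair): `ligand`, `receptor`, `pair_name`, `source_cluster`,
#'   `target_cluster`, `n_source_spots`, `n_target_spots`,
#'   `ligand_fraction`, `receptor_fraction`, `mean_score`, `p_value`,
#'   `p_value_conservative`, `n_permutations`. Empty (zero-row) when fewer
#'   than two clusters touch.
#' @export
run_boundary_lr <- function(norm, labels, graph, pairs, width = 2L,
                            threshold = 0.1, n_perm = 1000L, seed = 1L,
                            permute_over = c("interface", "clusters")) {
  permute_over <- match.arg(permute_over)
  norm <- as_gene_spot_matrix(norm, "norm")
  present <- pairs$ligand %in% rownames(norm) & pairs$receptor %in% rownames(norm)
  if (!all(present)) {
    warning(sprintf("dropping %d pair(s) with genes absent from the matrix",
                    sum(!present)), call. = FALSE)
    pairs <- pairs[present, , drop = FALSE]
  }
  adj <- domain_adjacency(labels, graph)
  empty <- data.frame(
    ligand = character(0), receptor = character(0), pair_name = character(0),
    source_cluster = character(0), target_cluster = character(0),
    n_source_spots = integer(0), n_target_spots = integer(0),
    ligand_fraction = numeric(0), receptor_fraction = numeric(0),
    mean_score = numeric(0), p_value = numeric(0),
    p_value_conservative = numeric(0), n_permutations = integer(0))
  if (nrow(adj) == 0L || nrow(pairs) == 0L) {
    class(empty) <- c("lr_result", "data.frame")
    return(empty)
  }
  # ordered cluster pairs: both directions of every adjacency
  ordered <- rbind(
    data.frame(src = adj$label_a, tgt = adj$label_b),
    data.frame(src = adj$label_b, tgt = adj$label_a))
  ordered <- ordered[order(ordered$src, ordered$tgt), , drop = FALSE]
  seeds <- derive_seeds(seed, nrow(ordered) * nrow(pairs))
  rows <- vector("list", nrow(ordered) * nrow(pairs))
  ri <- 0L
  for (ci in seq_len(nrow(ordered))) {
    src <- ordered$src[ci]; tgt <- ordered$tgt[ci]
    iface <- extract_interface(labels, graph, src, tgt, width)
    sa <- iface$spots_a; sb <- iface$spots_b
    if (length(sa) < 2L || length(sb) < 2L) next
    pool <- if (permute_over == "clusters") {
      names(labels)[labels %in% c(src, tgt)]
    } else NULL
    for (pi in seq_len(nrow(pairs))) {
      lg <- pairs$ligand[pi]; rc <- pairs$receptor[pi]
      lf <- expression_fraction(norm, lg, sa)
      rf <- expression_fraction(norm, rc, sb)
      ri <- ri + 1L
      if (pair_filter(lf, rf, threshold)) {
        pv <- permutation_pvalue(norm, lg, rc, sa, sb, n_perm = n_perm,
                                 seed = seeds[(ci - 1L) * nrow(pairs) + pi],
                                 pool_spots = pool)
        rows[[ri]] <- data.frame(
          ligand = lg, receptor = rc, pair_name = paste(lg, rc, sep = "_"),
          source_cluster = src, target_cluster = tgt,
          n_source_spots = length(sa), n_target_spots = length(sb),
          ligand_fraction = lf, receptor_fraction = rf,
          mean_score = pv$mean_score, p_value = pv$p_value,
          p_value_conservative = pv$p_value_conservative,
          n_permutations = pv$n_permutations)
      } else {
        rows[[ri]] <- data.frame(
          ligand = lg, receptor = rc, pair_name = paste(lg, rc, sep = "_"),
          source_cluster = src, target_cluster = tgt,
          n_source_spots = length(sa), n_target_spots = length(sb),
          ligand_fraction = lf, receptor_fraction = rf,
          mean_score = NA_real_, p_value = NA_real_,
          p_value_conservative = NA_real_, n_permutations = 0L)
      }
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0L) empty else do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lr_result", "data.frame")
  out
}
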