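#' Cell-type expression program
#'
#' Describes how one cell type expresses genes in the count simulator: a set
#' of marker genes enriched multiplicatively over a negative-binomial
#' baseline shared by all other genes.
#'
#' @param cell_type Cell-type name.
#' @param marker_genes Non-empty character vector of marker gene names.
#' @param marker_log_fold Natural-log fold enrichment of marker genes over
#'   baseline (> 0); the marker mean per cell is
#'   `baseline_mean * exp(marker_log_fold)`.
#' @param baseline_mean Negative-binomial mean per cell for non-marker genes
#'   (>= 0).
#' @param dispersion Negative-binomial size parameter per cell (> 0); larger
#'   values mean less overdispersion.
#'
#' @return A `cell_type_program` list.
#' @export
cell_type_program <- function(cell_type, marker_genes, marker_log_fold = 2,
                              baseline_mean = 0.2, dispersion = 2) {
  if (length(marker_genes) == 0L) stop_invalid("marker_genes must be non-empty")
  if (marker_log_fold <= 0) stop_invalid("marker_log_fold must be > 0")
  if (baseline_mean < 0) stop_invalid("baseline_mean must be >= 0")
  if (dispersion <= 0) stop_invalid("dispersion must be > 0")
  structure(
    list(cell_type = cell_type, marker_genes = unique(marker_genes),
         marker_log_fold = marker_log_fold, baseline_mean = baseline_mean,
         dispersion = dispersion),
    class = "cell_type_program"
  )
}

#' Planted ligand-receptor interaction
#'
#' Ground truth for the boundary interaction test: the ligand gene's
#' negative-binomial mean is raised by `effect` (per cell) in the source
#' cell type, and the receptor gene's mean in the target cell type.
#'
#' @param ligand_gene,receptor_gene Distinct gene names.
#' @param source_type,target_type Distinct cell-type names.
#' @param effect Additive mean increment per cell (> 0).
#' @return A `planted_interaction` list.
#' @export
planted_interaction <- function(ligand_gene, receptor_gene,
                                source_type, target_type, effect = 3) {
  if (identical(ligand_gene, receptor_gene)) stop_invalid("ligand and receptor genes must differ")
  if (identical(source_type, target_type)) stop_invalid("source and target types must differ")
  if (effect <= 0) stop_invalid("effect must be > 0")
  structure(
    list(ligand_gene = ligand_gene, receptor_gene = receptor_gene,
         source_type = source_type, target_type = target_type, effect = effect),
    class = "planted_interaction"
  )
}

# Cell types of the synthetic lesion, listed core-outward for the mature scar.
scar_cell_types <- function() {
  c("fibroblast", "macrophage", "microglia", "astrocyte",
    "oligodendrocyte", "neuron")
}

#' Default ring radii of the synthetic lesion
#'
#' Outer radii (um) of the concentric scar domains at each time point,
#' ordered core-outward; the outermost domain (neurons, gray matter) extends
#' beyond the last radius. At 3 dpi the core is a macrophage infiltrate; at
#' 7, 14 and 28 dpi a fibrotic core is wrapped by microglial then astrocytic
#' rings inside an oligodendrocyte white-matter band, with the core
#' shrinking as the scar matures. Radii are generator configuration, chosen
#' so the scar (through the astrocytic ring) spans roughly 1.2-1.3 mm.
#'
#' @param time_dpi One of 3, 7, 14, 28 (days post-injury).
#' @return Named numeric vector of outer radii in micrometers.
#' @export
default_ring_radii <- function(time_dpi) {
  switch(as.character(time_dpi),
    "3"  = c(macrophage = 600, microglia = 950, astrocyte = 1300, oligodendrocyte = 1700),
    "7"  = c(fibroblast = 550, microglia = 950, astrocyte = 1300, oligodendrocyte = 1700),
    "14" = c(fibroblast = 450, microglia = 800, astrocyte = 1150, oligodendrocyte = 1550),
    "28" = c(fibroblast = 350, microglia = 650, astrocyte = 1000, oligodendrocyte = 1400),
    stop_invalid("time_dpi must be one of 3, 7, 14, 28 (got %s)", time_dpi)
  )
}

#' Generate a synthetic scar scene
#'
#' Lays concentric scar domains over a spot lattice at one post-injury time
#' point: each spot gets a cell count (uniform on 1..6, emulating per-spot
#' DAPI counts), a cell-type mixture concentrated on the domain ring
#' containing the spot with Gaussian leakage into adjacent rings near the
#' boundaries, and a ground-truth label equal to the mixture argmax (always
#' the containing ring).
#'
#' @param lattice A `spot_lattice`.
#' @param time_dpi One of 3, 7, 14, 28.
#' @param seed Integer seed; identical `(lattice, time_dpi, seed)` give
#'   identical scenes.
#' @param ring_radii_um Named outer radii per domain, core-outward; defaults
#'   to [default_ring_radii()].
#' @param boundary_sd_um Gaussian scale (um) of mixture leakage across ring
#'   boundaries; default 75, under one spot pitch, so mixing is confined to
#'   boundary-adjacent spots.
#'
#' @return A `scar_scene`: list with `time_dpi`, `center_um`,
#'   `ring_radii_um`, `cell_types`, `cells_per_spot` (named integer, 1..6),
#'   `spot_mixture` (spots x cell-types matrix, rows summing to 1), and
#'   `truth_labels` (named character).
#' @export
make_scene <- function(lattice, time_dpi, seed,
                       ring_radii_um = default_ring_radii(time_dpi),
                       boundary_sd_um = 75) {
  if (!time_dpi %in% c(3, 7, 14, 28)) {
    stop_invalid("time_dpi must be one of 3, 7, 14, 28 (got %s)", time_dpi)
  }
  if (is.unsorted(ring_radii_um, strictly = TRUE)) {
    stop_invalid("ring_radii_um must be strictly increasing core-outward")
  }
  types <- c(names(ring_radii_um), "neuron")
  center <- c(x = mean(lattice$x_um), y = mean(lattice$y_um))
  r <- sqrt((lattice$x_um - center["x"])^2 + (lattice$y_um - center["y"])^2)
  # annulus [inner, outer) per domain; outermost unbounded
  inner <- c(0, unname(ring_radii_um))
  outer <- c(unname(ring_radii_um), Inf)
  band <- findInterval(r, inner)          # 1..length(types); r < outer[band]
  # mixture weight: 1 inside the annulus, Gaussian decay with radial
  # distance to the annulus outside it
  n <- nrow(lattice)
  w <- matrix(0, n, length(types), dimnames = list(lattice$spot_id, types))
  for (j in seq_along(types)) {
    d <- pmax(inner[j] - r, r - outer[j], 0)
    w[, j] <- exp(-d^2 / (2 * boundary_sd_um^2))
  }
  # spots exactly on a ring boundary tie between the two bands; the
  # half-open [inner, outer) annulus owns them, so nudge its weight up
  w[cbind(seq_len(n), band)] <- w[cbind(seq_len(n), band)] * (1 + 1e-9)
  mix <- w / rowSums(w)
  truth <- types[band]
  names(truth) <- lattice$spot_id
  stopifnot(all(types[max.col(mix, ties.method = "first")] == truth))
  cells <- with_seed(seed, sample.int(6L, n, replace = TRUE))
  names(cells) <- lattice$spot_id
  structure(
    list(time_dpi = time_dpi, center_um = center,
         ring_radii_um = ring_radii_um, cell_types = types,
         cells_per_spot = cells, spot_mixture = mix, truth_labels = truth,
         seed = seed),
    class = "scar_scene"
  )
}

#' @export
print.scar_scene <- function(x, ...) {
  cat(sprintf("<scar_scene> %d dpi, %d spots, domains: %s\n",
              x$time_dpi, length(x$truth_labels),
              paste(x$cell_types, collapse = ", ")))
  invisible(x)
}

#' Default cell-type programs for the synthetic lesion
#'
#' Marker programs for the six lesion cell types, using canonical murine
#' markers (e.g. Col1a1/Dcn for fibroblasts, P2ry12/Tmem119 for microglia,
#' Gfap/Aqp4 for astrocytes, Plp1/Mbp for oligodendrocytes). Marker sets are
#' disjoint across programs.
#'
#' @param marker_log_fold,baseline_mean,dispersion Shared program
#'   parameters; see [cell_type_program()].
#' @return Named list of `cell_type_program`s, one per lesion cell type.
#' @export
default_programs <- function(marker_log_fold = 2.5, baseline_mean = 0.2,
                             dispersion = 2) {
  markers <- list(
    fibroblast      = c("Col1a1", "Col1a2", "Col3a1", "Dcn", "Lum", "Fn1", "Postn", "Pdgfra"),
    macrophage      = c("Cd68", "Lyz2", "Arg1", "Mrc1", "Ms4a7", "Ccr2", "Fcgr1", "Itgam"),
    microglia       = c("P2ry12", "Tmem119", "Cx3cr1", "Hexb", "Siglech", "Trem2", "Csf1r", "Sall1"),
    astrocyte       = c("Gfap", "Aqp4", "Slc1a3", "Aldh1l1", "Vim", "S100b", "Mt3", "Sparcl1"),
    oligodendrocyte = c("Plp1", "Mbp", "Mog", "Mag", "Cnp", "Sox10", "Olig1", "Cldn11"),
    neuron          = c("Snap25", "Rbfox3", "Syt1", "Map2", "Tubb3", "Nefl", "Gap43", "Eno2")
  )
  lapply(stats::setNames(nm = names(markers)), function(t) {
    cell_type_program(t, markers[[t]], marker_log_fold, baseline_mean, dispersion)
  })
}

#' Default planted ligand-receptor interactions
#'
#' Five ligand-receptor pairs planted between adjacent synthetic domains,
#' modeled on pairs reported at glial scar boundaries (Psap-Gpr37l1,
#' Grn-Tnfrsf1b, Spp1-Cd44, Ptn-Plxnb2, Sema4d-Plxnb2).
#'
#' @param effect Additive per-cell mean increment for each planted gene.
#' @return List of `planted_interaction`s.
#' @export
default_interactions <- function(effect = 3) {
  list(
    planted_interaction("Psap",   "Gpr37l1",  "fibroblast", "microglia", effect),
    planted_interaction("Grn",    "Tnfrsf1b", "fibroblast", "microglia", effect),
    planted_interaction("Spp1",   "Cd44",     "microglia",  "astrocyte", effect),
    planted_interaction("Ptn",    "Plxnb2",   "astrocyte",  "microglia", effect),
    planted_interaction("Sema4d", "Plxnb2",   "astrocyte",  "microglia", effect)
  )
}

#' Simulate spot-level UMI counts for a scene
#'
#' Each spot's counts are the sum over its constituent cells of independent
#' negative-binomial draws. Cells are assigned types multinomially from the
#' spot's mixture; within a type, per-cell means are `baseline_mean` for
#' non-markers and `baseline_mean * exp(marker_log_fold)` for that type's
#' markers, plus the additive effects of any planted interactions. The sum
#' over k i.i.d. NB(mu, size) cells is drawn exactly as NB(k*mu, k*size).
#'
#' @param scene A `scar_scene`.
#' @param programs Named list of `cell_type_program`s covering every cell
#'   type in the scene.
#' @param interactions List of `planted_interaction`s (may be empty).
#' @param n_genes Total number of genes; must be at least the number of
#'   distinct named genes (markers, ligands, receptors). Remaining genes are
#'   unstructured fillers named `gene0001`, ...
#' @param seed Integer seed; identical inputs and seed give identical counts.
#'
#' @return A sparse `dgCMatrix` of nonnegative integer counts, genes x
#'   spots, with gene and spot dimnames.
#' @export
sample_counts <- function(scene, programs = default_programs(),
                          interactions = list(), n_genes = 400L, seed = 1L) {
  types_used <- scene$cell_types
  missing <- setdiff(types_used, names(programs))
  if (length(missing) > 0L) {
    stop_invalid("no cell_type_program for scene cell type(s): %s",
                 paste(missing, collapse = ", "))
  }
  # the gene panel covers every supplied program (not just cell types in
  # this scene), so sections from different time points share one universe
  named_genes <- unique(c(
    unlist(lapply(programs, `[[`, "marker_genes"), use.names = FALSE),
    unlist(lapply(interactions, function(it) c(it$ligand_gene, it$receptor_gene)),
           use.names = FALSE)
  ))
  if (n_genes < length(named_genes)) {
    stop_invalid("n_genes (%d) < number of named genes (%d)",
                 n_genes, length(named_genes))
  }
  n_fill <- n_genes - length(named_genes)
  genes <- c(named_genes, if (n_fill > 0L) sprintf("gene%04d", seq_len(n_fill)))

  # per-type mean and size vectors over the gene universe
  mu <- sapply(types_used, function(t) {
    p <- programs[[t]]
    m <- rep(p$baseline_mean, length(genes))
    m[genes %in% p$marker_genes] <- p$baseline_mean * exp(p$marker_log_fold)
    m
  })
  size1 <- vapply(types_used, function(t) programs[[t]]$dispersion, numeric(1))
  for (it in interactions) {
    if (!it$source_type %in% types_used || !it$target_type %in% types_used) next
    mu[match(it$ligand_gene, genes), it$source_type] <-
      mu[match(it$ligand_gene, genes), it$source_type] + it$effect
    mu[match(it$receptor_gene, genes), it$target_type] <-
      mu[match(it$receptor_gene, genes), it$target_type] + it$effect
  }

  spots <- names(scene$cells_per_spot)
  mix <- scene$spot_mixture[spots, types_used, drop = FALSE]
  counts <- with_seed(seed, {
    out <- matrix(0L, length(genes), length(spots))
    for (s in seq_along(spots)) {
      k <- scene$cells_per_spot[[s]]
      ncell <- as.vector(stats::rmultinom(1L, k, mix[s, ]))
      for (j in which(ncell > 0L)) {
        lam <- ncell[j] * mu[, j]
        if (any(lam > 0)) {
          out[, s] <- out[, s] +
            stats::rnbinom(length(genes), mu = lam, size = ncell[j] * size1[j])
        }
      }
    }
    out
  })
  dimnames(counts) <- list(genes, spots)
  methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
              "CsparseMatrix")
}

#' Write a generated scene as on-disk fixtures
#'
#' Writes the counts (Matrix Market + features/barcodes), the spot positions
#' (tissue-positions CSV) and the ground-truth labels (TSV) into `dir`, in
#' exactly the formats the package's readers consume, so the pipeline can be
#' exercised end-to-end through its public readers.
#'
#' @param dir Output directory (created if needed).
#' @param lattice,scene,counts The lattice, scene and count matrix to write.
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_scene_fixtures <- function(dir, lattice, scene, counts) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    matrix   = file.path(dir, "matrix.mtx"),
    features = file.path(dir, "features.tsv"),
    barcodes = file.path(dir, "barcodes.tsv"),
    positions = file.path(dir, "tissue_positions.csv"),
    truth    = file.path(dir, "truth_labels.tsv")
  )
  write_counts(counts, paths["matrix"], paths["features"], paths["barcodes"])
  write_positions(lattice, paths["positions"])
  write_labels(scene$truth_labels, paths["truth"])
  invisible(paths)
}
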