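# Shared fixture builders. All randomized fixtures take an explicit seed so
# every test is reproducible.

# Ring radii scaled to a ~30x30 lattice so every domain is several spots deep.
test_ring_radii <- function() {
  c(fibroblast = 500, microglia = 900, astrocyte = 1300, oligodendrocyte = 1700)
}

# Strong, sharply bounded scene: nearly pure domains, high marker enrichment.
strong_scene <- function(lattice, time_dpi = 14, seed = 1) {
  make_scene(lattice, time_dpi, seed, ring_radii_um = test_ring_radii(),
             boundary_sd_um = 5)
}

strong_programs <- function() {
  default_programs(marker_log_fold = 3.5, baseline_mean = 0.3, dispersion = 5)
}

# Random dense count matrix with dimnames.
random_counts <- function(n_genes, n_spots, seed, lambda = 3) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_spots, lambda), n_genes, n_spots,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_spots))))
    m
  })
}

# Independent lattice-step distance oracle built on igraph shortest paths.
igraph_step_distances <- function(graph) {
  g <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(graph$spot_id) - igraph::vcount(g)))
  igraph::distances(g)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
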