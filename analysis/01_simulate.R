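#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — one lesion scene per time point
# (3, 7, 14, 28 dpi) on a 30 x 30 spot lattice, with the default cell-type
# marker programs and the five planted ligand-receptor pairs, written to
# disk in the same formats the pipeline's readers consume.

suppressPackageStartupMessages(library(scarscape))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lattice <- build_lattice(30, 30, pitch_um = 100, diameter_um = 55)
programs <- default_programs(marker_log_fold = 3.5, baseline_mean = 0.3,
                             dispersion = 5)
interactions <- default_interactions(effect = 5)

ring_radii <- list(
  `3`  = c(macrophage = 500, microglia = 900, astrocyte = 1300, oligodendrocyte = 1700),
  `7`  = c(fibroblast = 550, microglia = 950, astrocyte = 1300, oligodendrocyte = 1700),
  `14` = c(fibroblast = 450, microglia = 800, astrocyte = 1150, oligodendrocyte = 1550),
  `28` = c(fibroblast = 350, microglia = 650, astrocyte = 1000, oligodendrocyte = 1400))

for (dpi in c(3, 7, 14, 28)) {
  scene <- make_scene(lattice, dpi, seed = 100 + dpi,
                      ring_radii_um = ring_radii[[as.character(dpi)]],
                      boundary_sd_um = 5)
  counts <- sample_counts(scene, programs, interactions, n_genes = 300,
                          seed = 200 + dpi)
  dir <- file.path(out, sprintf("dpi%02d", dpi))
  write_scene_fixtures(dir, lattice, scene, counts)
  cat(sprintf("dpi %2d: %d spots, %d genes, %d UMIs total, domains: %s\n",
              dpi, ncol(counts), nrow(counts), sum(counts),
              paste(names(table(scene$truth_labels)), collapse = ", ")))
}
cat(sprintf("fixtures written under %s\n", out))
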