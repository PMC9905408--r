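#!/usr/bin/env Rscript
# Stage 3: quantify scar architecture from the called cell-type labels —
# scar center and radius per time point (in um and in spots), the
# four-layer division, and the cell-type fraction time course over the
# scar.

suppressPackageStartupMessages(library(scarscape))

lattice <- positions_to_lattice(
  read_positions("results/sim/dpi07/tissue_positions.csv"))
scar_types <- c("fibroblast", "macrophage", "microglia", "astrocyte")

labels_by_time <- list()
rows <- list()
for (dpi in c(3, 7, 14, 28)) {
  lab <- read_labels(sprintf("results/labels_dpi%02d.tsv", dpi))
  labels_by_time[[as.character(dpi)]] <- lab
  ctr <- scar_center(lab, lattice, scar_types)
  rad <- scar_radius_spots(lab, lattice, scar_types)
  rows[[as.character(dpi)]] <- data.frame(
    time_dpi = dpi, center_x_um = round(ctr[["x"]], 1),
    center_y_um = round(ctr[["y"]], 1),
    radius_um = round(rad$radius_um, 1), radius_spots = rad$radius_spots)
}
geom <- do.call(rbind, rows)
write.table(geom, "results/scar_geometry.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("scar center and radius per time point:\n")
print(geom, row.names = FALSE)

layers <- assign_layers(lattice, n_layers = 4, axis = "row")
write_labels(setNames(as.character(layers$layers), names(layers$layers)),
             "results/layers.tsv")
cat(sprintf("four layers of %s spots\n",
            paste(table(layers$layers), collapse = "/")))

scar_spots <- lapply(labels_by_time, function(l) names(l)[l %in% scar_types])
fr <- celltype_fractions(labels_by_time, scar_spots)
write.table(fr, "results/celltype_fractions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nscar cell-type fractions over time:\n")
print(fr[fr$cell_type %in% scar_types, ], row.names = FALSE)
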