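#!/usr/bin/env Rscript
# Stage 6: unbiased co-expression modules across the four time points —
# Pearson correlation of the highly-variable genes over all spots and
# times, k-means module assignment, the spatiotemporal map of the module
# holding the fibroblast program, and its hierarchical submodules.

suppressPackageStartupMessages(library(scarscape))

norm_by_time <- list()
for (dpi in c(3, 7, 14, 28)) {
  dir <- sprintf("results/sim/dpi%02d", dpi)
  counts <- read_counts(file.path(dir, "matrix.mtx"),
                        file.path(dir, "features.tsv"),
                        file.path(dir, "barcodes.tsv"))
  norm_by_time[[as.character(dpi)]] <- log_normalize(counts)
}
common <- Reduce(intersect, lapply(norm_by_time, rownames))
combined <- do.call(cbind, lapply(names(norm_by_time), function(tp) {
  m <- norm_by_time[[tp]][common, , drop = FALSE]
  colnames(m) <- paste(tp, colnames(m), sep = ":")
  m
}))

hvg <- select_hvg(combined, 150)
cc <- gene_correlation(combined[hvg, ])
mods <- kmeans_modules(cc, k = 8, seed = 600)
write.table(data.frame(gene = names(mods$assignment), module = mods$assignment),
            "results/gene_modules.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("%d modules over %d HVGs; sizes: %s\n", mods$k,
            length(mods$assignment), paste(mods$sizes, collapse = ", ")))

# which module captured the fibroblast program?
fib <- default_programs()$fibroblast$marker_genes
fib_mod <- as.integer(names(which.max(table(mods$assignment[intersect(fib, hvg)]))))
cat(sprintf("fibroblast markers concentrate in module %d (%d of %d markers)\n",
            fib_mod, sum(mods$assignment[intersect(fib, hvg)] == fib_mod),
            length(intersect(fib, hvg))))

map <- module_spatiotemporal_map(mods$modules[[fib_mod]], norm_by_time)
write.table(map, "results/module_map.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
agg <- tapply(map$mean_expr, map$time_dpi, mean)
cat(sprintf("module %d mean expression by dpi: %s\n", fib_mod,
            paste(sprintf("%s=%.2f", names(agg), agg), collapse = ", ")))

sub <- submodule_hierarchy(mods$modules[[fib_mod]], cc, cut_height = 0.5,
                           module_id = as.character(fib_mod))
write_labels(sub$submodules, "results/submodules.tsv")
cat(sprintf("module %d splits into %d submodules at cut 0.5; largest: %s\n",
            fib_mod, length(unique(sub$submodules)),
            paste(head(names(sub$submodules)[sub$submodules == paste0(fib_mod, ".1")], 6),
                  collapse = ", ")))
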