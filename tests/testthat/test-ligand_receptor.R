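test_that("expression fraction counts nonzero spots", {
  m <- matrix(0, 2, 20, dimnames = list(c("g1", "g2"), sprintf("s%02d", 1:20)))
  m["g1", 1:3] <- 2
  expect_equal(expression_fraction(m, "g1", colnames(m)), 0.15)
  expect_equal(expression_fraction(m, "g2", colnames(m)), 0)
  r <- log_normalize(random_counts(10, 30, seed = 1, lambda = 0.5))
  for (g in rownames(r)[1:3]) {
    expect_equal(expression_fraction(r, g, colnames(r)),
                 sum(r[g, ] > 0) / ncol(r))
  }
  expect_error(expression_fraction(m, "g1", character(0)), "empty")
  expect_error(expression_fraction(m, "nope", colnames(m)), "not in matrix")
})

test_that("pair filter is strict at the threshold", {
  expect_true(pair_filter(0.15, 0.2, 0.1))
  expect_false(pair_filter(0.10, 0.5, 0.1))   # equality fails
  expect_false(pair_filter(0.5, 0.10, 0.1))
  expect_true(pair_filter(0.01, 0.01, 0))
  expect_false(pair_filter(0, 0.5, 0))
})

test_that("interaction score is the mean of the two cluster averages", {
  m <- matrix(0, 2, 8, dimnames = list(c("L", "R"), sprintf("s%d", 1:8)))
  m["L", 1:4] <- 2; m["R", 5:8] <- 4
  expect_equal(interaction_score(m, "L", "R", sprintf("s%d", 1:4),
                                 sprintf("s%d", 5:8)), 3)
  expect_equal(interaction_score(m * 0, "L", "R", colnames(m)[1:4],
                                 colnames(m)[5:8]), 0)
  # swapping genes and spot sets simultaneously leaves the score unchanged
  r <- log_normalize(random_counts(6, 30, seed = 2))
  a <- colnames(r)[1:12]; b <- colnames(r)[13:30]
  expect_equal(interaction_score(r, "g001", "g002", a, b),
               interaction_score(r, "g002", "g001", b, a))
  # brute-force two-mean oracle
  expect_equal(interaction_score(r, "g003", "g004", a, b),
               (mean(as.matrix(r)["g003", a]) + mean(as.matrix(r)["g004", b])) / 2)
  expect_error(interaction_score(m, "L", "R", character(0), "s5"), "non-empty")
})

test_that("permutation p-value: constant gene gives p = 1; seeds reproduce", {
  m <- matrix(1.7, 2, 24, dimnames = list(c("L", "R"), sprintf("s%02d", 1:24)))
  res <- permutation_pvalue(m, "L", "R", colnames(m)[1:10], colnames(m)[11:24],
                            n_perm = 200, seed = 3)
  expect_equal(res$p_value, 1)
  expect_equal(res$p_value_conservative, 1)

  r <- log_normalize(random_counts(4, 40, seed = 4))
  a <- colnames(r)[1:15]; b <- colnames(r)[16:40]
  r1 <- permutation_pvalue(r, "g001", "g002", a, b, n_perm = 300, seed = 9)
  r2 <- permutation_pvalue(r, "g001", "g002", a, b, n_perm = 300, seed = 9)
  expect_identical(r1, r2)
  expect_gte(r1$p_value, 0); expect_lte(r1$p_value, 1)
  expect_error(permutation_pvalue(r, "g001", "g002", a[1], b, n_perm = 10,
                                  seed = 1), "at least 2")
})

test_that("a strong planted interaction at a clean boundary is significant", {
  # ligand only in source spots, receptor only in target spots
  n <- 40
  m <- matrix(0, 3, n, dimnames = list(c("L", "R", "x"), sprintf("s%02d", 1:n)))
  src <- colnames(m)[1:20]; tgt <- colnames(m)[21:40]
  m["L", src] <- withr::with_seed(1, rpois(20, 8) + 1)
  m["R", tgt] <- withr::with_seed(2, rpois(20, 8) + 1)
  res <- permutation_pvalue(log_normalize(m), "L", "R", src, tgt,
                            n_perm = 1000, seed = 5)
  expect_lte(res$p_value, 0.01)
})

test_that("p-values are invariant to gene renaming and spot order", {
  r <- log_normalize(random_counts(5, 36, seed = 6))
  a <- colnames(r)[1:16]; b <- colnames(r)[17:36]
  base <- permutation_pvalue(r, "g001", "g002", a, b, n_perm = 200, seed = 7)
  r2 <- r; rownames(r2) <- sub("^g", "gene_", rownames(r2))
  ren <- permutation_pvalue(r2, "gene_001", "gene_002", a, b, n_perm = 200, seed = 7)
  expect_equal(ren$p_value, base$p_value)
  # permuting the matrix's column order does not change the result
  perm <- withr::with_seed(8, sample(ncol(r)))
  sh <- permutation_pvalue(r[, perm], "g001", "g002", a, b, n_perm = 200, seed = 7)
  expect_equal(sh$p_value, base$p_value)
})

test_that("boundary screen reports both orderings and honors the filter", {
  lat <- build_lattice(8, 8)
  g <- neighbor_graph(lat)
  lab <- setNames(ifelse(lat$array_row <= 3, "A", "B"), lat$spot_id)
  m <- withr::with_seed(10, matrix(rpois(4 * 64, 3), 4, 64,
        dimnames = list(c("L1", "R1", "L2", "R2"), lat$spot_id)))
  m["L2", ] <- 0  # fails the expression filter everywhere
  norm <- log_normalize(m)
  pairs <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"))
  res <- run_boundary_lr(norm, lab, g, pairs, n_perm = 100, seed = 11)
  expect_s3_class(res, "lr_result")
  expect_equal(nrow(res), 4L)  # 2 orderings x 2 pairs
  expect_setequal(paste(res$source_cluster, res$target_cluster),
                  c("A B", "B A"))
  expect_true(all(is.na(res$p_value[res$ligand == "L2"])))
  expect_true(all(!is.na(res$p_value[res$ligand == "L1"])))
  expect_true(all(res$ligand_fraction >= 0 & res$ligand_fraction <= 1))

  # single-cluster labeling: empty result
  empty <- run_boundary_lr(norm, setNames(rep("A", 64), lat$spot_id), g,
                           pairs, n_perm = 10, seed = 1)
  expect_equal(nrow(empty), 0L)
})

test_that("planted pairs dominate the fibroblast-microglia boundary screen", {
  lat <- build_lattice(30, 30)
  sc <- strong_scene(lat, 14, seed = 20)
  ints <- default_interactions(effect = 5)
  cnt <- sample_counts(sc, strong_programs(), ints, n_genes = 150, seed = 21)
  norm <- log_normalize(cnt)
  g <- neighbor_graph(lat)
  planted <- data.frame(
    ligand = vapply(ints[1:2], `[[`, character(1), "ligand_gene"),
    receptor = vapply(ints[1:2], `[[`, character(1), "receptor_gene"))
  decoys <- data.frame(ligand = sprintf("gene%04d", 1:20),
                       receptor = sprintf("gene%04d", 21:40))
  res <- run_boundary_lr(norm, sc$truth_labels, g, rbind(planted, decoys),
                         n_perm = 500, seed = 22)
  fm <- res[res$source_cluster == "fibroblast" & res$target_cluster == "microglia", ]
  fm_planted <- fm[fm$ligand %in% planted$ligand, ]
  expect_equal(nrow(fm_planted), 2L)
  expect_true(all(fm_planted$p_value <= 0.01))
  # planted pairs have the largest mean scores on that boundary
  expect_true(all(fm_planted$mean_score >=
                    max(fm$mean_score[!fm$ligand %in% planted$ligand], na.rm = TRUE)))
})
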