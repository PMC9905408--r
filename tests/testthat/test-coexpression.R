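# Planted-block expression fixture: `blocks` gene groups sharing a latent
# spot factor so within-block correlation ~ r, between-block ~ 0.
planted_block_matrix <- function(n_genes, n_spots, blocks, r = 0.8, seed = 1) {
  withr::with_seed(seed, {
    per <- n_genes %/% blocks
    truth <- rep(seq_len(blocks), length.out = n_genes)
    f <- matrix(rnorm(blocks * n_spots), blocks, n_spots)
    x <- sqrt(r) * f[truth, ] + sqrt(1 - r) * matrix(rnorm(n_genes * n_spots),
                                                     n_genes, n_spots)
    dimnames(x) <- list(sprintf("g%04d", seq_len(n_genes)),
                        sprintf("s%04d", seq_len(n_spots)))
    list(x = x, truth = truth)
  })
}

test_that("gene correlation matches the textbook formula and handles degeneracy", {
  m <- log_normalize(random_counts(8, 30, seed = 3))
  m <- as.matrix(m)
  # duplicated gene -> correlation exactly 1; negated gene -> -1
  m2 <- rbind(m, dup = m[1, ], neg = -m[1, ])
  rownames(m2) <- c(rownames(m), "dup", "neg")
  cc <- gene_correlation(m2)
  expect_equal(cc["g001", "dup"], 1)
  expect_equal(cc["g001", "neg"], -1)
  expect_equal(cc, Matrix::t(cc))
  expect_equal(unname(diag(cc)), rep(1, nrow(m2)))
  expect_true(all(cc >= -1 - 1e-12 & cc <= 1 + 1e-12))

  # brute-force covariance / (sd * sd) oracle
  brute <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    brute[i, j] <- mean((m[i, ] - mean(m[i, ])) * (m[j, ] - mean(m[j, ]))) /
      (sd(m[i, ]) * sd(m[j, ])) * length(m[i, ]) / (length(m[i, ]) - 1)
  }
  expect_equal(unname(cc[1:4, 1:4]), brute, tolerance = 1e-9)

  # zero-variance gene: correlation 0 everywhere, diagonal 1, with warning
  m3 <- rbind(m, flat = rep(5, ncol(m)))
  expect_warning(c3 <- gene_correlation(m3), "zero-variance")
  expect_true(all(c3["flat", setdiff(rownames(m3), "flat")] == 0))
  expect_equal(c3["flat", "flat"], 1)

  expect_error(gene_correlation(m[, 1, drop = FALSE]), "at least 2")
})

test_that("k-means modules recover planted correlation blocks", {
  pb <- planted_block_matrix(40, 200, blocks = 2, r = 0.95, seed = 5)
  cc <- gene_correlation(pb$x)
  mods <- kmeans_modules(cc, k = 2, seed = 1)
  expect_equal(ari(mods$assignment, pb$truth), 1)
  # modules partition the genes and ids are in size order
  expect_setequal(names(mods$assignment), rownames(pb$x))
  expect_equal(sort(unique(mods$assignment)), 1:2)
  expect_true(!is.unsorted(rev(mods$sizes)))

  # k = gene count: singleton modules
  solo <- kmeans_modules(cc[1:6, 1:6] * 0 + diag(6) +
                           matrix(seq(0.01, 0.36, 0.01), 6, 6), k = 6, seed = 2)
  expect_equal(sort(unname(table(solo$assignment))), rep(1L, 6),
               ignore_attr = TRUE)
  expect_error(kmeans_modules(cc, k = 100, seed = 1), "exceeds")
})

test_that("module maps average member genes per spot and time", {
  norms <- list(`7` = log_normalize(random_counts(10, 20, seed = 6)),
                `14` = log_normalize(random_counts(10, 20, seed = 7)))
  # single-gene module: map equals that gene's own map
  map1 <- module_spatiotemporal_map("g003", norms)
  expect_equal(map1$mean_expr[map1$time_dpi == "7"],
               unname(as.matrix(norms[["7"]])["g003", ]))
  # module of identical genes equals any member's map
  dup <- lapply(norms, function(m) {
    m2 <- rbind(as.matrix(m), g_dup = as.matrix(m)["g001", ])
    m2
  })
  map2 <- module_spatiotemporal_map(c("g001", "g_dup"), dup)
  expect_equal(map2$mean_expr[map2$time_dpi == "14"],
               unname(dup[["14"]]["g001", ]))
  expect_error(module_spatiotemporal_map("absent", norms), "absent")
})

test_that("module map localizes a planted fibroblast-core module", {
  lat <- build_lattice(30, 30)
  norms <- list(); truths <- list()
  for (dpi in c(7, 14)) {
    sc <- strong_scene(lat, dpi, seed = dpi)
    cnt <- sample_counts(sc, strong_programs(), n_genes = 200, seed = dpi + 50)
    norms[[as.character(dpi)]] <- log_normalize(cnt)
    truths[[as.character(dpi)]] <- sc$truth_labels
  }
  fib_genes <- strong_programs()$fibroblast$marker_genes
  map <- module_spatiotemporal_map(fib_genes, norms)
  for (dpi in names(norms)) {
    sub <- map[map$time_dpi == dpi, ]
    tr <- truths[[dpi]][sub$spot_id]
    expect_gt(mean(sub$mean_expr[tr == "fibroblast"]),
              mean(sub$mean_expr[tr != "fibroblast"]))
  }
})

test_that("submodule hierarchy matches naive average-linkage agglomeration", {
  # two perfectly correlated pairs, uncorrelated across pairs
  cc <- diag(4); cc[1, 2] <- cc[2, 1] <- 1; cc[3, 4] <- cc[4, 3] <- 1
  dimnames(cc) <- list(letters[1:4], letters[1:4])
  sh <- submodule_hierarchy(letters[1:4], cc, cut_height = 0.5, module_id = "8")
  expect_equal(length(unique(sh$submodules)), 2L)
  expect_equal(sh$submodules[["a"]], sh$submodules[["b"]])
  expect_true(all(grepl("^8\\.[12]$", sh$submodules)))

  # all-identical genes collapse to one submodule at any cut < 1
  cc1 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  sh1 <- submodule_hierarchy(letters[1:3], cc1, cut_height = 0.2)
  expect_equal(length(unique(sh1$submodules)), 1L)

  # merge heights equal a naive repeated-agglomeration oracle (<= 10 genes)
  pb <- planted_block_matrix(8, 60, blocks = 2, r = 0.7, seed = 9)
  cc2 <- gene_correlation(pb$x)
  sh2 <- submodule_hierarchy(rownames(cc2), cc2)
  # naive average-linkage: repeatedly merge the closest pair of clusters,
  # distance = mean pairwise (1 - r) between members
  d <- 1 - cc2; diag(d) <- NA
  clusters <- as.list(rownames(cc2))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < bd) { bd <- avg; best <- c(j, i) }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  expect_equal(sh2$hclust$height, heights, tolerance = 1e-9)

  expect_error(submodule_hierarchy("a", cc1), "at least 2")
  expect_error(submodule_hierarchy(c("a", "zz"), cc1), "missing")
})

test_that("submodule labels are stable under gene-order permutation", {
  pb <- planted_block_matrix(12, 80, blocks = 3, r = 0.9, seed = 10)
  cc <- gene_correlation(pb$x)
  sh <- submodule_hierarchy(rownames(cc), cc)
  perm <- withr::with_seed(11, sample(rownames(cc)))
  sh_p <- submodule_hierarchy(perm, cc[perm, perm])
  expect_equal(sh_p$submodules[names(sh$submodules)], sh$submodules)
})

test_that("planted 6-block benchmark is recovered with high ARI", {
  pb <- planted_block_matrix(120, 300, blocks = 6, r = 0.8, seed = 12)
  cc <- gene_correlation(pb$x)
  mods <- kmeans_modules(cc, k = 6, seed = 13)
  expect_gte(ari(mods$assignment, pb$truth), 0.8)
})
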