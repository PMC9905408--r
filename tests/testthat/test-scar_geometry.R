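test_that("neighbor graph matches a brute-force distance filter", {
  lat <- build_lattice(10, 10)
  g <- neighbor_graph(lat)
  d <- as.matrix(dist(lat[, c("x_um", "y_um")]))
  expected <- which(abs(d - 100) <= 1e-6 & upper.tri(d), arr.ind = TRUE)
  got <- g$edges[order(g$edges[, 1], g$edges[, 2]), , drop = FALSE]
  expected <- expected[order(expected[, 1], expected[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(expected))
  # interior spot degree is 6
  interior <- which(lat$array_row %in% 2:7 & lat$array_col %in% 2:7)
  expect_true(all(lengths(g$adj[interior]) == 6L))
})

test_that("scar center and radius: analytic cases and the mean/max oracle", {
  lat <- build_lattice(6, 6)
  lab <- setNames(rep("neuron", nrow(lat)), lat$spot_id)
  lab[lat$spot_id[14]] <- "fibroblast"
  ctr <- scar_center(lab, lat, "fibroblast")
  expect_equal(unname(ctr), c(lat$x_um[14], lat$y_um[14]))
  r1 <- scar_radius_spots(lab, lat, "fibroblast")
  expect_equal(r1$radius_um, 0)
  expect_equal(r1$radius_spots, 0L)

  # random labeling: centroid equals the brute-force coordinate mean
  lab2 <- withr::with_seed(2, setNames(sample(c("scar", "rest"), nrow(lat), TRUE),
                                       lat$spot_id))
  ctr2 <- scar_center(lab2, lat, "scar")
  sel <- names(lab2)[lab2 == "scar"]
  i <- match(sel, lat$spot_id)
  expect_equal(unname(ctr2), c(mean(lat$x_um[i]), mean(lat$y_um[i])))
  r2 <- scar_radius_spots(lab2, lat, "scar")
  expect_equal(r2$radius_um,
               max(sqrt((lat$x_um[i] - ctr2["x"])^2 + (lat$y_um[i] - ctr2["y"])^2)))

  expect_error(scar_center(lab, lat, "missing_label"), "no spot")
})

test_that("1.2 mm at 100-um pitch is 12 spots", {
  # 25 scar spots in one row: centroid at the middle spot, max distance
  # exactly 12 pitches = 1200 um
  lat <- build_lattice(1, 25)
  lab <- setNames(rep("scar", 25), lat$spot_id)
  r <- scar_radius_spots(lab, lat, "scar")
  expect_equal(r$radius_um, 1200)
  expect_equal(r$radius_spots, 12L)
})

test_that("layers cut equal-width bands along the chosen axis", {
  lat <- build_lattice(40, 6)
  la <- assign_layers(lat, 4, axis = "row")
  by_row <- tapply(la$layers, lat$array_row[match(names(la$layers), lat$spot_id)],
                   unique)
  expect_equal(as.vector(unlist(by_row)), rep(1:4, each = 10))
  # band widths differ by at most one row
  widths <- table(unlist(by_row))
  expect_lte(diff(range(widths)), 1)

  one <- assign_layers(lat, 1)
  expect_true(all(one$layers == 1L))
  expect_error(assign_layers(lat, 0), "n_layers")
})

test_that("interface extraction: half-planes, separated clusters, checkerboard", {
  lat <- build_lattice(10, 10)
  g <- neighbor_graph(lat)
  # two half-planes split between rows 4 and 5
  lab <- setNames(ifelse(lat$array_row <= 4, "A", "B"), lat$spot_id)
  iface <- extract_interface(lab, g, "A", "B", width = 2)
  rows_a <- lat$array_row[match(iface$spots_a, lat$spot_id)]
  rows_b <- lat$array_row[match(iface$spots_b, lat$spot_id)]
  expect_equal(sort(unique(rows_a)), c(3L, 4L))  # two boundary rows per side
  expect_equal(sort(unique(rows_b)), c(5L, 6L))
  expect_equal(length(iface$spots_a), 20L)
  expect_equal(length(iface$spots_b), 20L)

  # clusters separated by a wide third cluster: both sides empty
  lab3 <- setNames(rep("C", nrow(lat)), lat$spot_id)
  lab3[lat$array_row == 0] <- "A"
  lab3[lat$array_row == 9] <- "B"
  far <- extract_interface(lab3, g, "A", "B", width = 2)
  expect_equal(length(far$spots_a), 0L)
  expect_equal(length(far$spots_b), 0L)

  # checkerboard: every spot borders the other cluster
  lab4 <- setNames(ifelse((lat$array_row + lat$array_col) %% 2 == 0, "A", "B"),
                   lat$spot_id)
  cb <- extract_interface(lab4, g, "A", "B", width = 2)
  expect_equal(sort(c(cb$spots_a, cb$spots_b)), sort(lat$spot_id))

  expect_error(extract_interface(lab, g, "A", "nope"), "unknown cluster")
})

test_that("interface bands match the independent BFS oracle and grow with width", {
  for (dims in list(c(6, 8), c(12, 12))) {
    lat <- build_lattice(dims[1], dims[2])
    g <- neighbor_graph(lat)
    dmat <- igraph_step_distances(g)
    for (s in 1:5) {
      lab <- withr::with_seed(100 * dims[1] + s, {
        setNames(sample(c("A", "B", "C"), nrow(lat), TRUE), lat$spot_id)
      })
      ia <- which(lab == "A"); ib <- which(lab == "B")
      if (length(ia) == 0 || length(ib) == 0) next
      prev <- character(0)
      for (w in 1:3) {
        iface <- extract_interface(lab, g, "A", "B", width = w)
        # oracle: graph distance to the nearest opposite-cluster spot
        expect_setequal(iface$spots_a,
                        lat$spot_id[ia][apply(dmat[ia, ib, drop = FALSE], 1, min) <= w])
        expect_setequal(iface$spots_b,
                        lat$spot_id[ib][apply(dmat[ib, ia, drop = FALSE], 1, min) <= w])
        expect_true(all(prev %in% iface$spots_a))  # monotone in width
        prev <- iface$spots_a
      }
    }
  }
})

test_that("domain adjacency equals the brute-force edge scan", {
  lat <- build_lattice(8, 8)
  g <- neighbor_graph(lat)
  lab <- setNames(ifelse(lat$array_row <= 3, "A", "B"), lat$spot_id)
  expect_equal(domain_adjacency(lab, g),
               data.frame(label_a = "A", label_b = "B"))
  expect_equal(nrow(domain_adjacency(setNames(rep("A", 64), lat$spot_id), g)), 0L)

  lab3 <- withr::with_seed(5, setNames(sample(c("A", "B", "C"), 64, TRUE),
                                       lat$spot_id))
  got <- domain_adjacency(lab3, g)
  # oracle: scan every lattice edge
  seen <- unique(t(apply(g$edges, 1, function(e) sort(c(lab3[e[1]], lab3[e[2]])))))
  seen <- seen[seen[, 1] != seen[, 2], , drop = FALSE]
  seen <- seen[order(seen[, 1], seen[, 2]), , drop = FALSE]
  expect_equal(unname(as.matrix(got)), unname(seen))
})

test_that("cell-type fractions count scar spots per time and sum to one", {
  lab <- setNames(c(rep("fibroblast", 4), rep("microglia", 6)),
                  sprintf("s%02d", 1:10))
  tab <- celltype_fractions(list(`7` = lab), list(`7` = names(lab)))
  expect_equal(tab$fraction[tab$cell_type == "fibroblast"], 0.4)
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(tab$n_spots), 10L)

  # single cell type: fraction 1
  one <- celltype_fractions(list(`3` = lab[1:4]), list(`3` = names(lab)[1:4]))
  expect_equal(one$fraction, 1)

  # generated scenes across four time points: tallies match brute force
  lat <- build_lattice(20, 20)
  labs <- lapply(c(`3` = 3, `7` = 7, `14` = 14, `28` = 28), function(dpi) {
    make_scene(lat, dpi, seed = dpi)$truth_labels
  })
  scar <- lapply(labs, function(l) names(l)[l != "neuron"])
  tab <- celltype_fractions(labs, scar)
  for (tp in names(labs)) {
    rows <- tab[tab$time_dpi == tp, ]
    expect_equal(sum(rows$fraction), 1, tolerance = 1e-9)
    expect_equal(sum(rows$n_spots), length(scar[[tp]]))
    brute <- table(labs[[tp]][scar[[tp]]])
    expect_equal(setNames(rows$n_spots, rows$cell_type),
                 setNames(as.integer(brute), names(brute)))
  }
  expect_error(celltype_fractions(list(`3` = lab), list(`3` = character(0))),
               "no scar spots")
})
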