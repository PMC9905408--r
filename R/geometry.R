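# Spatial structure of the lesion: center, radius, layers, interfaces,
# domain adjacency and cell-type fraction time courses.

match_labeled_spots <- function(labels, lattice) {
  idx <- match(names(labels), lattice$spot_id)
  if (anyNA(idx)) {
    stop_invalid("label table contains spot(s) absent from the lattice: %s",
                 paste(utils::head(names(labels)[is.na(idx)], 3L), collapse = ", "))
  }
  idx
}

#' Scar center
#'
#' Centroid (mean x_um, y_um) of the spots carrying a scar label.
#'
#' @param labels Named character vector, spot barcode -> domain label.
#' @param lattice A `spot_lattice` containing all labeled spots.
#' @param scar_labels Labels counted as scar (e.g. fibrotic core plus
#'   immune rings).
#' @return Numeric `c(x, y)` in micrometers.
#' @export
scar_center <- function(labels, lattice, scar_labels) {
  idx <- match_labeled_spots(labels, lattice)
  sel <- idx[labels %in% scar_labels]
  if (length(sel) == 0L) stop_invalid("no spot carries a scar label")
  c(x = mean(lattice$x_um[sel]), y = mean(lattice$y_um[sel]))
}

#' Scar radius in micrometers and in spots
#'
#' Maximum distance from the scar centroid to a scar-labeled spot, and that
#' radius expressed in spot units, `ceiling(radius_um / pitch_um)` (a small
#' numeric guard keeps exact multiples of the pitch from rounding up, so
#' 1.2 mm at 100-um pitch is 12 spots).
#'
#' @inheritParams scar_center
#' @return List with `radius_um` and `radius_spots`.
#' @export
scar_radius_spots <- function(labels, lattice, scar_labels) {
  ctr <- scar_center(labels, lattice, scar_labels)
  idx <- match_labeled_spots(labels, lattice)
  sel <- idx[labels %in% scar_labels]
  r <- max(sqrt((lattice$x_um[sel] - ctr[["x"]])^2 +
                (lattice$y_um[sel] - ctr[["y"]])^2))
  list(radius_um = r,
       radius_spots = as.integer(ceiling(r / lattice_pitch(lattice) - 1e-9)))
}

#' Assign spots to layers
#'
#' Cuts the lattice into `n_layers` equal-width geometric bands
#' perpendicular to the chosen axis, spanning the occupied coordinate range.
#' With `axis = "row"` the bands group consecutive array rows (band widths
#' differ by at most one row when rows divide evenly).
#'
#' @param lattice A `spot_lattice`.
#' @param n_layers Number of bands (>= 1); default 4.
#' @param axis `"row"` (bands along y, the default) or `"col"` (bands
#'   along x).
#' @return A `layer_assignment`: list with `layers` (named integer vector,
#'   spot -> layer in 1..n_layers), `axis`, `n_layers`, `breaks`.
#' @export
assign_layers <- function(lattice, n_layers = 4L, axis = c("row", "col")) {
  axis <- match.arg(axis)
  if (n_layers < 1L) stop_invalid("n_layers must be >= 1")
  coord <- if (axis == "row") lattice$y_um else lattice$x_um
  breaks <- seq(min(coord), max(coord), length.out = n_layers + 1L)
  if (n_layers == 1L || min(coord) == max(coord)) {
    layer <- rep(1L, nrow(lattice))
  } else {
    layer <- findInterval(coord, breaks, rightmost.closed = TRUE)
  }
  structure(
    list(layers = stats::setNames(as.integer(layer), lattice$spot_id),
         axis = axis, n_layers = as.integer(n_layers), breaks = breaks),
    class = "layer_assignment"
  )
}

#' Extract the interface band between two domains
#'
#' The boundary region between two spatial clusters: on each side, the spots
#' whose lattice-graph step distance to the nearest spot of the opposite
#' cluster is at most `width` (default 2, i.e. a band two spots wide along
#' the boundary line on each side). When the clusters are nowhere within
#' `width` steps of each other both sides are empty (not an error).
#'
#' @param labels Named character vector, spot barcode -> label.
#' @param graph A `spot_graph` from [neighbor_graph()].
#' @param cluster_a,cluster_b Labels of the two clusters (must occur in
#'   `labels`).
#' @param width Band width in lattice steps (>= 1).
#' @return An `interface_region`: list with `cluster_a`, `cluster_b`,
#'   `spots_a`, `spots_b` (character barcodes), `width`.
#' @export
extract_interface <- function(labels, graph, cluster_a, cluster_b, width = 2L) {
  if (!cluster_a %in% labels) stop_invalid("unknown cluster label '%s'", cluster_a)
  if (!cluster_b %in% labels) stop_invalid("unknown cluster label '%s'", cluster_b)
  if (width < 1L) stop_invalid("width must be >= 1")
  lab <- labels[match(graph$spot_id, names(labels))]
  ia <- which(!is.na(lab) & lab == cluster_a)
  ib <- which(!is.na(lab) & lab == cluster_b)
  da <- bfs_distance_to_set(graph, ib, max_steps = width)  # distance to b
  db <- bfs_distance_to_set(graph, ia, max_steps = width)  # distance to a
  structure(
    list(cluster_a = cluster_a, cluster_b = cluster_b,
         spots_a = graph$spot_id[ia[da[ia] <= width]],
         spots_b = graph$spot_id[ib[db[ib] <= width]],
         width = as.integer(width)),
    class = "interface_region"
  )
}

#' @export
print.interface_region <- function(x, ...) {
  cat(sprintf("<interface_region> %s | %s (width %d): %d + %d spots\n",
              x$cluster_a, x$cluster_b, x$width,
              length(x$spots_a), length(x$spots_b)))
  invisible(x)
}

#' Adjacent domain pairs
#'
#' The unordered label pairs joined by at least one lattice edge.
#'
#' @inheritParams extract_interface
#' @return Data frame with columns `label_a`, `label_b` (label_a < label_b),
#'   zero rows when no two labels touch.
#' @export
domain_adjacency <- function(labels, graph) {
  lab <- labels[match(graph$spot_id, names(labels))]
  e <- graph$edges
  la <- lab[e[, 1L]]; lb <- lab[e[, 2L]]
  keep <- !is.na(la) & !is.na(lb) & la != lb
  if (!any(keep)) {
    return(data.frame(label_a = character(0), label_b = character(0)))
  }
  a <- pmin(la[keep], lb[keep]); b <- pmax(la[keep], lb[keep])
  pairs <- unique(data.frame(label_a = a, label_b = b))
  pairs <- pairs[order(pairs$label_a, pairs$label_b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Cell-type fraction time course over the scar
#'
#' For each time point, counts the spots of each cell type among the scar
#' spots and their fraction of all scar spots at that time.
#'
#' @param labels_by_time Named list (time as name, e.g. `"3"`) of named
#'   label vectors.
#' @param scar_spots_by_time Named list (same names) of character vectors
#'   of scar spot barcodes.
#' @return Data frame with columns `time_dpi`, `cell_type`, `n_spots`,
#'   `fraction`; fractions sum to 1 within each time point.
#' @export
celltype_fractions <- function(labels_by_time, scar_spots_by_time) {
  if (!setequal(names(labels_by_time), names(scar_spots_by_time))) {
    stop_invalid("labels_by_time and scar_spots_by_time must cover the same time points")
  }
  out <- lapply(names(labels_by_time), function(tp) {
    lab <- labels_by_time[[tp]]
    spots <- scar_spots_by_time[[tp]]
    if (length(spots) == 0L) stop_invalid("no scar spots at time %s", tp)
    missing <- setdiff(spots, names(lab))
    if (length(missing) > 0L) {
      stop_invalid("time %s: scar spot(s) without a label: %s", tp,
                   paste(utils::head(missing, 3L), collapse = ", "))
    }
    tab <- table(lab[spots])
    data.frame(time_dpi = tp, cell_type = names(tab),
               n_spots = as.integer(tab),
               fraction = as.numeric(tab) / length(spots))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
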