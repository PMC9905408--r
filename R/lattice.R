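#' Build a hexagonally packed spot lattice
#'
#' Constructs a Visium-like capture array: spots laid out in a hexagonal
#' (offset-row) packing in which odd array rows are shifted by half a pitch
#' and consecutive rows are `pitch_um * sqrt(3)/2` apart, so every interior
#' spot has six neighbors at exactly `pitch_um` center-to-center distance.
#'
#' @param n_rows,n_cols Number of array rows and columns (>= 1).
#' @param pitch_um Center-to-center distance between adjacent spots, in
#'   micrometers. Default 100, the standard Visium pitch.
#' @param diameter_um Spot diameter in micrometers; must not exceed
#'   `pitch_um`. Default 55.
#'
#' @return A `spot_lattice`: a data frame with columns `spot_id`,
#'   `array_row`, `array_col` (0-based), `x_um`, `y_um`, and attributes
#'   `pitch_um` and `diameter_um`. Coordinates use the image convention:
#'   origin at the top-left spot, y increasing downward.
#'
#' @examples
#' lat <- build_lattice(5, 5)
#' nrow(lat)  # 25
#' @export
build_lattice <- function(n_rows, n_cols, pitch_um = 100, diameter_um = 55) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols)) {
    stop_invalid("n_rows and n_cols must be positive integers")
  }
  if (!is.numeric(pitch_um) || pitch_um <= 0) stop_invalid("pitch_um must be > 0")
  if (!is.numeric(diameter_um) || diameter_um <= 0 || diameter_um > pitch_um) {
    stop_invalid("diameter_um must be in (0, pitch_um]")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  lat <- data.frame(
    spot_id   = sprintf("spot%05d", seq_len(n_rows * n_cols)),
    array_row = row,
    array_col = col,
    x_um      = col * pitch_um + (row %% 2L) * pitch_um / 2,
    y_um      = row * pitch_um * sqrt(3) / 2,
    stringsAsFactors = FALSE
  )
  attr(lat, "pitch_um") <- pitch_um
  attr(lat, "diameter_um") <- diameter_um
  class(lat) <- c("spot_lattice", "data.frame")
  lat
}

#' Default full capture-array lattice
#'
#' The 78-row by 64-column hexagonal lattice (4,992 spots at 100-um pitch,
#' 55-um spot diameter) matching the standard spatial gene expression slide
#' capture area.
#'
#' @return A `spot_lattice` with 4,992 spots.
#' @export
default_lattice <- function() build_lattice(78L, 64L, pitch_um = 100, diameter_um = 55)

#' @export
print.spot_lattice <- function(x, ...) {
  cat(sprintf("<spot_lattice> %d spots, pitch %g um, diameter %g um\n",
              nrow(x), attr(x, "pitch_um"), attr(x, "diameter_um")))
  invisible(x)
}

lattice_pitch <- function(lattice) {
  p <- attr(lattice, "pitch_um")
  if (is.null(p)) stop_invalid("object is not a spot_lattice (missing pitch_um)")
  p
}

#' Spot neighbor graph
#'
#' Builds the lattice adjacency: two spots are neighbors iff their Euclidean
#' distance equals the lattice pitch within a 1e-6 um tolerance. Interior
#' spots of a hexagonal lattice therefore have degree 6. Neighbor search is
#' done on a spatial hash of the coordinates, so it also works for position
#' tables read from disk.
#'
#' @param lattice A `spot_lattice` (or data frame with `spot_id`, `x_um`,
#'   `y_um` and a `pitch_um` attribute).
#' @param tol Distance tolerance in micrometers.
#'
#' @return A `spot_graph`: list with `spot_id` (character vector), `adj`
#'   (list of integer neighbor indices per spot), and `edges` (two-column
#'   integer matrix of index pairs, each edge once with from < to).
#' @export
neighbor_graph <- function(lattice, tol = 1e-6) {
  pitch <- lattice_pitch(lattice)
  n <- nrow(lattice)
  x <- lattice$x_um; y <- lattice$y_um
  # hash spots into pitch-sized cells; neighbors can only be in the 3x3 block
  cx <- floor(x / pitch); cy <- floor(y / pitch)
  key <- paste(cx, cy, sep = ",")
  bins <- split(seq_len(n), key)
  adj <- vector("list", n)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cx[i] + dx, cy[i] + dy, sep = ",")
      b <- bins[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand != i]
    d <- sqrt((x[cand] - x[i])^2 + (y[cand] - y[i])^2)
    nb <- cand[abs(d - pitch) <= tol]
    adj[[i]] <- sort(nb)
    keep <- nb[nb > i]
    from <- c(from, rep(i, length(keep))); to <- c(to, keep)
  }
  structure(
    list(spot_id = lattice$spot_id, adj = adj,
         edges = cbind(from = from, to = to)),
    class = "spot_graph"
  )
}

#' @export
print.spot_graph <- function(x, ...) {
  cat(sprintf("<spot_graph> %d spots, %d edges\n",
              length(x$spot_id), nrow(x$edges)))
  invisible(x)
}

# Multi-source BFS: lattice-step distance from every spot to the nearest
# spot of `sources` (integer indices), capped at `max_steps` (Inf beyond).
bfs_distance_to_set <- function(graph, sources, max_steps = Inf) {
  n <- length(graph$spot_id)
  dist <- rep(Inf, n)
  if (length(sources) == 0L) return(dist)
  dist[sources] <- 0
  frontier <- sources
  step <- 0
  while (length(frontier) > 0L && step < max_steps) {
    step <- step + 1
    nxt <- unique(unlist(graph$adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    if (length(nxt) == 0L) break
    dist[nxt] <- step
    frontier <- nxt
  }
  dist
}
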