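#' Read a gene-by-spot count matrix
#'
#' Reads a Matrix Market coordinate file together with one-per-line gene and
#' barcode lists (CellRanger convention: genes are matrix rows). Values must
#' be nonnegative integers and dimensions must match the name lists.
#'
#' @param matrix_path Matrix Market (.mtx) coordinate file.
#' @param features_path Text file, one gene name per line (first
#'   tab-separated field is used, so CellRanger features.tsv works).
#' @param barcodes_path Text file, one spot barcode per line.
#' @return Sparse `dgCMatrix`, genes x spots, with dimnames.
#' @export
read_counts <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- vapply(strsplit(readLines(features_path), "\t", fixed = TRUE),
                  `[[`, character(1), 1L)
  barcodes <- vapply(strsplit(readLines(barcodes_path), "\t", fixed = TRUE),
                     `[[`, character(1), 1L)
  if (nrow(m) != length(genes)) {
    stop_invalid("%s: matrix has %d rows but %s lists %d features",
                 matrix_path, nrow(m), features_path, length(genes))
  }
  if (ncol(m) != length(barcodes)) {
    stop_invalid("%s: matrix has %d columns but %s lists %d barcodes",
                 matrix_path, ncol(m), barcodes_path, length(barcodes))
  }
  if (anyDuplicated(genes)) stop_invalid("%s: duplicated gene names", features_path)
  if (anyDuplicated(barcodes)) stop_invalid("%s: duplicated barcodes", barcodes_path)
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (length(m@x) > 0L) {
    if (any(m@x < 0)) stop_invalid("%s: negative count values", matrix_path)
    if (any(m@x != round(m@x))) stop_invalid("%s: non-integer count values", matrix_path)
  }
  dimnames(m) <- list(genes, barcodes)
  m
}

#' Write a count matrix as Matrix Market plus name lists
#'
#' @param counts Gene-by-spot matrix with dimnames.
#' @param matrix_path,features_path,barcodes_path Output paths.
#' @return Invisibly, `matrix_path`.
#' @export
write_counts <- function(counts, matrix_path, features_path, barcodes_path) {
  counts <- as_gene_spot_matrix(counts, "counts")
  Matrix::writeMM(counts, matrix_path)
  writeLines(rownames(counts), features_path)
  writeLines(colnames(counts), barcodes_path)
  invisible(matrix_path)
}

#' Read a tissue-positions table
#'
#' Reads the Space Ranger `tissue_positions` CSV dialect: columns barcode,
#' in_tissue (0/1), array_row, array_col, pixel_row, pixel_col. Both the
#' headerless and the headered variant are accepted; the header is detected
#' from the first line's content.
#'
#' @param path CSV path.
#' @param all If `FALSE` (default) only `in_tissue == 1` records are
#'   returned.
#' @return Data frame with columns `barcode`, `in_tissue`, `array_row`,
#'   `array_col`, `pixel_row`, `pixel_col`.
#' @export
read_positions <- function(path, all = FALSE) {
  cols <- c("barcode", "in_tissue", "array_row", "array_col",
            "pixel_row", "pixel_col")
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    # completely empty file: treat as empty table
    pos <- stats::setNames(
      data.frame(character(0), integer(0), integer(0), integer(0),
                 numeric(0), numeric(0)), cols)
    return(pos)
  }
  has_header <- grepl("barcode", first, fixed = TRUE)
  pos <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(pos) != 6L) {
    stop_invalid("%s: expected 6 columns (tissue_positions dialect), found %d",
                 path, ncol(pos))
  }
  names(pos) <- cols
  if (anyDuplicated(pos$barcode)) {
    stop_invalid("%s: duplicate barcode(s): %s", path,
                 paste(unique(pos$barcode[duplicated(pos$barcode)]), collapse = ", "))
  }
  if (!all) pos <- pos[pos$in_tissue == 1L, , drop = FALSE]
  rownames(pos) <- NULL
  pos
}

#' Write a tissue-positions table
#'
#' Writes a `spot_lattice` (or a positions data frame) in the headered
#' tissue-positions CSV dialect. For a lattice, micrometer coordinates are
#' written into the pixel columns (pixel_row = y_um, pixel_col = x_um) and
#' all spots are marked `in_tissue = 1`.
#'
#' @param x A `spot_lattice` or a data frame as returned by
#'   [read_positions()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_positions <- function(x, path) {
  if (inherits(x, "spot_lattice")) {
    x <- data.frame(barcode = x$spot_id, in_tissue = 1L,
                    array_row = x$array_row, array_col = x$array_col,
                    pixel_row = x$y_um, pixel_col = x$x_um)
  }
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a positions table to a spot lattice
#'
#' Reconstructs a `spot_lattice` from a positions table whose pixel columns
#' hold micrometer coordinates (as written by [write_positions()]).
#'
#' @param pos Positions data frame.
#' @param pitch_um,diameter_um Lattice geometry attributes.
#' @return A `spot_lattice`.
#' @export
positions_to_lattice <- function(pos, pitch_um = 100, diameter_um = 55) {
  lat <- data.frame(spot_id = pos$barcode, array_row = pos$array_row,
                    array_col = pos$array_col, x_um = pos$pixel_col,
                    y_um = pos$pixel_row, stringsAsFactors = FALSE)
  attr(lat, "pitch_um") <- pitch_um
  attr(lat, "diameter_um") <- diameter_um
  class(lat) <- c("spot_lattice", "data.frame")
  lat
}

#' Read gene sets from a GMT file
#'
#' Tab-separated GMT lines: set name, description, then gene names. Gene
#' order within a set is preserved; duplicate genes within a set are dropped
#' with a warning. Duplicate set names or lines with fewer than three fields
#' are format errors.
#'
#' @param path GMT path.
#' @return Named list of character vectors (set name -> genes).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop_invalid("%s: line %d has fewer than 3 tab-separated fields",
                 path, short[1L])
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop_invalid("%s: duplicate gene-set name(s): %s", path,
                 paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    if (anyDuplicated(g)) {
      warning(sprintf("gene set '%s': dropping duplicated gene(s): %s", f[1L],
                      paste(unique(g[duplicated(g)]), collapse = ", ")),
              call. = FALSE)
      g <- g[!duplicated(g)]
    }
    g
  })
  stats::setNames(sets, nm)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path, description = "NA") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a barcode-to-label table
#'
#' Two-column tab-separated table mapping spot barcodes to categorical
#' labels (domain labels, truth labels, layer indices, ...).
#'
#' @param labels Named character vector (names are barcodes).
#' @param path TSV path.
#' @return `read_labels()`: a named character vector; `write_labels()`:
#'   invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(barcode = names(labels), label = unname(labels)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (anyDuplicated(tab[[1L]])) stop_invalid("%s: duplicate barcode(s)", path)
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Read or write a barcode-to-score table
#'
#' @param scores Named numeric vector (names are barcodes).
#' @param path TSV path.
#' @return `read_scores()`: a named numeric vector; `write_scores()`:
#'   invisibly, `path`.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(
    data.frame(barcode = names(scores), score = unname(scores)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
}

#' Read a two-column ligand-receptor pair table
#'
#' @param path TSV with columns ligand, receptor (header optional; detected
#'   from the first line).
#' @return Data frame with columns `ligand`, `receptor`.
#' @export
read_lr_pairs <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("ligand", first, ignore.case = TRUE)
  tab <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_invalid("%s: expected 2 columns (ligand, receptor)", path)
  stats::setNames(tab[1:2], c("ligand", "receptor"))
}
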