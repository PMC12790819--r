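# Readers and writers for the package's on-disk formats: TSV coordinate and
# label tables, Matrix Market counts with genes.tsv/cells.tsv companions
# (10x-style triplet, genes x cells), and flat run configs (YAML canonical).

#' Write / read cell coordinates
#'
#' TSV with header `cell_id  x  y [z]`.
#'
#' @param plate a `cell_plate` (or coordinate matrix).
#' @param path file path.
#' @param cell_ids optional ids (default `cell_1` ...).
#' @return the path, invisibly.
#' @export
write_coords <- function(plate, path, cell_ids = NULL) {
  coords <- if (inherits(plate, "cell_plate")) plate$coords else as.matrix(plate)
  df <- data.frame(cell_id = cell_ids %||% paste0("cell_", seq_len(nrow(coords))),
                   coords, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coords
#' @param bounds optional plate bounds; default the coordinate range.
#' @export
read_coords <- function(path, bounds = NULL) {
  df <- read.delim(path, check.names = FALSE)
  axes <- intersect(c("x", "y", "z"), names(df))
  if (!"cell_id" %in% names(df) || length(axes) < 2L)
    .stop_invalid("coordinate file ", path, " lacks a cell_id/x/y header")
  coords <- as.matrix(df[axes])
  if (is.null(bounds))
    bounds <- cbind(min = apply(coords, 2, min), max = apply(coords, 2, max))
  structure(list(coords = coords, bounds = .check_bounds(bounds, ncol(coords)),
                 n_cells = nrow(coords), mode = "loaded",
                 cell_ids = df$cell_id),
            class = "cell_plate")
}

#' Write / read a label table
#'
#' TSV with header `cell_id  cell_type`.
#'
#' @param labels label vector.
#' @param path file path.
#' @param cell_ids optional ids.
#' @return `write_labels()` the path invisibly; `read_labels()` a character
#'   vector named by cell id.
#' @export
write_labels <- function(labels, path, cell_ids = NULL) {
  df <- data.frame(cell_id = cell_ids %||% paste0("cell_", seq_along(labels)),
                   cell_type = as.character(labels))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (!all(c("cell_id", "cell_type") %in% names(df)))
    .stop_invalid("label file ", path, " lacks a cell_id/cell_type header")
  setNames(as.character(df$cell_type), df$cell_id)
}

#' Export a graph adjacency as Matrix Market
#'
#' Writes the symmetric pattern of the adjacency in Matrix Market coordinate
#' format.
#'
#' @param graph a `neighbor_graph`.
#' @param path output `.mtx` path.
#' @return the path, invisibly.
#' @export
write_graph_mm <- function(graph, path) {
  stopifnot(inherits(graph, "neighbor_graph"))
  A <- methods::as(Matrix::forceSymmetric(graph$adjacency), "nsparseMatrix")
  Matrix::writeMM(A, path)
  invisible(path)
}

#' Write a single-cell dataset directory
#'
#' Writes `cells.tsv` (cell_id + coordinates), `labels.tsv`, `matrix.mtx`
#' (genes x cells, Matrix Market) with `genes.tsv`, and a `manifest.json`.
#'
#' @param sc an `sc_st`.
#' @param dir output directory (created if needed).
#' @return the manifest (named list of file paths), invisibly.
#' @export
write_dataset <- function(sc, dir) {
  stopifnot(inherits(sc, "sc_st"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- rownames(sc$counts) %||% paste0("cell_", seq_len(sc$plate$n_cells))
  write_coords(sc$plate, file.path(dir, "cells.tsv"), cell_ids = ids)
  write_labels(sc$labels, file.path(dir, "labels.tsv"), cell_ids = ids)
  M <- methods::as(Matrix::Matrix(t(sc$counts), sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(M, file.path(dir, "matrix.mtx"))
  writeLines(colnames(sc$counts), file.path(dir, "genes.tsv"))
  manifest <- list(cells = "cells.tsv", labels = "labels.tsv",
                   matrix = "matrix.mtx", genes = "genes.tsv",
                   n_cells = sc$plate$n_cells, n_genes = ncol(sc$counts))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  plate <- read_coords(file.path(dir, "cells.tsv"))
  labels <- read_labels(file.path(dir, "labels.tsv"))
  M <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  counts <- t(as.matrix(M))
  storage.mode(counts) <- "integer"
  if (length(genes) != ncol(counts))
    .stop_invalid("genes.tsv does not match matrix.mtx dimensions")
  if (nrow(counts) != plate$n_cells)
    .stop_invalid("matrix.mtx does not match cells.tsv dimensions")
  if (!identical(names(labels), as.character(plate$cell_ids)))
    .stop_invalid("labels.tsv cell ids do not match cells.tsv")
  dimnames(counts) <- list(plate$cell_ids, genes)
  single_cell_st(plate, unname(labels), counts)
}

#' Read a labelled expression reference from disk
#'
#' Accepts either a Matrix Market triplet (`counts` = `.mtx`, `genes` = one
#' gene id per line, `labels` = TSV with cell_id/cell_type) or a single dense
#' delimited table with gene ids in the header or first column. The
#' `orientation` flag declares the matrix layout.
#'
#' @param counts path to `.mtx` or a dense CSV/TSV table.
#' @param labels path to the cell label TSV.
#' @param genes path to the gene id file (Matrix Market input only).
#' @param orientation `"cells_by_genes"` or `"genes_by_cells"`.
#' @return an `expr_reference`.
#' @export
read_labeled_reference <- function(counts, labels, genes = NULL,
                                   orientation = c("cells_by_genes",
                                                   "genes_by_cells")) {
  orientation <- match.arg(orientation)
  lab <- read_labels(labels)
  if (tolower(tools::file_ext(counts)) == "mtx") {
    M <- tryCatch(Matrix::readMM(counts),
                  error = function(e) .stop_invalid(
                    "malformed Matrix Market file ", counts, ": ",
                    conditionMessage(e)))
    mat <- as.matrix(M)
    if (is.null(genes))
      .stop_invalid("Matrix Market input needs a `genes` companion file")
    gid <- readLines(genes)
    if (orientation == "genes_by_cells") mat <- t(mat)
    if (length(gid) != ncol(mat))
      .stop_invalid("gene file ", genes, " does not match ", counts,
                    " dimensions")
    colnames(mat) <- gid
  } else {
    sep <- if (tolower(tools::file_ext(counts)) == "tsv") "\t" else ","
    df <- utils::read.table(counts, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE)
    mat <- as.matrix(df)
    if (orientation == "genes_by_cells") mat <- t(mat)
  }
  if (nrow(mat) != length(lab))
    .stop_invalid("label file ", labels, " has ", length(lab),
                  " cells but the matrix has ", nrow(mat))
  ids <- names(lab)
  if (!is.null(rownames(mat)) && !all(ids %in% rownames(mat)) &&
      !all(rownames(mat) == as.character(seq_len(nrow(mat)))))
    .stop_invalid("label file ", labels,
                  " contains cell ids absent from the matrix")
  if (!is.null(rownames(mat)) && all(ids %in% rownames(mat)))
    mat <- mat[ids, , drop = FALSE]
  expr_reference(mat, unname(lab), cell_ids = ids)
}

#' Write spot-level outputs
#'
#' Writes `counts.mtx` (genes x spots), `spots.tsv`
#' (spot_id, x, y, n_cells), and `composition.tsv` (spot_id + one count
#' column per type), plus `proportions.tsv`.
#'
#' @param spots a `spot_st`.
#' @param dir output directory.
#' @return named list of written files, invisibly.
#' @export
write_spots <- function(spots, dir) {
  stopifnot(inherits(spots, "spot_st"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  M <- methods::as(Matrix::Matrix(t(spots$spot_counts), sparse = TRUE),
                   "CsparseMatrix")
  Matrix::writeMM(M, file.path(dir, "counts.mtx"))
  sdf <- data.frame(spot_id = rownames(spots$spot_counts),
                    spots$grid$centers[, 1:2, drop = FALSE],
                    n_cells = spots$n_cells, check.names = FALSE)
  write.table(sdf, file.path(dir, "spots.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cdf <- data.frame(spot_id = rownames(spots$composition),
                    spots$composition, check.names = FALSE)
  write.table(cdf, file.path(dir, "composition.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pdf_ <- data.frame(spot_id = rownames(spots$composition),
                     spots$proportions, check.names = FALSE)
  write.table(pdf_, file.path(dir, "proportions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(counts = "counts.mtx", spots = "spots.tsv",
                 composition = "composition.tsv",
                 proportions = "proportions.tsv"))
}
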