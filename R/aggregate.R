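#' Build a regular spot lattice
#'
#' Lays out capture spots over the plate. Square lattices place centres on a
#' regular grid at pitch equal to the spot diameter (circle) or side
#' (rectangle), so spots abut without overlapping; hexagonal lattices offset
#' alternate rows by half a pitch with row spacing `pitch * sqrt(3) / 2`.
#' Only spots lying entirely inside the bounds are kept.
#'
#' @param bounds plate bounds (d x 2 matrix; the first two axes are used).
#' @param shape `"circle"` or `"rectangle"`.
#' @param size circle radius, or rectangle side length(s) (scalar or length 2),
#'   in coordinate units.
#' @param lattice `"square"` or `"hexagonal"`.
#' @return an object of class `spot_grid` with spot `centers`, `shape`,
#'   `size`, `lattice`, and per-axis `pitch`.
#' @examples
#' g <- make_spot_lattice(shape = "rectangle", size = 0.5)
#' nrow(g$centers)  # 4 spots tiling the unit square
#' @export
make_spot_lattice <- function(bounds = NULL, shape = c("circle", "rectangle"),
                              size, lattice = c("square", "hexagonal")) {
  shape <- match.arg(shape)
  lattice <- match.arg(lattice)
  dimb <- if (is.null(bounds)) 2L else nrow(as.matrix(bounds))
  bounds <- .check_bounds(bounds, dimb)
  if (!is.numeric(size) || any(size <= 0))
    .stop_invalid("`size` must be positive")
  pitch <- if (shape == "circle") c(2 * size, 2 * size)
           else rep_len(size, 2L)
  span <- bounds[1:2, 2L] - bounds[1:2, 1L]
  if (any(pitch > span + 1e-12))
    .stop_invalid("spot size larger than the plate")

  if (lattice == "square") {
    cx <- seq(bounds[1L, 1L] + pitch[1L] / 2, bounds[1L, 2L] - pitch[1L] / 2 + 1e-12,
              by = pitch[1L])
    cy <- seq(bounds[2L, 1L] + pitch[2L] / 2, bounds[2L, 2L] - pitch[2L] / 2 + 1e-12,
              by = pitch[2L])
    centers <- as.matrix(expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE))
  } else {
    rowstep <- pitch[2L] * sqrt(3) / 2
    cy <- seq(bounds[2L, 1L] + pitch[2L] / 2, bounds[2L, 2L] - pitch[2L] / 2 + 1e-12,
              by = rowstep)
    rows <- lapply(seq_along(cy), function(r) {
      off <- if (r %% 2L == 0L) pitch[1L] / 2 else 0
      cx <- seq(bounds[1L, 1L] + pitch[1L] / 2 + off,
                bounds[1L, 2L] - pitch[1L] / 2 + 1e-12, by = pitch[1L])
      if (!length(cx)) return(NULL)
      cbind(x = cx, y = cy[r])
    })
    centers <- do.call(rbind, rows)
  }
  if (is.null(centers) || nrow(centers) == 0L)
    .stop_invalid("no spot fits inside the plate at this size")
  rownames(centers) <- paste0("spot_", seq_len(nrow(centers)))
  structure(list(centers = centers, shape = shape, size = size,
                 lattice = lattice, pitch = pitch, bounds = bounds),
            class = "spot_grid")
}

#' @export
print.spot_grid <- function(x, ...) {
  cat(sprintf("spot_grid: %d %s spots (%s lattice), size %s\n",
              nrow(x$centers), x$shape, x$lattice,
              paste(signif(x$size, 3), collapse = " x ")))
  invisible(x)
}

#' Aggregate single-cell data to spots
#'
#' Captures each cell into at most one spot (cell-centre membership) and sums
#' the member cells' expression per spot. Rectangle membership uses half-open
#' intervals `[min, max)` per axis so abutting spots never double-count a
#' boundary cell; circle membership is the strict interior, so cells falling
#' in lattice gaps are dropped and reported in `uncaptured`.
#'
#' @param sc an `sc_st` dataset.
#' @param grid a `spot_grid` on the same bounds.
#' @return an object of class `spot_st` with `spot_counts` (spots x genes),
#'   `composition` (spots x K member-cell counts), `proportions`, `n_cells`
#'   per spot, `uncaptured` (number of cells in no spot), and `spot_of`
#'   (per-cell spot index, NA if uncaptured).
#' @export
aggregate_to_spots <- function(sc, grid) {
  stopifnot(inherits(sc, "sc_st"), inherits(grid, "spot_grid"))
  coords <- sc$plate$coords[, 1:2, drop = FALSE]
  n <- nrow(coords)
  ns <- nrow(grid$centers)

  if (grid$shape == "rectangle" && grid$lattice == "square") {
    # exact tile arithmetic: spot s covers [cx - p/2, cx + p/2) per axis
    ox <- min(grid$centers[, 1L]) - grid$pitch[1L] / 2
    oy <- min(grid$centers[, 2L]) - grid$pitch[2L] / 2
    nx <- length(unique(grid$centers[, 1L]))
    ny <- length(unique(grid$centers[, 2L]))
    ix <- floor((coords[, 1L] - ox) / grid$pitch[1L])
    iy <- floor((coords[, 2L] - oy) / grid$pitch[2L])
    ok <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
    spot_of <- ifelse(ok, iy * nx + ix + 1L, NA_integer_)
  } else {
    # nearest centre, then shape membership (non-overlapping spots)
    spot_of <- rep(NA_integer_, n)
    block <- max(1L, floor(2e6 / ns))
    for (start in seq(1L, n, by = block)) {
      rows <- start:min(start + block - 1L, n)
      D <- .dist_block(coords[rows, , drop = FALSE], grid$centers, "euclidean")
      nearest <- max.col(-D, ties.method = "first")
      if (grid$shape == "circle") {
        dmin <- D[cbind(seq_along(rows), nearest)]
        inside <- dmin < grid$size
      } else {
        half <- grid$pitch / 2
        dx <- coords[rows, 1L] - grid$centers[nearest, 1L]
        dy <- coords[rows, 2L] - grid$centers[nearest, 2L]
        inside <- dx >= -half[1L] & dx < half[1L] & dy >= -half[2L] & dy < half[2L]
      }
      spot_of[rows[inside]] <- nearest[inside]
    }
  }

  cl <- .coerce_labels(sc$labels)
  captured <- !is.na(spot_of)
  Sp <- Matrix::sparseMatrix(i = which(captured), j = spot_of[captured], x = 1,
                             dims = c(n, ns))
  spot_counts <- as.matrix(Matrix::crossprod(Sp, sc$counts))
  storage.mode(spot_counts) <- "integer"
  X <- onehot_matrix(cl$codes, cl$K)
  composition <- as.matrix(Matrix::crossprod(Sp, X))
  storage.mode(composition) <- "integer"
  n_cells <- as.integer(Matrix::colSums(Sp))
  rn <- rownames(grid$centers)
  dimnames(spot_counts) <- list(rn, colnames(sc$counts))
  dimnames(composition) <- list(rn, cl$types)
  proportions <- composition / ifelse(n_cells > 0, n_cells, 1)
  structure(list(spot_counts = spot_counts, composition = composition,
                 proportions = proportions, n_cells = n_cells,
                 uncaptured = sum(!captured), spot_of = spot_of,
                 grid = grid, types = cl$types),
            class = "spot_st")
}

#' @export
print.spot_st <- function(x, ...) {
  cat(sprintf("spot_st: %d spots x %d genes; %d cells captured, %d uncaptured\n",
              nrow(x$spot_counts), ncol(x$spot_counts), sum(x$n_cells),
              x$uncaptured))
  cat(sprintf("cells per spot: %d-%d (median %g)\n",
              min(x$n_cells), max(x$n_cells), stats::median(x$n_cells)))
  invisible(x)
}
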