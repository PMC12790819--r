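#' Generate a cell plate
#'
#' Draws `n` cell coordinates on a rectangular (2-D) or box-shaped (3-D) plate,
#' either i.i.d. uniform per axis (`mode = "random"`) or on the most-square
#' regular lattice with at least `n` sites, truncated row-major to exactly `n`
#' points placed at lattice cell centres (`mode = "grid"`).
#'
#' @param n number of cells (positive integer).
#' @param mode `"random"` or `"grid"`.
#' @param bounds d x 2 matrix of per-axis (min, max); defaults to the unit
#'   square/cube.
#' @param dim spatial dimension, 2 or 3.
#' @param seed optional integer seed; identical seeds give identical plates.
#' @return an object of class `cell_plate` with fields `coords` (n x d matrix),
#'   `bounds`, `n_cells`, and `mode`.
#' @examples
#' p <- generate_plate(100, "random", seed = 1)
#' range(p$coords)
#' @export
generate_plate <- function(n, mode = c("random", "grid"), bounds = NULL,
                           dim = 2, seed = NULL) {
  mode <- match.arg(mode)
  n <- .check_count(n, "n")
  dim <- as.integer(dim)
  if (!dim %in% c(2L, 3L)) .stop_invalid("`dim` must be 2 or 3")
  bounds <- .check_bounds(bounds, dim)
  if (!is.null(seed)) set.seed(seed)

  if (mode == "random") {
    coords <- vapply(seq_len(dim),
                     function(a) runif(n, bounds[a, 1L], bounds[a, 2L]),
                     numeric(n))
    coords <- matrix(coords, nrow = n, dimnames = list(NULL, .axis_names(dim)))
  } else {
    sides <- .grid_sides(n, dim)
    centres <- lapply(seq_len(dim), function(a) {
      step <- (bounds[a, 2L] - bounds[a, 1L]) / sides[a]
      bounds[a, 1L] + (seq_len(sides[a]) - 0.5) * step
    })
    # row-major: the first axis varies fastest
    grid <- as.matrix(expand.grid(centres, KEEP.OUT.ATTRS = FALSE))
    coords <- grid[seq_len(n), , drop = FALSE]
    dimnames(coords) <- list(NULL, .axis_names(dim))
  }
  structure(list(coords = coords, bounds = bounds, n_cells = n, mode = mode),
            class = "cell_plate")
}

# most-square per-axis site counts with prod >= n
.grid_sides <- function(n, dim) {
  if (dim == 2L) {
    nx <- ceiling(sqrt(n))
    c(nx, ceiling(n / nx))
  } else {
    nx <- ceiling(n^(1 / 3))
    ny <- ceiling(sqrt(n / nx))
    c(nx, ny, ceiling(n / (nx * ny)))
  }
}

#' @export
print.cell_plate <- function(x, ...) {
  cat(sprintf("cell_plate: %d cells in %d-D (%s)\n", x$n_cells,
              ncol(x$coords), x$mode))
  for (a in seq_len(nrow(x$bounds)))
    cat(sprintf("  %s in [%g, %g]\n", rownames(x$bounds)[a],
                x$bounds[a, 1L], x$bounds[a, 2L]))
  invisible(x)
}

#' @export
plot.cell_plate <- function(x, labels = NULL, pch = 16, cex = 0.5, ...) {
  col <- if (is.null(labels)) "grey30" else as.integer(factor(labels)) + 1L
  graphics::plot(x$coords[, 1L], x$coords[, 2L], col = col, pch = pch,
                 cex = cex, xlab = "x", ylab = "y", asp = 1, ...)
  invisible(x)
}

# ---- pairwise distances (blocked, metric-aware) -----------------------------

.dist_block <- function(X, Y, metric) {
  switch(metric,
    euclidean = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
      sqrt(pmax(d2, 0))
    },
    manhattan = {
      d <- matrix(0, nrow(X), nrow(Y))
      for (a in seq_len(ncol(X)))
        d <- d + abs(outer(X[, a], Y[, a], "-"))
      d
    },
    cosine = {
      nx <- sqrt(rowSums(X^2))
      ny <- sqrt(rowSums(Y^2))
      1 - tcrossprod(X, Y) / outer(nx, ny)
    })
}

.check_metric_ok <- function(coords, metric) {
  if (metric != "cosine") return(invisible(NULL))
  if (any(rowSums(coords^2) == 0))
    .stop_invalid("cosine metric is undefined for zero-norm coordinates")
  if (nrow(unique(coords)) == 1L)
    .stop_invalid("cosine metric is degenerate: all coordinates identical")
  invisible(NULL)
}

# directed k-nearest-neighbour lists; ties at the k-th distance break to the
# lowest index (order() is stable), so graphs are deterministic
.knn_lists <- function(coords, k, metric) {
  n <- nrow(coords)
  block <- max(1L, floor(2e6 / n))
  out <- vector("list", n)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    D <- .dist_block(coords[rows, , drop = FALSE], coords, metric)
    for (r in seq_along(rows)) {
      d <- D[r, ]
      d[rows[r]] <- Inf
      out[[rows[r]]] <- order(d)[seq_len(k)]
    }
  }
  out
}

.radius_pairs <- function(coords, r, metric) {
  n <- nrow(coords)
  block <- max(1L, floor(2e6 / n))
  ii <- jj <- list()
  b <- 0L
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    D <- .dist_block(coords[rows, , drop = FALSE], coords, metric)
    hit <- which(D < r, arr.ind = TRUE)
    if (nrow(hit)) {
      gi <- rows[hit[, 1L]]
      gj <- hit[, 2L]
      keep <- gi < gj           # strict inequality also drops self pairs
      b <- b + 1L
      ii[[b]] <- gi[keep]
      jj[[b]] <- gj[keep]
    }
  }
  cbind(unlist(ii), unlist(jj))
}

#' Build a spatial neighbourhood graph
#'
#' Constructs the sparse symmetric 0/1 adjacency matrix the assignment
#' optimiser runs on. Methods: `knn` (edge if either endpoint nominates the
#' other among its `k` nearest; union symmetrisation), `radius` (edge iff
#' pairwise distance is strictly below `r`), `delaunay` (edges of the 2-D
#' Delaunay triangulation), and `snn` (edge iff the two cells are kNN
#' candidates of each other in at least one direction and share at least
#' `snn_shared` common kNN neighbours).
#'
#' @param plate a `cell_plate`.
#' @param method one of `"knn"`, `"radius"`, `"delaunay"`, `"snn"`.
#' @param param neighbour count `k` (knn/snn) or radius `r` (radius), in the
#'   same units as the coordinates; ignored for `delaunay`.
#' @param metric `"euclidean"` (default), `"cosine"`, or `"manhattan"`,
#'   computed on the raw coordinates.
#' @param snn_shared minimum number of shared kNN neighbours for `snn`.
#' @return an object of class `neighbor_graph` with fields `adjacency` (sparse
#'   symmetric N x N, zero diagonal), `method`, `param`, `metric`, `n`.
#' @examples
#' p <- generate_plate(50, seed = 1)
#' g <- build_graph(p, "knn", 4)
#' Matrix::isSymmetric(g$adjacency)
#' @export
build_graph <- function(plate, method = c("knn", "radius", "delaunay", "snn"),
                        param = NULL, metric = c("euclidean", "cosine", "manhattan"),
                        snn_shared = 1L) {
  stopifnot(inherits(plate, "cell_plate"))
  method <- match.arg(method)
  metric <- match.arg(metric)
  coords <- plate$coords
  n <- nrow(coords)
  .check_metric_ok(coords, metric)

  pairs <- switch(method,
    knn = {
      k <- .check_count(param, "param (k)")
      if (k >= n) .stop_invalid("`k` must satisfy 1 <= k < N")
      nn <- .knn_lists(coords, k, metric)
      i <- rep(seq_len(n), each = k)
      j <- unlist(nn)
      cbind(pmin(i, j), pmax(i, j))
    },
    radius = {
      if (!is.numeric(param) || length(param) != 1L || param <= 0)
        .stop_invalid("`param` must be a positive radius r")
      .radius_pairs(coords, param, metric)
    },
    delaunay = {
      if (ncol(coords) != 2L)
        .stop_invalid("delaunay graphs are supported for 2-D plates only")
      ds <- deldir::deldir(coords[, 1L], coords[, 2L],
                           rw = as.vector(t(plate$bounds)))$delsgs
      cbind(pmin(ds$ind1, ds$ind2), pmax(ds$ind1, ds$ind2))
    },
    snn = {
      k <- .check_count(param, "param (k)")
      if (k >= n) .stop_invalid("`k` must satisfy 1 <= k < N")
      nn <- .knn_lists(coords, k, metric)
      i <- rep(seq_len(n), each = k)
      j <- unlist(nn)
      cand <- unique(cbind(pmin(i, j), pmax(i, j)))
      shared <- vapply(seq_len(nrow(cand)), function(e) {
        length(intersect(nn[[cand[e, 1L]]], nn[[cand[e, 2L]]]))
      }, integer(1))
      cand[shared >= snn_shared, , drop = FALSE]
    })

  pairs <- unique(pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE])
  A <- Matrix::sparseMatrix(i = c(pairs[, 1L], pairs[, 2L]),
                            j = c(pairs[, 2L], pairs[, 1L]),
                            x = 1, dims = c(n, n))
  structure(list(adjacency = A, method = method, param = param,
                 metric = metric, n = n, snn_shared = if (method == "snn") snn_shared),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  ne <- Matrix::nnzero(x$adjacency) / 2
  cat(sprintf("neighbor_graph: %d cells, %d edges (%s%s, %s metric)\n",
              x$n, ne, x$method,
              if (!is.null(x$param)) paste0(", param=", x$param) else "",
              x$metric))
  invisible(x)
}

#' Graph degrees
#' @param graph a `neighbor_graph`.
#' @return integer vector of node degrees.
#' @export
graph_degrees <- function(graph) {
  as.integer(Matrix::rowSums(graph$adjacency))
}
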