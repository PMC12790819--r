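#' Assign cell types by constrained simulated annealing
#'
#' Solves the constrained binary optimisation
#' `argmin_X || P - rownorm(X' A X) ||_F` subject to one label per cell and
#' exact per-type counts (largest-remainder apportionment of
#' `proportions * N`), using one of three strategies:
#' \describe{
#'   \item{gsa}{global simulated annealing: Metropolis annealing over
#'     count-preserving label swaps between pairs of cells, on the whole
#'     plate. Suited to small plates.}
#'   \item{lsa}{local simulated annealing: the plate is split into a regular
#'     grid and each grid cell is annealed independently (seeded as
#'     `seed + grid index`) against the global target, then concatenated and
#'     recalibrated to exact global counts.}
#'   \item{bsa}{batched simulated annealing: the plate is recursively
#'     partitioned into cell zones with window sizes shrinking by powers of
#'     two across epochs (see [epoch_schedule()]). Epoch 1 draws one label per
#'     zone from a multinomial with the target proportions; later epochs
#'     inherit each child zone's label from its parent, then anneal zone
#'     labels on the zone contact graph (two zones are adjacent iff any
#'     inter-zone cell edge exists; contacts are weighted by the number of
#'     such edges, with intra-zone edges on the diagonal, so the zone energy
#'     coarse-grains the cell energy) with `2^m` swaps per iteration. After
#'     the last epoch, zone labels are expanded to cells, recalibrated to
#'     exact counts, and refined by a final cell-level annealing pass.}
#' }
#'
#' All methods return the best-so-far incumbent (never worse than the initial
#' labelling) and satisfy the count constraints exactly on return.
#'
#' @param graph a `neighbor_graph` built on `plate`.
#' @param plate the `cell_plate` the graph was built on.
#' @param spec a `pattern_spec` (target proportions and transition matrix).
#' @param method `"bsa"` (default), `"gsa"`, or `"lsa"`.
#' @param schedule an [epoch_schedule()]; default derived from the plate.
#' @param seed optional integer seed; all randomness flows from it.
#' @param refine run the final cell-level refinement pass (BSA only).
#' @param n_grids grid cells per axis for LSA (default aims at about 1000
#'   cells per grid cell).
#' @return an object of class `cell_assignment` with fields `labels` (integer
#'   codes), `types`, `objective_value`, `trace` (per-iteration objective),
#'   `target_counts`, `method`, `schedule`, `seed`.
#' @examples
#' p <- generate_plate(300, seed = 1)
#' g <- build_graph(p, "knn", 4)
#' sp <- predefined_pattern("attractive", K = 2)
#' a <- assign_celltypes(g, p, sp, method = "gsa", seed = 1)
#' table(a$labels)
#' @export
assign_celltypes <- function(graph, plate, spec,
                             method = c("bsa", "gsa", "lsa"),
                             schedule = NULL, seed = NULL, refine = TRUE,
                             n_grids = NULL) {
  stopifnot(inherits(graph, "neighbor_graph"), inherits(plate, "cell_plate"),
            inherits(spec, "pattern_spec"))
  method <- match.arg(method)
  n <- graph$n
  if (n != plate$n_cells)
    .stop_invalid("graph and plate disagree on the number of cells")
  K <- spec$n_types
  if (K > n) .stop_invalid("more cell types than cells (K > N)")
  targets <- proportion_counts(spec$proportions, n)
  if (!is.null(seed)) set.seed(seed)

  if (.is_disconnected(graph))
    warning("neighbourhood graph is disconnected; annealing proceeds per component",
            call. = FALSE)

  P <- spec$transition
  schedule <- schedule %||% epoch_schedule(n, bounds = plate$bounds)
  csr <- .graph_csr(graph$adjacency)

  if (K == 1L) {
    labels <- rep(1L, n)
    trace <- data.frame(phase = "none", epoch = 0L, temperature = 0,
                        objective = 0, best_objective = 0, acceptance = 0)
  } else if (method == "gsa") {
    labels0 <- sample(rep.int(seq_len(K), targets))
    res <- .run_kernel(labels0, csr, P,
                       t0 = schedule$t0, alpha = schedule$alpha,
                       tmin_frac = schedule$tmin_frac,
                       iters_per_temp = schedule$iters_per_temp,
                       stall_limit = schedule$stall_limit)
    labels <- res$labels
    trace <- cbind(phase = "cell", epoch = 1L, res$trace)
  } else if (method == "lsa") {
    out <- .assign_lsa(graph, plate, spec, schedule, csr, seed, n_grids)
    labels <- recalibrate_proportions(out$labels, targets)
    trace <- out$trace
  } else {
    out <- .assign_bsa(graph, plate, spec, schedule, csr, refine, targets)
    labels <- out$labels
    trace <- out$trace
  }

  obj <- objective(labels, graph$adjacency, P, K = K)
  structure(list(labels = labels, types = spec$types, n = n, K = K,
                 target_counts = targets, objective_value = obj,
                 trace = trace, method = method, schedule = schedule,
                 seed = seed, spec = spec, plate = plate, graph = graph),
            class = "cell_assignment")
}

.is_disconnected <- function(graph) {
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected",
                                           weighted = NULL, diag = FALSE)
  igraph::components(g)$no > 1L
}

# ---- LSA --------------------------------------------------------------------

.assign_lsa <- function(graph, plate, spec, schedule, csr, seed, n_grids) {
  n <- graph$n
  K <- spec$n_types
  g <- n_grids %||% max(1L, ceiling(sqrt(n / 1000)))
  d <- ncol(plate$coords)
  # grid over the first two axes
  gx <- .zone_axis_index(plate$coords[, 1L], plate$bounds[1L, ], g)
  gy <- if (d >= 2L) .zone_axis_index(plate$coords[, 2L], plate$bounds[2L, ], g) else 0L
  grid_id <- gx * g + gy + 1L
  labels <- integer(n)
  traces <- list()
  for (gi in sort(unique(grid_id))) {
    idx <- which(grid_id == gi)
    ng <- length(idx)
    tg <- proportion_counts(spec$proportions, ng)
    if (!is.null(seed)) set.seed(seed + gi)
    labels0 <- sample(rep.int(seq_len(K), tg))
    if (sum(tg > 0L) < 2L || ng < 2L) {
      labels[idx] <- labels0
      next
    }
    sub <- .graph_csr(graph$adjacency[idx, idx, drop = FALSE])
    res <- .run_kernel(labels0, sub, spec$transition,
                       t0 = schedule$t0, alpha = schedule$alpha,
                       tmin_frac = schedule$tmin_frac,
                       iters_per_temp = max(200L, ng),
                       stall_limit = schedule$stall_limit)
    labels[idx] <- res$labels
    traces[[length(traces) + 1L]] <- cbind(phase = paste0("grid_", gi),
                                           epoch = 1L, res$trace)
  }
  list(labels = labels, trace = do.call(rbind, traces))
}

.zone_axis_index <- function(x, rng, nzone) {
  i <- floor((x - rng[1L]) / ((rng[2L] - rng[1L]) / nzone))
  pmin(pmax(as.integer(i), 0L), nzone - 1L)
}

# ---- BSA --------------------------------------------------------------------

.assign_bsa <- function(graph, plate, spec, schedule, csr, refine, targets) {
  n <- graph$n
  K <- spec$n_types
  P <- spec$transition
  d <- ncol(plate$coords)
  M <- schedule$n_epochs
  n0 <- schedule$zones_per_axis

  # base (finest) zone index per cell, per axis
  base_idx <- vapply(seq_len(d), function(a) {
    .zone_axis_index(plate$coords[, a], plate$bounds[a, ], n0[a])
  }, integer(n))
  base_idx <- matrix(base_idx, nrow = n)

  zone_labels <- NULL     # named by linear zone id of the previous epoch
  traces <- list()

  for (m in seq_len(M)) {
    shift <- 2^(M - m)
    epoch_idx <- base_idx %/% shift
    nz_axis <- ceiling(n0 / shift)
    lin <- .linear_zone_id(epoch_idx, nz_axis)
    zs <- sort(unique(lin))
    zid <- match(lin, zs)                      # 1..nz over non-empty zones
    nz <- length(zs)

    if (m == 1L) {
      zl <- sample.int(K, nz, replace = TRUE, prob = spec$proportions)
    } else {
      parent_axis <- epoch_idx %/% 2L
      pnz_axis <- ceiling(n0 / (shift * 2))
      plin <- .linear_zone_id(parent_axis, pnz_axis)
      # one parent per zone: take any member cell's parent id
      first_cell <- match(zs, lin)
      zl <- unname(zone_labels[as.character(plin[first_cell])])
    }

    # zone contact graph: W = Z' A Z, diagonal = intra-zone ordered pairs
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = zid, x = 1, dims = c(n, nz))
    W <- as.matrix(Matrix::crossprod(Z, graph$adjacency %*% Z))
    selfw <- diag(W)
    diag(W) <- 0
    zcsr <- .graph_csr(methods::as(W, "CsparseMatrix"))

    if (nz >= 2L && length(unique(zl)) > 1L) {
      res <- .run_kernel(zl, zcsr, P, selfw = selfw,
                         swaps = schedule$swaps[m],
                         t0 = schedule$t0, alpha = schedule$alpha,
                         tmin_frac = schedule$tmin_frac,
                         iters_per_temp = max(200L, nz),
                         stall_limit = schedule$stall_limit)
      zl <- res$labels
      traces[[length(traces) + 1L]] <- cbind(phase = "zone", epoch = m,
                                             res$trace)
    }
    zone_labels <- setNames(zl, as.character(zs))
    if (m == M) labels <- zl[zid]
  }

  labels <- recalibrate_proportions(labels, targets)

  if (refine && K > 1L) {
    res <- .run_kernel(labels, csr, P,
                       t0 = schedule$t0, alpha = schedule$alpha,
                       tmin_frac = schedule$tmin_frac,
                       iters_per_temp = schedule$iters_per_temp,
                       stall_limit = schedule$stall_limit)
    labels <- res$labels
    traces[[length(traces) + 1L]] <- cbind(phase = "cell", epoch = M + 1L,
                                           res$trace)
  }
  list(labels = labels, trace = do.call(rbind, traces))
}

.linear_zone_id <- function(idx_mat, nz_axis) {
  lin <- idx_mat[, 1L]
  if (ncol(idx_mat) >= 2L)
    for (a in 2L:ncol(idx_mat))
      lin <- lin * nz_axis[a] + idx_mat[, a]
  lin
}

# ---- methods ----------------------------------------------------------------

#' @export
print.cell_assignment <- function(x, ...) {
  cat(sprintf("cell_assignment (%s): %d cells, %d types, objective %.4f\n",
              x$method, x$n, x$K, x$objective_value))
  cnt <- tabulate(x$labels, x$K)
  cat("counts:", paste(sprintf("%s=%d", x$types, cnt), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cell_assignment <- function(object, ...) {
  cat(sprintf("Cell type assignment by %s\n", toupper(object$method)))
  print(object)
  cat("\nachieved transition matrix:\n")
  print(round(transition_frequency(object$labels, .assignment_adjacency(object),
                                   K = object$K), 3))
  cat("\ntarget transition matrix:\n")
  print(round(object$spec$transition, 3))
  invisible(object)
}

.assignment_adjacency <- function(object) object$graph$adjacency

#' @export
plot.cell_assignment <- function(x, ...) {
  plot(x$plate, labels = x$labels, ...)
  invisible(x)
}

#' Extract labels from an assignment
#' @param assignment a `cell_assignment`.
#' @param as_factor return a factor with the type names as levels.
#' @return label vector.
#' @export
assignment_labels <- function(assignment, as_factor = TRUE) {
  if (as_factor)
    factor(assignment$types[assignment$labels], levels = assignment$types)
  else assignment$labels
}

#' Join-count statistic of a labelled graph
#'
#' Fraction of graph edges whose two endpoints carry the same label; a simple
#' spatial-autocorrelation summary (higher = more self-adjacent / segregated).
#'
#' @param graph a `neighbor_graph`.
#' @param labels length-N label vector.
#' @return scalar in [0, 1].
#' @export
join_count <- function(graph, labels) {
  stopifnot(inherits(graph, "neighbor_graph"))
  cl <- .coerce_labels(labels)
  tr <- .adj_triplets(graph$adjacency)
  same <- cl$codes[tr$i] == cl$codes[tr$j]
  mean(same)
}
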