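#' Neighbour-type transition frequency matrix
#'
#' Given a one-hot assignment X (or a label vector) and the graph adjacency A,
#' computes the row-normalised contact count matrix
#' `rownorm(X' A X)`: entry (i, j) is the observed frequency with which a
#' neighbour of a type-i cell has type j. All-zero count rows (types with no
#' neighbour contacts) are returned as all-zero rows and flagged in the
#' `zero_rows` attribute.
#'
#' @param X one-hot N x K matrix or a length-N label vector.
#' @param A adjacency matrix (dense or sparse) or a `neighbor_graph`.
#' @param K number of types when `X` is a label vector.
#' @return K x K matrix with non-zero rows summing to 1.
#' @export
transition_frequency <- function(X, A, K = NULL) {
  if (inherits(A, "neighbor_graph")) A <- A$adjacency
  if (is.null(dim(X))) X <- onehot_matrix(X, K)
  if (nrow(X) != nrow(A))
    .stop_invalid("X and A dimensions do not conform")
  TT <- as.matrix(Matrix::crossprod(X, A %*% X))
  rs <- rowSums(TT)
  out <- TT / ifelse(rs > 0, rs, 1)
  out[rs == 0, ] <- 0
  if (any(rs == 0)) attr(out, "zero_rows") <- unname(which(rs == 0))
  out
}

#' Assignment objective
#'
#' The Frobenius norm `||P - rownorm(X' A X)||_F` minimised by
#' [assign_celltypes()]. Zero iff the assignment reproduces the target
#' transition matrix exactly.
#'
#' @inheritParams transition_frequency
#' @param P K x K row-stochastic target transition matrix (or a
#'   `pattern_spec`).
#' @return non-negative scalar.
#' @export
objective <- function(X, A, P, K = NULL) {
  if (inherits(P, "pattern_spec")) P <- P$transition
  P <- as.matrix(P)
  TF <- transition_frequency(X, A, K = K)
  if (!all(dim(TF) == dim(P)))
    .stop_invalid("dimension mismatch between assignment and target matrix")
  sqrt(sum((P - TF)^2))
}

#' Batched-annealing epoch schedule
#'
#' Derives the epoch structure of the batched simulated annealing (BSA)
#' strategy for a plate of `n` cells: the number of epochs
#' `M = max(1, floor(log2(n / 1000) / 2) + 1)` (clamped to >= 1 for small
#' plates where the formula is non-positive), a base zone grid with
#' `ceiling(n^(1 / (2 d)))` zones per axis (about sqrt(n) zones in total),
#' per-epoch window dimensions `l_m = l0 * 2^(M - m)` that shrink to the base
#' zone size at the final epoch, and per-epoch swap counts `2^m`.
#'
#' The annealing temperature controls are package defaults (the initial
#' temperature is estimated from the mean energy change of 100 random
#' candidate moves unless `t0` is given; geometric cooling by `alpha`;
#' stop below `tmin_frac * t0` or after `stall_limit` consecutive rejected
#' moves).
#'
#' @param n number of cells.
#' @param bounds plate bounds (d x 2); default unit square.
#' @param zone_dims optional (l0, w0, ...) base zone dimensions overriding the
#'   sqrt-n default.
#' @param t0 initial temperature (NULL = auto-estimate).
#' @param alpha geometric cooling factor.
#' @param tmin_frac stop when the temperature falls below `tmin_frac * t0`.
#' @param iters_per_temp proposals per temperature level (NULL = automatic,
#'   `max(200, n)` at cell level).
#' @param stall_limit consecutive rejected proposals before stopping.
#' @return an object of class `anneal_schedule`.
#' @examples
#' epoch_schedule(16000)$n_epochs  # 3
#' @export
epoch_schedule <- function(n, bounds = NULL, zone_dims = NULL,
                           t0 = NULL, alpha = 0.95, tmin_frac = 1e-4,
                           iters_per_temp = NULL, stall_limit = 200L) {
  n <- .check_count(n, "n")
  dimb <- if (is.null(bounds)) 2L else nrow(as.matrix(bounds))
  bounds <- .check_bounds(bounds, dimb)
  d <- nrow(bounds)
  M <- max(1L, as.integer(floor(0.5 * log2(n / 1000)) + 1L))
  if (is.null(zone_dims)) {
    per_axis <- max(1L, ceiling(n^(1 / (2 * d))))
    zone_dims <- (bounds[, 2L] - bounds[, 1L]) / per_axis
    zones_per_axis <- rep(per_axis, d)
  } else {
    zone_dims <- as.numeric(zone_dims)
    if (length(zone_dims) != d || any(zone_dims <= 0))
      .stop_invalid("`zone_dims` must give a positive size per axis")
    zones_per_axis <- ceiling((bounds[, 2L] - bounds[, 1L]) / zone_dims)
  }
  window_dims <- t(vapply(seq_len(M),
                          function(m) zone_dims * 2^(M - m), numeric(d)))
  colnames(window_dims) <- .axis_names(d)
  structure(list(n_epochs = M, zone_dims = zone_dims,
                 zones_per_axis = as.integer(zones_per_axis),
                 window_dims = window_dims,
                 swaps = as.integer(2^seq_len(M)),
                 t0 = t0, alpha = alpha, tmin_frac = tmin_frac,
                 iters_per_temp = iters_per_temp,
                 stall_limit = as.integer(stall_limit),
                 bounds = bounds),
            class = "anneal_schedule")
}

#' @export
print.anneal_schedule <- function(x, ...) {
  cat(sprintf("anneal_schedule: %d epoch(s), base zone grid %s\n",
              x$n_epochs, paste(x$zones_per_axis, collapse = " x ")))
  for (m in seq_len(x$n_epochs))
    cat(sprintf("  epoch %d: window %s, %d swaps/iteration\n", m,
                paste(signif(x$window_dims[m, ], 3), collapse = " x "),
                x$swaps[m]))
  cat(sprintf("  cooling alpha=%g, tmin_frac=%g, stall_limit=%d\n",
              x$alpha, x$tmin_frac, x$stall_limit))
  invisible(x)
}

#' Integer per-type target counts
#'
#' Apportions `n` cells to `K` types from target proportions by the
#' largest-remainder method; ties in the fractional remainders are broken
#' towards the lowest type index.
#'
#' @param proportions length-K non-negative vector summing to 1.
#' @param n total number of cells.
#' @return integer vector summing to `n`.
#' @examples
#' proportion_counts(rep(1 / 3, 3), 10)  # 4 3 3
#' @export
proportion_counts <- function(proportions, n) {
  n <- .check_count(n, "n")
  raw <- proportions / sum(proportions) * n
  base <- floor(raw)
  left <- as.integer(round(n - sum(base)))
  if (left > 0L) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Recalibrate labels to exact target counts
#'
#' Randomly switches cells of surplus types to deficient types until the label
#' counts equal `target_counts` exactly. Cells of types already at (or below)
#' target are never touched.
#'
#' @param labels integer label vector (codes 1..K).
#' @param target_counts integer vector of per-type targets summing to
#'   `length(labels)`.
#' @param graph unused; accepted for interface compatibility with the
#'   assignment pipeline.
#' @param seed optional seed; switched cells are chosen uniformly at random.
#' @return relabelled integer vector with `tabulate(out, K) == target_counts`.
#' @export
recalibrate_proportions <- function(labels, target_counts, graph = NULL,
                                    seed = NULL) {
  labels <- as.integer(labels)
  K <- length(target_counts)
  if (any(target_counts < 0) || any(target_counts != floor(target_counts)))
    .stop_invalid("`target_counts` must be non-negative integers")
  if (sum(target_counts) != length(labels))
    .stop_invalid("`target_counts` must sum to the number of cells")
  if (!is.null(seed)) set.seed(seed)
  cur <- tabulate(labels, K)
  delta <- cur - target_counts
  if (all(delta == 0L)) return(labels)
  donors <- unlist(lapply(which(delta > 0L), function(tp) {
    cand <- which(labels == tp)
    cand[sample.int(length(cand), delta[tp])]
  }))
  slots <- rep(which(delta < 0L), -delta[delta < 0L])
  labels[donors] <- slots[sample.int(length(slots))]
  labels
}

# ---- internal: CSR view of a sparse symmetric adjacency ---------------------

# returns 0-based (ptr, idx, w) arrays; symmetric input means the CSC slots of
# a dgCMatrix double as CSR
.graph_csr <- function(A) {
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  if (!methods::is(A, "dMatrix")) A <- A * 1
  list(ptr = A@p, idx = A@i, w = A@x)
}

.run_kernel <- function(labels, csr, P, selfw = NULL, swaps = 1L,
                        t0 = NULL, alpha = 0.95, tmin_frac = 1e-4,
                        iters_per_temp = NULL, stall_limit = 200L) {
  n <- length(labels)
  .sa_kernel(as.integer(labels), nrow(P),
             as.integer(csr$ptr), as.integer(csr$idx),
             as.numeric(csr$w),
             as.numeric(selfw %||% numeric(n)),
             as.matrix(P),
             as.integer(swaps),
             as.numeric(t0 %||% -1), as.numeric(alpha),
             as.numeric(tmin_frac),
             as.integer(iters_per_temp %||% max(200L, n)),
             as.integer(stall_limit))
}
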