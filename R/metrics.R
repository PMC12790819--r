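#' Adjusted Rand index
#'
#' Agreement between two partitions, corrected for chance:
#' `ARI = (sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(n_i,2) sum_j C(n_j,2) / C(n,2)` and
#' `max = (sum_i C(n_i,2) + sum_j C(n_j,2)) / 2`, where `n_ij` is the
#' contingency table of the two labellings.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return scalar in [-1, 1]; 1 for identical partitions.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    .stop_invalid("label vectors must have equal length")
  tab <- table(labels_a, labels_b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(sum(tab), 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)   # both partitions trivial
  (sij - expected) / (maxi - expected)
}

#' Normalised mutual information
#'
#' Mutual information of the two partitions divided by the arithmetic mean of
#' their entropies (natural log; the ratio is base-invariant). Two trivial
#' single-cluster partitions are defined to agree perfectly (NMI = 1).
#'
#' @inheritParams ari
#' @return scalar in [0, 1].
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    .stop_invalid("label vectors must have equal length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  hx <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hy <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (hx == 0 && hy == 0) return(1)  # both single-cluster
  pos <- pij > 0
  mi <- sum(pij[pos] * log(pij[pos] / outer(pi_, pj_)[pos]))
  mi / ((hx + hy) / 2)
}

#' Transition-matrix discrepancy
#'
#' Frobenius norm between two transition matrices, each given as a
#' `pattern_spec`, a plain matrix, or a `list(graph, labels)` pair estimated
#' via [estimate_pattern()]. Matrices with type names are aligned by name.
#'
#' @param a,b the two patterns/datasets to compare.
#' @return non-negative scalar; 0 for identical patterns.
#' @export
transition_discrepancy <- function(a, b) {
  ta <- .as_transition(a)
  tb <- .as_transition(b)
  if (!is.null(rownames(ta)) && !is.null(rownames(tb))) {
    if (!setequal(rownames(ta), rownames(tb)))
      .stop_invalid("type sets do not match: ",
                    paste(symdiff <- union(setdiff(rownames(ta), rownames(tb)),
                                           setdiff(rownames(tb), rownames(ta))),
                          collapse = ", "))
    tb <- tb[rownames(ta), rownames(ta), drop = FALSE]
  }
  if (!all(dim(ta) == dim(tb)))
    .stop_invalid("transition matrices have different sizes")
  sqrt(sum((ta - tb)^2))
}

.as_transition <- function(x) {
  if (inherits(x, "pattern_spec")) return(x$transition)
  if (is.matrix(x)) return(x)
  if (is.list(x) && length(x) == 2L)
    return(estimate_pattern(x[[1L]], x[[2L]])$transition)
  .stop_invalid("cannot interpret input as a transition matrix")
}

#' Centrality score matrix
#'
#' Per-type network centrality summary `[G1, G2, G3]`:
#' G1 = group degree centrality, the fraction of non-members adjacent to at
#' least one member; G2 = mean local clustering coefficient over member nodes
#' (nodes of degree < 2 contribute 0); G3 = group closeness, the number of
#' non-members divided by the sum of their shortest-path distances to the
#' group (unreachable non-members are excluded and flagged with a warning).
#' A type covering every cell has G1 and G3 undefined (NA).
#'
#' @param graph a `neighbor_graph`.
#' @param labels per-cell labels.
#' @return K x 3 matrix with columns G1, G2, G3, rows named by type.
#' @export
csm <- function(graph, labels) {
  stopifnot(inherits(graph, "neighbor_graph"))
  cl <- .coerce_labels(labels)
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency,
                                           mode = "undirected", diag = FALSE)
  A <- graph$adjacency
  out <- matrix(NA_real_, cl$K, 3,
                dimnames = list(cl$types, c("G1", "G2", "G3")))
  for (t in seq_len(cl$K)) {
    members <- which(cl$codes == t)
    others <- which(cl$codes != t)
    if (length(members) == 0L) next
    cc <- igraph::transitivity(g, type = "local", vids = members)
    cc[is.nan(cc)] <- 0
    out[t, 2L] <- mean(cc)
    if (length(others) == 0L) next  # G1/G3 undefined: type covers the graph
    touched <- Matrix::rowSums(A[others, members, drop = FALSE]) > 0
    out[t, 1L] <- mean(touched)
    dmat <- igraph::distances(g, v = others, to = members)
    dmin <- apply(dmat, 1L, min)
    reach <- is.finite(dmin)
    if (!all(reach))
      warning(sprintf("type %s: %d unreachable non-members excluded from G3",
                      cl$types[t], sum(!reach)), call. = FALSE)
    out[t, 3L] <- if (any(reach)) sum(reach) / sum(dmin[reach]) else NA_real_
  }
  out
}

#' Neighbourhood enrichment matrix
#'
#' Permutation z-scores of inter-type contact counts. The observed statistic
#' `x_ij` counts ordered adjacent endpoint pairs with types (i, j). The null
#' keeps the graph fixed and shuffles the labels (`n_perms` uniform
#' permutations, or every distinct arrangement of the label multiset when
#' `exhaustive = TRUE`); `z = (x - mu) / sigma` with the population (divide by
#' m) standard deviation, and `z = 0` whenever `sigma = 0` and `x = mu`.
#'
#' @param graph a `neighbor_graph`.
#' @param labels per-cell labels.
#' @param n_perms number of label shuffles (>= 2) for the Monte-Carlo null.
#' @param seed optional seed.
#' @param exhaustive enumerate all distinct label arrangements instead of
#'   sampling (small plates only; errors above `max_arrangements`).
#' @param max_arrangements safety cap for `exhaustive = TRUE`.
#' @return K x K symmetric z-score matrix.
#' @export
nem <- function(graph, labels, n_perms = 1000, seed = NULL,
                exhaustive = FALSE, max_arrangements = 1e5) {
  stopifnot(inherits(graph, "neighbor_graph"))
  cl <- .coerce_labels(labels)
  K <- cl$K
  tr <- .adj_triplets(graph$adjacency)
  ei <- tr$i
  ej <- tr$j

  count_mat <- function(codes) {
    idx <- (codes[ej] - 1L) * K + codes[ei]
    matrix(tabulate(idx, K * K), K, K)
  }
  x <- count_mat(cl$codes)

  if (exhaustive) {
    arr <- .multiset_arrangements(cl$codes, max_arrangements)
    stats <- vapply(arr, count_mat, matrix(0, K, K))
  } else {
    if (n_perms < 2) .stop_invalid("`n_perms` must be >= 2")
    if (!is.null(seed)) set.seed(seed)
    stats <- vapply(seq_len(n_perms),
                    function(b) count_mat(sample(cl$codes)),
                    matrix(0, K, K))
  }
  mu <- apply(stats, c(1, 2), mean)
  sigma <- sqrt(apply(stats, c(1, 2), function(v) mean((v - mean(v))^2)))
  z <- (x - mu) / sigma
  z[sigma == 0 & x == mu] <- 0
  dimnames(z) <- list(cl$types, cl$types)
  z
}

# all distinct arrangements of a label multiset (recursive; small n only)
.multiset_arrangements <- function(codes, cap) {
  counts <- tabulate(codes, max(codes))
  total <- exp(lgamma(length(codes) + 1) - sum(lgamma(counts + 1)))
  if (total > cap)
    .stop_invalid("too many arrangements for exhaustive enumeration (",
                  format(total, digits = 3), " > ", cap, ")")
  out <- list()
  rec <- function(prefix, remaining) {
    if (all(remaining == 0L)) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (t in which(remaining > 0L)) {
      remaining[t] <- remaining[t] - 1L
      rec(c(prefix, t), remaining)
      remaining[t] <- remaining[t] + 1L
    }
  }
  rec(integer(0), counts)
  out
}

#' Ripley's L function
#'
#' Point-pattern statistic for one cell type:
#' `K(t) = area / (n (n - 1)) * sum_{i != j} 1[d_ij <= t]` and
#' `L(t) = sqrt(K(t) / pi)`. Under complete spatial randomness (CSR, a
#' homogeneous Poisson process) `L(t) = t`; `L > t` indicates clustering and
#' `L < t` dispersion. No edge correction is applied by default (curves are
#' compared on matched geometry); `correction = "border"` restricts the outer
#' sum to points further than `t` from the boundary.
#'
#' @param coords n x 2 coordinate matrix of one type's cells.
#' @param bounds plate bounds (2 x 2).
#' @param t_grid strictly increasing positive distances.
#' @param correction `"none"` (default) or `"border"`.
#' @return data.frame with columns `t`, `L`, and the CSR baseline `csr = t`.
#' @export
ripley_l <- function(coords, bounds = NULL, t_grid = seq(0.01, 0.25, by = 0.01),
                     correction = c("none", "border")) {
  correction <- match.arg(correction)
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  n <- nrow(coords)
  if (n < 2L) .stop_invalid("Ripley's L needs at least 2 points")
  t_grid <- as.numeric(t_grid)
  if (any(t_grid <= 0) || any(diff(t_grid) <= 0))
    .stop_invalid("`t_grid` must be positive and strictly increasing")
  bounds <- .check_bounds(bounds, 2L)
  area <- prod(bounds[, 2L] - bounds[, 1L])

  D <- .dist_block(coords, coords, "euclidean")
  diag(D) <- Inf
  if (correction == "none") {
    dvec <- sort(D[is.finite(D)])
    counts <- findInterval(t_grid, dvec)       # ordered pairs with d <= t
    Khat <- area * counts / (n * (n - 1))
  } else {
    bdist <- pmin(coords[, 1L] - bounds[1L, 1L], bounds[1L, 2L] - coords[, 1L],
                  coords[, 2L] - bounds[2L, 1L], bounds[2L, 2L] - coords[, 2L])
    Khat <- vapply(t_grid, function(t) {
      keep <- bdist >= t
      if (!any(keep)) return(NA_real_)
      area * sum(D[keep, , drop = FALSE] <= t) / (sum(keep) * (n - 1))
    }, numeric(1))
  }
  data.frame(t = t_grid, L = sqrt(Khat / pi), csr = t_grid)
}

#' Per-type Ripley's L curves
#'
#' Convenience wrapper computing [ripley_l()] for each cell type; types with
#' fewer than 2 cells are skipped with a warning.
#'
#' @param coords n x 2 coordinates of all cells.
#' @param labels per-cell labels.
#' @inheritParams ripley_l
#' @return long data.frame with columns `type`, `t`, `L`, `csr`.
#' @export
ripley_curves <- function(coords, labels, bounds = NULL,
                          t_grid = seq(0.01, 0.25, by = 0.01),
                          correction = "none") {
  cl <- .coerce_labels(labels)
  out <- lapply(seq_len(cl$K), function(t) {
    idx <- cl$codes == t
    if (sum(idx) < 2L) {
      warning("type ", cl$types[t], " has < 2 cells; skipped", call. = FALSE)
      return(NULL)
    }
    cbind(type = cl$types[t],
          ripley_l(coords[idx, , drop = FALSE], bounds, t_grid, correction))
  })
  do.call(rbind, out)
}

#' Cosine similarity of two curves
#'
#' Standard cosine of two equal-length numeric vectors (e.g. two Ripley L
#' curves evaluated on the same distance grid). Undefined (NA, with a
#' warning) if either vector is all zero.
#'
#' @param curve_a,curve_b equal-length numeric vectors.
#' @return scalar in [-1, 1].
#' @export
curve_cosine <- function(curve_a, curve_b) {
  if (length(curve_a) != length(curve_b))
    .stop_invalid("curves must share the same grid")
  na <- sqrt(sum(curve_a^2))
  nb <- sqrt(sum(curve_b^2))
  if (na == 0 || nb == 0) {
    warning("cosine similarity undefined for a zero curve", call. = FALSE)
    return(NA_real_)
  }
  sum(curve_a * curve_b) / (na * nb)
}

#' Set similarity index
#'
#' Overlap of two sets normalised by the smaller set:
#' `SI = |A intersect B| / min(|A|, |B|)`, a size-corrected Jaccard variant
#' used to compare predicted ligand-receptor pair sets.
#'
#' @param set_a,set_b non-empty vectors of identifiers.
#' @return scalar in [0, 1].
#' @export
si <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!length(set_a) || !length(set_b))
    .stop_invalid("SI is undefined for empty sets")
  length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}

#' Ranked ligand-receptor set
#'
#' Pairs ranked 1..n by descending score (ties broken by first occurrence,
#' deterministically).
#'
#' @param pairs unique pair identifiers.
#' @param scores per-pair scores.
#' @return an object of class `ranked_lr_set` with fields `pairs`, `scores`,
#'   `ranks`.
#' @export
ranked_lr_set <- function(pairs, scores) {
  if (anyDuplicated(pairs)) .stop_invalid("`pairs` must be unique")
  if (length(pairs) != length(scores))
    .stop_invalid("`pairs` and `scores` must have equal length")
  ranks <- rank(-as.numeric(scores), ties.method = "first")
  structure(list(pairs = as.character(pairs), scores = as.numeric(scores),
                 ranks = as.integer(ranks)),
            class = "ranked_lr_set")
}

#' Rank-based similarity index
#'
#' For the overlap `C = A intersect B`,
#' `RSI = 1 - mean_i |R_A(i)/|A| - R_B(i)/|B||` over the pairs in C, where
#' ranks are taken within each full set. 1 means the shared pairs occupy the
#' same relative positions in both rankings. Undefined (NA, with a warning)
#' when the overlap is empty.
#'
#' @param ranked_a,ranked_b two [ranked_lr_set()] objects.
#' @return scalar <= 1.
#' @export
rsi <- function(ranked_a, ranked_b) {
  stopifnot(inherits(ranked_a, "ranked_lr_set"),
            inherits(ranked_b, "ranked_lr_set"))
  common <- intersect(ranked_a$pairs, ranked_b$pairs)
  if (!length(common)) {
    warning("RSI undefined: no overlapping pairs", call. = FALSE)
    return(NA_real_)
  }
  ra <- ranked_a$ranks[match(common, ranked_a$pairs)] / length(ranked_a$pairs)
  rb <- ranked_b$ranks[match(common, ranked_b$pairs)] / length(ranked_b$pairs)
  1 - mean(abs(ra - rb))
}

#' Tidy metric report
#'
#' Collects named metric values into the package's tidy CSV layout
#' (metric, type_or_pair, value) and optionally writes it.
#'
#' @param ... named scalar metrics, or matrices (flattened row-by-column).
#' @param path optional CSV output path.
#' @return data.frame with columns `metric`, `type_or_pair`, `value`.
#' @export
metric_report <- function(..., path = NULL) {
  vals <- list(...)
  rows <- lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    if (is.matrix(v)) {
      idx <- expand.grid(row = rownames(v) %||% seq_len(nrow(v)),
                         col = colnames(v) %||% seq_len(ncol(v)))
      data.frame(metric = nm,
                 type_or_pair = paste(idx$row, idx$col, sep = ":"),
                 value = as.vector(v))
    } else {
      data.frame(metric = nm,
                 type_or_pair = names(v) %||% rep("", length(v)),
                 value = as.numeric(v))
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
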