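# Small graph/plate builders used across the suite. Graphs built directly
# from an adjacency matrix bypass the geometric constructors so that
# hand-enumerable topologies (paths, cliques, bridges) can be tested exactly.

`%||%` <- function(x, y) if (is.null(x)) y else x

graph_from_adjacency <- function(A) {
  A <- Matrix::Matrix(as.matrix(A) * 1, sparse = TRUE)
  structure(list(adjacency = A, method = "custom", param = NULL,
                 metric = "euclidean", n = nrow(A)),
            class = "neighbor_graph")
}

path_graph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  graph_from_adjacency(A)
}

clique_graph <- function(n) {
  A <- matrix(1, n, n) - diag(n)
  graph_from_adjacency(A)
}

# two disjoint cliques of size n1, n2
two_cliques <- function(n1, n2) {
  A <- matrix(0, n1 + n2, n1 + n2)
  A[seq_len(n1), seq_len(n1)] <- 1
  A[n1 + seq_len(n2), n1 + seq_len(n2)] <- 1
  diag(A) <- 0
  graph_from_adjacency(A)
}

# two triangles {1,2,3} and {4,5,6} joined by the bridge 3-4
bridged_triangles <- function() {
  A <- matrix(0, 6, 6)
  tri <- function(v) for (p in combn(v, 2, simplify = FALSE))
    A[p[1], p[2]] <<- A[p[2], p[1]] <<- 1
  tri(1:3); tri(4:6)
  A[3, 4] <- A[4, 3] <- 1
  graph_from_adjacency(A)
}

# plate with explicit coordinates
make_plate <- function(coords, bounds = NULL) {
  coords <- as.matrix(coords)
  colnames(coords) <- c("x", "y", "z")[seq_len(ncol(coords))]
  if (is.null(bounds))
    bounds <- cbind(min = apply(coords, 2, min) - 0.5,
                    max = apply(coords, 2, max) + 0.5)
  structure(list(coords = coords, bounds = bounds, n_cells = nrow(coords),
                 mode = "fixed"),
            class = "cell_plate")
}

# undirected edge list (i < j) of a graph, as a sorted two-column matrix
edge_list <- function(graph) {
  tr <- Matrix::summary(methods::as(graph$adjacency, "TsparseMatrix"))
  e <- unique(cbind(pmin(tr$i, tr$j), pmax(tr$i, tr$j)))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# brute-force objective minimum over all count-feasible two-type labelings
enumerate_min_objective <- function(graph, P, n_type1) {
  n <- graph$n
  A <- graph$adjacency
  best <- Inf
  for (set in combn(n, n_type1, simplify = FALSE)) {
    lab <- rep(2L, n)
    lab[set] <- 1L
    best <- min(best, objective(lab, A, P, K = 2L))
  }
  best
}
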