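`%||%` <- function(x, y) if (is.null(x)) y else x

# both directions of every edge as triplets (symmetric storage only keeps one
# triangle, so force general storage first)
.adj_triplets <- function(A) {
  A <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
  list(i = A@i + 1L, j = A@j + 1L, x = A@x)
}

.stop_invalid <- function(...) stop(..., call. = FALSE)

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    .stop_invalid(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .stop_invalid(sprintf("`%s` must be a probability in [0, 1]", name))
  as.numeric(x)
}

# bounds: d x 2 matrix with columns (min, max)
.check_bounds <- function(bounds, dim) {
  if (is.null(bounds))
    bounds <- matrix(rep(c(0, 1), each = dim), nrow = dim,
                     dimnames = list(c("x", "y", "z")[seq_len(dim)], c("min", "max")))
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != dim || ncol(bounds) != 2L)
    .stop_invalid("`bounds` must be a ", dim, " x 2 matrix of (min, max) per axis")
  if (any(!is.finite(bounds)) || any(bounds[, 2L] <= bounds[, 1L]))
    .stop_invalid("`bounds` are degenerate: every axis needs max > min")
  if (is.null(rownames(bounds)))
    rownames(bounds) <- c("x", "y", "z")[seq_len(dim)]
  colnames(bounds) <- c("min", "max")
  bounds
}

.axis_names <- function(dim) c("x", "y", "z")[seq_len(dim)]

# labels coerced to integer codes 1..K plus a type-name vector
.coerce_labels <- function(labels, types = NULL) {
  if (is.factor(labels)) {
    types <- types %||% levels(labels)
    codes <- as.integer(labels)
  } else if (is.character(labels)) {
    types <- types %||% sort(unique(labels))
    codes <- match(labels, types)
  } else {
    codes <- as.integer(labels)
    if (any(is.na(codes)) || any(codes < 1L))
      .stop_invalid("integer labels must be positive type codes")
    types <- types %||% as.character(seq_len(max(codes)))
  }
  if (any(is.na(codes)))
    .stop_invalid("labels contain values not present in the type set")
  list(codes = codes, types = types, K = length(types))
}

#' One-hot label matrix
#'
#' Expands a length-N label vector into the sparse N x K indicator matrix used
#' by the assignment objective (one 1 per row).
#'
#' @param labels integer, character, or factor label vector.
#' @param K number of types; defaults to the number of distinct labels.
#' @return a sparse `Matrix` with one column per type.
#' @export
onehot_matrix <- function(labels, K = NULL) {
  cl <- .coerce_labels(labels)
  K <- K %||% cl$K
  Matrix::sparseMatrix(i = seq_along(cl$codes), j = cl$codes, x = 1,
                       dims = c(length(cl$codes), K),
                       dimnames = list(NULL, cl$types[seq_len(K)]))
}
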