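#' Construct and validate a spatial pattern specification
#'
#' A pattern specification is the target of the assignment optimiser: cell-type
#' proportions `proportions` (length K, non-negative, summing to 1) and a
#' row-stochastic K x K transition matrix `transition` giving the probability
#' that a neighbour of a type-i cell has type j.
#'
#' @param proportions length-K numeric vector of type proportions.
#' @param transition K x K row-stochastic matrix.
#' @param mode free-text pattern mode tag (e.g. `"custom"`, `"attractive"`).
#' @param types optional type names (default `type_1` ... `type_K`).
#' @param layout optional [layer_layout()] carried by layered/gyrus patterns.
#' @param allow_zero_rows allow all-zero transition rows (used for estimates
#'   from data where a type has no observed neighbours; such rows are flagged).
#' @return an object of class `pattern_spec`.
#' @export
pattern_spec <- function(proportions, transition, mode = "custom",
                         types = NULL, layout = NULL, allow_zero_rows = FALSE) {
  proportions <- as.numeric(proportions)
  K <- length(proportions)
  transition <- as.matrix(transition)
  if (K < 1L) .stop_invalid("need at least one cell type")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    .stop_invalid("`proportions` must be non-negative and sum to 1 (tol 1e-9)")
  if (!all(dim(transition) == c(K, K)))
    .stop_invalid("`transition` must be K x K with K = length(proportions)")
  if (any(transition < -1e-12) || any(transition > 1 + 1e-12))
    .stop_invalid("`transition` entries must lie in [0, 1]")
  rs <- rowSums(transition)
  bad <- abs(rs - 1) > 1e-9
  if (allow_zero_rows) bad <- bad & rs != 0
  if (any(bad))
    .stop_invalid("every row of `transition` must sum to 1 (tol 1e-9)")
  types <- types %||% paste0("type_", seq_len(K))
  dimnames(transition) <- list(types, types)
  names(proportions) <- types
  structure(list(n_types = K, proportions = proportions,
                 transition = transition, mode = mode, types = types,
                 layout = layout),
            class = "pattern_spec")
}

#' @export
print.pattern_spec <- function(x, ...) {
  cat(sprintf("pattern_spec (%s): %d types\n", x$mode, x$n_types))
  cat("proportions:", paste(sprintf("%s=%.3g", x$types, x$proportions),
                            collapse = ", "), "\n")
  cat("transition matrix:\n")
  print(round(x$transition, 3))
  invisible(x)
}

#' Layer layout for layered and gyrus patterns
#'
#' Describes straight (or sinusoidally folded) strata along one axis of the
#' plate. Each layer has a dominant cell type drawn with probability
#' `dominant_prob`; the remaining probability mass is uniform over the other
#' types.
#'
#' @param n_layers number of layers (>= 1).
#' @param bounds plate bounds (d x 2); default unit square.
#' @param axis axis index the layers are stacked along (default 2 = y).
#' @param dominant_prob multinomial parameter of each layer's dominant type,
#'   default 0.8.
#' @param boundaries optional strictly increasing interior break positions
#'   along the axis (length `n_layers - 1`); defaults to equal strata.
#' @param wave_amplitude amplitude (coordinate units) of the sinusoidal
#'   displacement of layer boundaries; 0 gives straight strata, > 0 gives the
#'   folded "gyrus" geometry.
#' @param wave_frequency number of full folds across the plate.
#' @return an object of class `layer_layout`.
#' @export
layer_layout <- function(n_layers, bounds = NULL, axis = 2L,
                         dominant_prob = 0.8, boundaries = NULL,
                         wave_amplitude = 0, wave_frequency = 1) {
  n_layers <- .check_count(n_layers, "n_layers")
  dominant_prob <- .check_prob(dominant_prob, "dominant_prob")
  if (dominant_prob <= 0) .stop_invalid("`dominant_prob` must be > 0")
  dimb <- if (is.null(bounds)) 2L else nrow(as.matrix(bounds))
  bounds <- .check_bounds(bounds, dimb)
  axis <- .check_count(axis, "axis")
  if (axis > nrow(bounds)) .stop_invalid("`axis` exceeds plate dimension")
  lo <- bounds[axis, 1L]; hi <- bounds[axis, 2L]
  if (is.null(boundaries)) {
    boundaries <- lo + (hi - lo) * seq_len(n_layers - 1L) / n_layers
  }
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != n_layers - 1L)
    .stop_invalid("`boundaries` must have length n_layers - 1")
  if (n_layers > 1L &&
      (any(diff(c(lo, boundaries, hi)) <= 0)))
    .stop_invalid("`boundaries` must be strictly increasing inside the plate bounds")
  structure(list(n_layers = n_layers, bounds = bounds, axis = axis,
                 dominant_prob = dominant_prob, boundaries = boundaries,
                 wave_amplitude = wave_amplitude,
                 wave_frequency = wave_frequency),
            class = "layer_layout")
}

# transition matrix implied by a chain of layers: high self-transition,
# residual mass split over the adjacent layers' types (package default)
.layered_transition <- function(K, dominant_prob) {
  P <- matrix(0, K, K)
  if (K == 1L) return(matrix(1, 1, 1))
  for (i in seq_len(K)) {
    P[i, i] <- dominant_prob
    nb <- intersect(c(i - 1L, i + 1L), seq_len(K))
    P[i, nb] <- (1 - dominant_prob) / length(nb)
  }
  P
}

#' Predefined spatial patterns
#'
#' Builds the pattern specification for one of the package's predefined
#' spatial organisations:
#' \describe{
#'   \item{attractive}{each type clusters with itself: transition diagonal
#'     `dominant_prob` (default 0.8), off-diagonal uniform.}
#'   \item{repulsive}{types stay within their group: within-group mass
#'     `dominant_prob` split uniformly over the group (including self),
#'     residual mass uniform over the other groups' types.}
#'   \item{layered / gyrus}{types organised in strata (straight, or folded for
#'     gyrus); returns a spec whose `layout` field drives [layered_labels()].}
#'   \item{time_cold / time_mixed / time_compartmentalized}{tumour
#'     immune-microenvironment presets (two types, tumor and immune). The
#'     numeric matrices are editable package defaults chosen to satisfy the
#'     qualitative structure of each phenotype: cold has few immune cells and
#'     strongly self-adherent tumour; mixed has high cross-type transitions;
#'     compartmentalized has high self-transition for both blocks.}
#' }
#'
#' @param mode pattern mode name.
#' @param K number of cell types (>= 2 for attractive/repulsive).
#' @param groups for `repulsive`: partition of `1:K` into >= 2 non-empty
#'   groups, as a list of integer vectors.
#' @param dominant_prob dominant transition/multinomial parameter, default 0.8.
#' @param proportions optional target proportions (default uniform).
#' @param n_layers number of layers for layered/gyrus (default `K`).
#' @param bounds,axis,wave_amplitude,wave_frequency layout geometry, see
#'   [layer_layout()].
#' @param type_names optional type names.
#' @return a `pattern_spec` (with `$layout` set for layered/gyrus).
#' @examples
#' predefined_pattern("attractive", K = 5)$transition
#' @export
predefined_pattern <- function(mode = c("attractive", "repulsive", "layered",
                                        "gyrus", "time_cold", "time_mixed",
                                        "time_compartmentalized"),
                               K = NULL, groups = NULL, dominant_prob = 0.8,
                               proportions = NULL, n_layers = NULL,
                               bounds = NULL, axis = 2L,
                               wave_amplitude = 0.1, wave_frequency = 2,
                               type_names = NULL) {
  mode <- match.arg(mode)
  dominant_prob <- .check_prob(dominant_prob, "dominant_prob")

  if (startsWith(mode, "time_")) {
    types <- type_names %||% c("tumor", "immune")
    preset <- switch(mode,
      time_cold = list(pi = c(0.9, 0.1),
                       P = rbind(c(0.90, 0.10), c(0.50, 0.50))),
      time_mixed = list(pi = c(0.5, 0.5),
                        P = rbind(c(0.30, 0.70), c(0.70, 0.30))),
      time_compartmentalized = list(pi = c(0.55, 0.45),
                                    P = rbind(c(0.90, 0.10), c(0.10, 0.90))))
    return(pattern_spec(proportions %||% preset$pi, preset$P, mode = mode,
                        types = types))
  }

  K <- .check_count(K, "K")
  proportions <- proportions %||% rep(1 / K, K)

  if (mode == "attractive") {
    if (K < 2L) .stop_invalid("attractive mode needs K >= 2")
    P <- matrix((1 - dominant_prob) / (K - 1), K, K)
    diag(P) <- dominant_prob
    return(pattern_spec(proportions, P, mode = mode, types = type_names))
  }

  if (mode == "repulsive") {
    if (K < 2L) .stop_invalid("repulsive mode needs K >= 2")
    if (is.null(groups) || length(groups) < 2L)
      .stop_invalid("repulsive mode needs a partition of the types into >= 2 groups")
    if (any(lengths(groups) == 0L)) .stop_invalid("empty group in `groups`")
    groups <- lapply(groups, as.integer)
    members <- sort(unlist(groups))
    if (!identical(members, seq_len(K)))
      .stop_invalid("`groups` must partition 1:K")
    P <- matrix(0, K, K)
    for (g in seq_along(groups)) {
      own <- groups[[g]]
      others <- setdiff(seq_len(K), own)
      for (i in own) {
        P[i, own] <- dominant_prob / length(own)
        if (length(others))
          P[i, others] <- (1 - dominant_prob) / length(others)
        else
          P[i, own] <- P[i, own] + (1 - dominant_prob) / length(own)
      }
    }
    return(pattern_spec(proportions, P, mode = mode, types = type_names))
  }

  # layered / gyrus
  n_layers <- if (is.null(n_layers)) K else .check_count(n_layers, "n_layers")
  layout <- layer_layout(n_layers, bounds = bounds, axis = axis,
                         dominant_prob = dominant_prob,
                         wave_amplitude = if (mode == "gyrus") wave_amplitude else 0,
                         wave_frequency = wave_frequency)
  P <- .layered_transition(K, dominant_prob)
  pattern_spec(proportions, P, mode = mode, types = type_names, layout = layout)
}

#' Draw layer-structured cell-type labels
#'
#' Assigns each cell the dominant type of its layer with probability
#' `layout$dominant_prob` and one of the remaining `K - 1` types uniformly
#' otherwise. Layer membership is determined along the layout axis; with
#' `wave_amplitude > 0` the layer boundaries are displaced by a sinusoid of the
#' orthogonal coordinate (the folded "gyrus" geometry).
#'
#' @param plate a `cell_plate`.
#' @param layout a [layer_layout()].
#' @param type_per_layer integer vector mapping each layer to its dominant
#'   type (default layer i -> type i).
#' @param n_types total number of types K (default `max(type_per_layer)`).
#' @param seed optional seed.
#' @return integer label vector of length `n_cells`.
#' @export
layered_labels <- function(plate, layout, type_per_layer = NULL,
                           n_types = NULL, seed = NULL) {
  stopifnot(inherits(plate, "cell_plate"), inherits(layout, "layer_layout"))
  type_per_layer <- type_per_layer %||% seq_len(layout$n_layers)
  if (length(type_per_layer) != layout$n_layers || any(is.na(type_per_layer)))
    .stop_invalid("every layer needs a dominant type (`type_per_layer`)")
  type_per_layer <- as.integer(type_per_layer)
  K <- n_types %||% max(type_per_layer)
  if (any(type_per_layer > K)) .stop_invalid("`type_per_layer` exceeds `n_types`")
  if (!is.null(seed)) set.seed(seed)

  u <- plate$coords[, layout$axis]
  if (layout$wave_amplitude > 0) {
    other <- setdiff(seq_len(ncol(plate$coords)), layout$axis)[1L]
    span <- plate$bounds[other, 2L] - plate$bounds[other, 1L]
    tnorm <- (plate$coords[, other] - plate$bounds[other, 1L]) / span
    u <- u - layout$wave_amplitude *
      sin(2 * pi * layout$wave_frequency * tnorm)
  }
  layer <- findInterval(u, layout$boundaries) + 1L
  layer <- pmin(pmax(layer, 1L), layout$n_layers)
  dominant <- type_per_layer[layer]

  labels <- dominant
  if (K > 1L) {
    flip <- runif(plate$n_cells) >= layout$dominant_prob
    if (any(flip)) {
      alt <- sample.int(K - 1L, sum(flip), replace = TRUE)
      d <- dominant[flip]
      labels[flip] <- ifelse(alt >= d, alt + 1L, alt)
    }
  }
  labels
}

#' Estimate a spatial pattern from labelled data
#'
#' Computes the empirical type proportions and the row-normalised
#' neighbour-type count matrix from a neighbourhood graph and a label vector.
#' Types with no observed neighbour contacts yield an all-zero transition row,
#' which is left as-is and flagged in the `zero_rows` attribute of the
#' transition matrix.
#'
#' @param graph a `neighbor_graph`.
#' @param labels length-N label vector (integer codes, characters, or factor).
#' @return a `pattern_spec` with `mode = "estimated"`.
#' @examples
#' p <- generate_plate(200, seed = 1)
#' g <- build_graph(p, "knn", 4)
#' estimate_pattern(g, sample(1:2, 200, TRUE))
#' @export
estimate_pattern <- function(graph, labels) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (length(labels) != graph$n)
    .stop_invalid("`labels` length does not match the graph size")
  cl <- .coerce_labels(labels)
  X <- onehot_matrix(cl$codes, cl$K)
  TT <- as.matrix(Matrix::crossprod(X, graph$adjacency %*% X))
  rs <- rowSums(TT)
  P <- TT / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 0
  pihat <- tabulate(cl$codes, cl$K) / length(cl$codes)
  spec <- pattern_spec(pihat, P, mode = "estimated", types = cl$types,
                       allow_zero_rows = TRUE)
  if (any(rs == 0))
    attr(spec$transition, "zero_rows") <- unname(which(rs == 0))
  spec
}

# ---- pattern config serialization ------------------------------------------

#' Write / read a pattern specification as a flat config file
#'
#' The canonical on-disk dialect is YAML; `read_pattern_config()` also accepts
#' JSON and a flat TOML subset (key = value with scalar and array values).
#'
#' @param spec a `pattern_spec`.
#' @param path file path; the extension selects the dialect on read.
#' @return `write_pattern_config()` returns `path` invisibly;
#'   `read_pattern_config()` returns a `pattern_spec`.
#' @export
write_pattern_config <- function(spec, path) {
  stopifnot(inherits(spec, "pattern_spec"))
  obj <- list(mode = spec$mode, n_types = spec$n_types,
              types = as.list(spec$types),
              proportions = as.list(unname(spec$proportions)),
              transition = lapply(seq_len(spec$n_types),
                                  function(i) as.list(unname(spec$transition[i, ]))))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_pattern_config
#' @export
read_pattern_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    toml = .read_flat_toml(path),
    .stop_invalid("unsupported config dialect: .", ext))
  P <- if (is.matrix(obj$transition)) obj$transition
       else do.call(rbind, lapply(obj$transition,
                                  function(r) as.numeric(unlist(r))))
  pattern_spec(as.numeric(unlist(obj$proportions)), P,
               mode = obj$mode %||% "custom",
               types = if (!is.null(obj$types)) as.character(unlist(obj$types)))
}

# minimal flat TOML reader: `key = value` lines with scalars and
# (possibly nested) arrays; enough for the configs this package writes
.read_flat_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) .stop_invalid("malformed TOML line: ", ln)
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    out[[key]] <- .parse_toml_value(val)
  }
  out
}

.parse_toml_value <- function(s) {
  s <- trimws(s)
  if (startsWith(s, "[")) {
    inner <- substr(s, 2L, nchar(s) - 1L)
    parts <- character(0)
    depth <- 0L; start <- 1L
    chars <- strsplit(inner, "")[[1]]
    for (p in seq_along(chars)) {
      ch <- chars[p]
      if (ch == "[") depth <- depth + 1L
      if (ch == "]") depth <- depth - 1L
      if (ch == "," && depth == 0L) {
        parts <- c(parts, substr(inner, start, p - 1L))
        start <- p + 1L
      }
    }
    if (start <= nchar(inner)) parts <- c(parts, substr(inner, start, nchar(inner)))
    vals <- lapply(trimws(parts), .parse_toml_value)
    if (all(vapply(vals, is.numeric, logical(1)) & lengths(vals) == 1L))
      return(unlist(vals))
    return(vals)
  }
  if (startsWith(s, "\"")) return(gsub("^\"|\"$", "", s))
  if (s %in% c("true", "false")) return(s == "true")
  as.numeric(s)
}
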