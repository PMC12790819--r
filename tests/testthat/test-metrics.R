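test_that("ARI matches the hand-evaluated worked example and is invariant", {
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 2, 2)
  expect_equal(ari(a, a), 1)
  expect_equal(ari(a, b), (4 - 2.8) / (6.5 - 2.8), tolerance = 1e-12)
  # relabelling either partition changes nothing
  expect_equal(ari(a, b), ari(3 - a, b))
  expect_equal(ari(a, b), ari(b, a))
  expect_error(ari(a, b[-1]), "length")
})

test_that("ARI and NMI agree with independent reference implementations", {
  skip_if_not_installed("mclust")
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(20:200, 1)
    a <- sample.int(sample(2:6, 1), n, replace = TRUE)
    b <- sample.int(sample(2:6, 1), n, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-9)
    expect_equal(nmi(a, b), igraph::compare(a, b, method = "nmi"),
                 tolerance = 1e-9)
  }
})

test_that("NMI matches its printed-formula evaluation and handles degeneracy", {
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 2, 2)
  # independent evaluation of the formula from the contingency table
  # n_ij = [[2,1],[0,3]], n = 6
  pij <- c(2, 1, 3) / 6
  ppr <- c(0.5 * (1 / 3), 0.5 * (2 / 3), 0.5 * (2 / 3))
  mi <- sum(pij * log(pij / ppr))
  hx <- log(2)
  hy <- -(1 / 3) * log(1 / 3) - (2 / 3) * log(2 / 3)
  expect_equal(nmi(a, b), mi / ((hx + hy) / 2), tolerance = 1e-12)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(rep(1, 5), rep(2, 5)), 1)  # two trivial partitions

  set.seed(12)
  big_a <- sample.int(4, 10000, replace = TRUE)
  big_b <- sample.int(4, 10000, replace = TRUE)
  expect_lte(nmi(big_a, big_b), 0.01)         # independence
})

test_that("transition discrepancy is a symmetric pseudometric on patterns", {
  g <- path_graph(4)
  lab <- c(1, 1, 2, 2)
  expect_equal(transition_discrepancy(list(g, lab), list(g, lab)), 0)
  est <- estimate_pattern(g, lab)
  expect_equal(transition_discrepancy(est, diag(2)), 2 / 3)
  expect_equal(transition_discrepancy(est, diag(2)),
               transition_discrepancy(diag(2), est$transition))
  other <- pattern_spec(c(0.5, 0.5), rbind(c(0.5, 0.5), c(0.5, 0.5)),
                        types = c("X", "Y"))
  expect_error(transition_discrepancy(est, other), "type sets")
})

test_that("centrality scores match hand enumeration on the bridged triangles", {
  g <- bridged_triangles()
  lab <- rep(1:2, each = 3)
  out <- csm(g, lab)
  # G1: one of three non-members touches each triangle
  expect_equal(unname(out[, "G1"]), c(1 / 3, 1 / 3))
  # G2: clustering 1, 1, 1/3 within each triangle
  expect_equal(unname(out[, "G2"]), rep((1 + 1 + 1 / 3) / 3, 2))
  # G3: distances from {4,5,6} to triangle 1 are 1,2,2
  expect_equal(unname(out[, "G3"]), rep(3 / 5, 2))

  # complete graph: every non-member touches the group
  k6 <- clique_graph(6)
  expect_equal(unname(csm(k6, rep(1:3, 2))[, "G1"]), rep(1, 3))
  # triangle-free graph has zero clustering
  expect_equal(unname(csm(path_graph(5), c(1, 2, 1, 2, 1))[, "G2"]), c(0, 0))
  # a type covering the whole graph has G1/G3 undefined
  full <- csm(k6, rep(1, 6))
  expect_true(is.na(full[1, "G1"]) && is.na(full[1, "G3"]))
})

test_that("neighbourhood enrichment matches the exhaustive permutation null", {
  g <- two_cliques(3, 3)
  lab <- rep(1:2, each = 3)

  # independent brute force over all C(6,3) = 20 balanced labelings
  combos <- combn(6, 3, simplify = FALSE)
  A <- as.matrix(g$adjacency)
  count2 <- function(l) {
    x <- matrix(0, 2, 2)
    for (i in 1:6) for (j in 1:6) if (A[i, j] == 1)
      x[l[i], l[j]] <- x[l[i], l[j]] + 1
    x
  }
  stats <- vapply(combos, function(s) {
    l <- rep(2L, 6); l[s] <- 1L
    count2(l)
  }, matrix(0, 2, 2))
  mu <- apply(stats, c(1, 2), mean)
  sg <- sqrt(apply(stats, c(1, 2), function(v) mean((v - mean(v))^2)))
  z_expected <- (count2(lab) - mu) / sg

  z <- nem(g, lab, exhaustive = TRUE)
  expect_equal(unname(z), z_expected, tolerance = 1e-9)
  expect_equal(z, t(z))  # symmetric adjacency gives a symmetric z-matrix

  # Monte-Carlo agrees with the exhaustive null within 3 SE
  zmc <- nem(g, lab, n_perms = 4000, seed = 1)
  expect_true(all(abs(zmc - z) < 0.2))
})

test_that("permutation-invariant configurations give zero enrichment", {
  k6 <- clique_graph(6)
  z <- nem(k6, rep(1:2, each = 3), n_perms = 50, seed = 2)
  expect_equal(unname(z), matrix(0, 2, 2))
})

test_that("Ripley's L matches its definition and an independent estimator", {
  # two points: no pairs below their separation
  two <- rbind(c(0.2, 0.5), c(0.8, 0.5))
  rl <- ripley_l(two, t_grid = c(0.1, 0.3, 0.7))
  expect_equal(rl$L[1:2], c(0, 0))
  expect_gt(rl$L[3], 0)
  expect_equal(rl$csr, c(0.1, 0.3, 0.7))

  skip_if_not_installed("spatstat.explore")
  set.seed(21)
  pts <- cbind(runif(120), runif(120))
  tg <- seq(0.02, 0.2, by = 0.02)
  mine <- ripley_l(pts, t_grid = tg)
  pp <- spatstat.geom::ppp(pts[, 1], pts[, 2], window = spatstat.geom::owin())
  ks <- spatstat.explore::Kest(pp, r = c(0, tg), correction = "none")
  expect_equal(mine$L, sqrt(ks$un[-1] / pi), tolerance = 1e-9)
})

test_that("clustered points inflate L above the CSR baseline", {
  set.seed(22)
  cl <- rbind(cbind(rnorm(100, 0.3, 0.01), rnorm(100, 0.3, 0.01)),
              cbind(rnorm(100, 0.7, 0.01), rnorm(100, 0.7, 0.01)))
  rl <- ripley_l(cl, t_grid = c(0.05, 0.1))
  expect_true(all(rl$L > rl$csr))
  expect_error(ripley_l(cl[1, , drop = FALSE]), "2 points")
})

test_that("per-type curves and cosine similarity behave as documented", {
  fx <- starmap_like_fixture(seed = 5)
  cs <- ripley_curves(fx$plate$coords, fx$labels, fx$plate$bounds,
                      t_grid = seq(0.02, 0.1, by = 0.02))
  expect_setequal(unique(cs$type), levels(fx$labels))
  expect_equal(nrow(cs), 6 * 5)

  expect_equal(curve_cosine(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(curve_cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(curve_cosine(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_warning(out <- curve_cosine(c(0, 0), c(1, 1)), "zero")
  expect_true(is.na(out))
})

test_that("SI and RSI follow their set formulas", {
  expect_equal(si(letters[1:4], letters[1:4]), 1)
  expect_equal(si(letters[1:3], letters[10:12]), 0)
  expect_equal(si(letters[1:4], c(letters[3:4], letters[10:13])), 0.5)
  expect_error(si(character(0), "a"), "empty")

  a <- ranked_lr_set(c("p1", "p2"), c(10, 5))
  b <- ranked_lr_set(c("p1", "p2", "p3", "p4"), c(9, 8, 2, 1))
  expect_equal(rsi(a, b), 1 - 0.5 * (abs(1 / 2 - 1 / 4) + abs(2 / 2 - 2 / 4)))
  expect_equal(rsi(a, b), rsi(b, a))
  same <- ranked_lr_set(c("x", "y", "z"), c(3, 2, 1))
  expect_equal(rsi(same, same), 1)
  other <- ranked_lr_set("q", 1)
  expect_warning(out <- rsi(same, other), "overlap")
  expect_true(is.na(out))
})

test_that("metric reports collect into the tidy layout", {
  rep_df <- metric_report(ari = 0.5, nem = matrix(1:4, 2))
  expect_named(rep_df, c("metric", "type_or_pair", "value"))
  expect_equal(nrow(rep_df), 5)
})
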