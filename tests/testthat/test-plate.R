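test_that("grid mode places cells on the most-square lattice, truncated row-major", {
  p <- generate_plate(4, "grid")
  expect_equal(p$n_cells, 4)
  got <- p$coords[order(p$coords[, 2], p$coords[, 1]), ]
  expect_equal(unname(got),
               rbind(c(0.25, 0.25), c(0.75, 0.25), c(0.25, 0.75), c(0.75, 0.75)))

  # non-square counts still return exactly n, all inside bounds
  p7 <- generate_plate(7, "grid")
  expect_equal(nrow(p7$coords), 7)
  expect_true(all(p7$coords >= 0 & p7$coords <= 1))
})

test_that("random plates are seed-reproducible and contained in bounds", {
  p1 <- generate_plate(1000, "random", seed = 7)
  p2 <- generate_plate(1000, "random", seed = 7)
  expect_identical(p1$coords, p2$coords)
  expect_true(all(p1$coords >= 0 & p1$coords <= 1))

  b <- rbind(c(-2, 2), c(10, 20), c(0, 5))
  p3 <- generate_plate(500, "random", bounds = b, dim = 3, seed = 1)
  expect_equal(ncol(p3$coords), 3)
  for (a in 1:3)
    expect_true(all(p3$coords[, a] >= b[a, 1] & p3$coords[, a] <= b[a, 2]))
})

test_that("invalid plate arguments are rejected", {
  expect_error(generate_plate(0), "integer")
  expect_error(generate_plate(10, bounds = rbind(c(0, 0), c(0, 1))), "degenerate")
  expect_error(generate_plate(10, dim = 4), "2 or 3")
})

test_that("knn graph matches hand enumeration on collinear points", {
  p <- make_plate(cbind(c(0, 1, 3), 0), bounds = rbind(c(0, 3), c(-1, 1)))
  g <- build_graph(p, "knn", 1)
  expect_equal(edge_list(g), rbind(c(1, 2), c(2, 3)))
})

test_that("adjacency is symmetric, binary, and hollow for every method", {
  p <- generate_plate(120, seed = 3)
  graphs <- list(build_graph(p, "knn", 5),
                 build_graph(p, "radius", 0.15),
                 build_graph(p, "delaunay"),
                 build_graph(p, "snn", 5))
  for (g in graphs) {
    A <- as.matrix(g$adjacency)
    expect_identical(A, t(A))
    expect_true(all(diag(A) == 0))
    expect_true(all(A %in% c(0, 1)))
  }
})

test_that("knn degrees are bounded below by k with mean at most 2k", {
  # union symmetrisation guarantees degree >= k everywhere; the edge total is
  # at most N*k undirected edges, so the mean degree cannot exceed 2k (an
  # individual node may exceed 2k when it is nominated by many neighbours)
  p <- generate_plate(200, seed = 9)
  for (k in c(1, 4, 8)) {
    deg <- graph_degrees(build_graph(p, "knn", k))
    expect_true(all(deg >= k))
    expect_lte(mean(deg), 2 * k)
  }
})

test_that("radius graphs are strict and monotone in r", {
  p <- generate_plate(80, seed = 2)
  g1 <- build_graph(p, "radius", 0.1)
  g2 <- build_graph(p, "radius", 0.25)
  d <- g2$adjacency - g1$adjacency
  expect_true(all(d >= 0))   # edge set grows with r

  # radius above the diameter gives the complete graph minus the diagonal
  gall <- build_graph(p, "radius", 10)
  expect_equal(Matrix::nnzero(gall$adjacency), 80 * 79)
})

test_that("delaunay on a square yields 5 or 6 edges depending on the tie-break", {
  p <- make_plate(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  g <- build_graph(p, "delaunay")
  ne <- Matrix::nnzero(g$adjacency) / 2
  expect_true(ne %in% c(5, 6))
  expect_true(Matrix::isSymmetric(g$adjacency))
  p3 <- generate_plate(20, dim = 3, seed = 1)
  expect_error(build_graph(p3, "delaunay"), "2-D")
})

test_that("snn edges are knn candidates sharing a neighbour", {
  p <- generate_plate(100, seed = 5)
  gs <- build_graph(p, "snn", 4)
  gk <- build_graph(p, "knn", 4)
  expect_true(all((gs$adjacency - gk$adjacency) <= 0))  # snn subset of knn union
  # raising the shared-neighbour threshold can only remove edges
  gs3 <- build_graph(p, "snn", 4, snn_shared = 3)
  expect_true(all((gs3$adjacency - gs$adjacency) <= 0))
})

test_that("alternative metrics change the graph and degenerate cosine errors", {
  # anisotropic cloud: manhattan and euclidean nearest neighbours differ
  set.seed(4)
  coords <- cbind(runif(150), runif(150) * 20)
  p <- make_plate(coords)
  ge <- build_graph(p, "knn", 3, metric = "euclidean")
  gm <- build_graph(p, "knn", 3, metric = "manhattan")
  expect_gt(sum(abs(ge$adjacency - gm$adjacency)), 0)

  pd <- make_plate(matrix(1, 5, 2))
  expect_error(build_graph(pd, "knn", 2, metric = "cosine"), "degenerate")
  expect_error(build_graph(p, "knn", 200), "k <")
})

test_that("coordinates and adjacency round-trip through TSV / Matrix Market", {
  p <- generate_plate(40, seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_coords(p, f)
  p2 <- read_coords(f)
  expect_equal(unname(p2$coords), unname(p$coords), tolerance = 1e-12)

  g <- build_graph(p, "knn", 3)
  mm <- tempfile(fileext = ".mtx")
  write_graph_mm(g, mm)
  A2 <- as.matrix(Matrix::readMM(mm)) * 1
  expect_equal(unname(A2), unname(as.matrix(g$adjacency)))
})
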