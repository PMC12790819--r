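test_that("attractive pattern has dominant diagonal and uniform off-diagonal", {
  sp <- predefined_pattern("attractive", K = 5)
  expect_equal(unname(diag(sp$transition)), rep(0.8, 5))
  off <- sp$transition[row(sp$transition) != col(sp$transition)]
  expect_equal(unname(off), rep(0.05, 20))
  expect_equal(unname(rowSums(sp$transition)), rep(1, 5))

  sp2 <- predefined_pattern("attractive", K = 2, dominant_prob = 1.0)
  expect_equal(unname(sp2$transition), diag(2))
  expect_error(predefined_pattern("attractive", K = 1), "K >= 2")
})

test_that("repulsive pattern splits mass within and across groups", {
  sp <- predefined_pattern("repulsive", K = 4, groups = list(1:2, 3:4))
  # within-group (incl. self): 0.8 / 2; cross-group: 0.2 / 2
  expect_equal(unname(sp$transition[1, ]), c(0.4, 0.4, 0.1, 0.1))
  expect_equal(unname(sp$transition[3, ]), c(0.1, 0.1, 0.4, 0.4))
  expect_equal(unname(rowSums(sp$transition)), rep(1, 4))
  expect_error(predefined_pattern("repulsive", K = 4,
                                  groups = list(1:4, integer(0))), "empty")
  expect_error(predefined_pattern("repulsive", K = 4), "groups")
})

test_that("pattern_spec validates proportions and row-stochasticity", {
  expect_error(pattern_spec(c(0.5, 0.6), diag(2)), "sum to 1")
  expect_error(pattern_spec(c(0.5, 0.5), rbind(c(0.9, 0.2), c(0, 1))), "row")
  expect_error(pattern_spec(c(0.5, 0.5), rbind(c(1.2, -0.2), c(0, 1))),
               "\\[0, 1\\]")
})

test_that("layered labels are degenerate at dominant_prob = 1", {
  p <- generate_plate(300, seed = 2)
  lay <- layer_layout(3, dominant_prob = 1)
  lab <- layered_labels(p, lay, seed = 1)
  layer <- findInterval(p$coords[, 2], lay$boundaries) + 1
  expect_equal(lab, layer)
})

test_that("layered dominant fraction matches the multinomial parameter", {
  p <- generate_plate(10000, seed = 3)
  lay <- layer_layout(2, dominant_prob = 0.8)
  lab <- layered_labels(p, lay, seed = 4)
  layer <- findInterval(p$coords[, 2], lay$boundaries) + 1
  for (l in 1:2) {
    frac <- mean(lab[layer == l] == l)
    expect_lt(abs(frac - 0.8), 0.02)  # 3 SE at n ~ 5000
  }
  expect_identical(lab, layered_labels(p, lay, seed = 4))
})

test_that("gyrus folding makes layer membership depend on the cross axis", {
  p <- generate_plate(2000, seed = 5)
  straight <- layer_layout(2, dominant_prob = 1)
  folded <- layer_layout(2, dominant_prob = 1, wave_amplitude = 0.2,
                         wave_frequency = 2)
  ls <- layered_labels(p, straight)
  lf <- layered_labels(p, folded)
  expect_gt(sum(ls != lf), 0)
  # cells relabelled by the fold sit near the straight boundary
  moved <- ls != lf
  expect_lt(max(abs(p$coords[moved, 2] - 0.5)), 0.2 + 1e-9)
})

test_that("estimate_pattern reproduces hand-counted transition frequencies", {
  g <- path_graph(4)
  est <- estimate_pattern(g, c(1, 1, 2, 2))
  expect_equal(unname(est$transition),
               rbind(c(2 / 3, 1 / 3), c(1 / 3, 2 / 3)))
  expect_equal(unname(est$proportions), c(0.5, 0.5))

  single <- estimate_pattern(g, rep(1, 4))
  expect_equal(unname(single$transition), matrix(1, 1, 1))
  expect_equal(unname(single$proportions), 1)
  expect_error(estimate_pattern(g, c(1, 2)), "length")
})

test_that("estimated transition error shrinks with sample size", {
  # i.i.d. labels: the true neighbour-type profile is the proportion vector
  pi0 <- c(0.5, 0.3, 0.2)
  target <- rbind(pi0, pi0, pi0)
  err <- vapply(c(500, 2000, 8000), function(n) {
    p <- generate_plate(n, seed = n)
    g <- build_graph(p, "knn", 6)
    set.seed(n + 1)
    lab <- sample.int(3, n, replace = TRUE, prob = pi0)
    max(abs(estimate_pattern(g, lab)$transition - target))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.03)
})

test_that("TIME presets satisfy their structural inequalities", {
  cold <- predefined_pattern("time_cold")
  expect_gte(cold$proportions[["tumor"]], cold$proportions[["immune"]])
  expect_gte(cold$transition["tumor", "tumor"], 0.8)

  mixed <- predefined_pattern("time_mixed")
  expect_gt(mixed$transition["tumor", "immune"], mixed$transition["tumor", "tumor"])
  expect_gt(mixed$transition["immune", "tumor"], mixed$transition["immune", "immune"])

  comp <- predefined_pattern("time_compartmentalized")
  expect_gte(comp$transition["tumor", "tumor"], 0.8)
  expect_gte(comp$transition["immune", "immune"], 0.8)
})

test_that("pattern configs round-trip through YAML, JSON, and flat TOML", {
  sp <- predefined_pattern("repulsive", K = 3, groups = list(1:2, 3),
                           proportions = c(0.2, 0.3, 0.5))
  fy <- tempfile(fileext = ".yaml")
  write_pattern_config(sp, fy)
  spy <- read_pattern_config(fy)
  expect_equal(spy$transition, sp$transition)
  expect_equal(spy$proportions, sp$proportions)

  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(mode = sp$mode, n_types = 3,
                            types = sp$types,
                            proportions = unname(sp$proportions),
                            transition = lapply(1:3, function(i)
                              unname(sp$transition[i, ]))),
                       fj, auto_unbox = TRUE, digits = NA)
  spj <- read_pattern_config(fj)
  expect_equal(unname(spj$transition), unname(sp$transition))

  ft <- tempfile(fileext = ".toml")
  writeLines(c('mode = "custom"',
               "proportions = [0.2, 0.3, 0.5]",
               "transition = [[0.4, 0.4, 0.2], [0.4, 0.4, 0.2], [0.1, 0.1, 0.8]]"),
             ft)
  spt <- read_pattern_config(ft)
  expect_equal(unname(spt$proportions), c(0.2, 0.3, 0.5))
  expect_equal(unname(spt$transition[3, ]), c(0.1, 0.1, 0.8))
})
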