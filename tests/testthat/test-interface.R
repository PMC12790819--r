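test_that("run configs fill defaults and reject unknown keys", {
  cfg <- run_config(list(n_cells = 100))
  expect_equal(cfg$n_cells, 100)
  expect_equal(cfg$graph_method, "knn")
  expect_error(run_config(list(n_cels = 100)), "unknown config key")

  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_cells = 50, n_types = 2, seed = 3), f)
  expect_equal(run_config(f)$seed, 3)
})

test_that("the pipeline is deterministic end-to-end (byte-identical files)", {
  cfg <- list(n_cells = 200, n_types = 2, n_genes = 30, seed = 11)
  d1 <- tempfile(); d2 <- tempfile()
  run_simulate(c(cfg, list(outdir = d1)))
  run_simulate(c(cfg, list(outdir = d2)))
  for (f in c("cells.tsv", "labels.tsv", "matrix.mtx")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("pipeline outputs are re-readable and logged", {
  dir <- tempfile()
  res <- run_simulate(list(n_cells = 150, n_types = 3, n_genes = 25, seed = 2,
                           aggregate = TRUE, spot_size = 0.15,
                           spot_shape = "rectangle", outdir = dir))
  d <- read_dataset(dir)
  expect_identical(unname(d$counts), unname(res$sc$counts))
  expect_equal(unname(d$plate$coords), unname(res$sc$plate$coords),
               tolerance = 1e-12)
  expect_identical(as.character(unname(read_labels(file.path(dir, "labels.tsv")))),
                   as.character(res$sc$labels))

  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_true(all(c("composition", "trace", "config", "log") %in% names(manifest)))
  log <- readLines(file.path(dir, "log.txt"))
  expect_true(any(grepl("seed: 2", log)))
  expect_true(any(grepl("schedule: M=", log)))
  expect_true(any(grepl("final objective", log)))
  # resolved config echo reloads to the same resolved values
  cfg2 <- run_config(file.path(dir, "config.yaml"))
  expect_equal(cfg2$n_cells, 150)
  expect_equal(cfg2$spot_shape, "rectangle")
})

test_that("a single-type run completes with an all-zero trace", {
  res <- run_simulate(list(n_cells = 60, n_types = 1, n_genes = 10, seed = 1,
                           pattern_mode = "custom",
                           proportions = 1, transition = matrix(1, 1, 1)))
  expect_equal(res$assignment$objective_value, 0)
  expect_true(all(res$assignment$trace$objective == 0))
})

test_that("stage errors carry the stage name", {
  expect_error(run_simulate(list(n_cells = 100, pattern_mode = "custom")),
               "stage 'pattern'")
  expect_error(run_simulate(list(n_cells = 100, graph_method = "radius")),
               "stage 'graph'")
})

test_that("labelled references load from Matrix Market and dense tables", {
  ref <- simulate_reference(K = 2, n_genes = 12, n_cells_per_type = 5, seed = 3)
  dir <- tempfile(); dir.create(dir)
  # write genes x cells mtx + companions
  Matrix::writeMM(Matrix::Matrix(t(ref$counts), sparse = TRUE),
                  file.path(dir, "m.mtx"))
  writeLines(ref$gene_ids, file.path(dir, "genes.tsv"))
  write_labels(ref$cell_labels, file.path(dir, "labels.tsv"),
               cell_ids = ref$cell_ids)
  back <- read_labeled_reference(file.path(dir, "m.mtx"),
                                 file.path(dir, "labels.tsv"),
                                 file.path(dir, "genes.tsv"),
                                 orientation = "genes_by_cells")
  expect_equal(unname(back$counts), unname(ref$counts))
  expect_equal(back$cell_labels, ref$cell_labels)

  # dense CSV in both orientations resolves to the same reference
  f1 <- file.path(dir, "cbg.csv")
  write.csv(ref$counts, f1)
  f2 <- file.path(dir, "gbc.csv")
  write.csv(t(ref$counts), f2)
  r1 <- read_labeled_reference(f1, file.path(dir, "labels.tsv"))
  r2 <- read_labeled_reference(f2, file.path(dir, "labels.tsv"),
                               orientation = "genes_by_cells")
  expect_equal(unname(r1$counts), unname(r2$counts))

  # schema violations name the offending file
  bad <- file.path(dir, "bad_labels.tsv")
  write_labels(ref$cell_labels[1:3], bad)
  expect_error(read_labeled_reference(f1, bad), "bad_labels")
})

test_that("the fixture round-trips through a dataset directory", {
  fx <- starmap_like_fixture(seed = 1)
  dir <- tempfile()
  write_dataset(fx, dir)
  back <- read_dataset(dir)
  expect_identical(unname(back$counts), unname(fx$counts))
  expect_equal(unname(back$plate$coords), unname(fx$plate$coords),
               tolerance = 1e-12)
  expect_identical(unname(as.character(back$labels)),
                   as.character(fx$labels))
})

test_that("the command-line front end simulates from a config file", {
  skip_if_not_installed("optparse")
  script <- system.file("cli", "stplate.R", package = "stplate")
  expect_true(nzchar(script))
  cfgf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_cells = 80, n_types = 2, n_genes = 10), cfgf)
  out <- tempfile()
  res <- suppressWarnings(system2("Rscript", c(script, "simulate", "-c", cfgf,
                                               "--seed", "4", "--out", out),
                                  stdout = TRUE, stderr = TRUE,
                                  env = paste0("R_LIBS=",
                                               paste(.libPaths(), collapse = ":"))))
  expect_equal(attr(res, "status") %||% 0L, 0L)
  expect_true(file.exists(file.path(out, "cells.tsv")))

  bad <- suppressWarnings(system2("Rscript", c(script, "simulate", "-c",
                                               "/nonexistent.yaml"),
                                  stdout = TRUE, stderr = TRUE,
                                  env = paste0("R_LIBS=",
                                               paste(.libPaths(), collapse = ":"))))
  expect_false((attr(bad, "status") %||% 0L) == 0L)
})
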