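test_that("generation is bit-identical under a fixed seed", {
  p <- tissue_params(shape = c(24, 96, 96), n_cells = 8, seed = 3)
  b1 <- generate_tissue(p)
  b2 <- generate_tissue(p)
  expect_identical(b1$channels$junctions$data, b2$channels$junctions$data)
  expect_identical(b1$channels$rna1$data, b2$channels$rna1$data)
  expect_identical(b1$truth$spots$rna1$coords, b2$truth$spots$rna1$coords)
  expect_identical(b1$truth$cells$cell_z, b2$truth$cells$cell_z)
})

test_that("the flat limit has constant cell Z matched by the projection", {
  b <- get_bundle("flat")
  expect_equal(length(unique(round(b$truth$cells$cell_z, 6))), 1)
  # on the clean render the argmax is exact everywhere on the tube
  clean <- volume_image(b$truth$clean_junctions, b$params$spacing, "j")
  zr0 <- project_apical(clean, method = "max")
  tube <- apply(b$truth$clean_junctions, c(2, 3), max) > 60
  expect_true(all(zr0$zmap[tube] == b$truth$zstar[tube]))
  # under acquisition noise the agreement stays essentially exact
  zr <- project_apical(b$channels$junctions, "local_peak", smooth_sigma = 1)
  expect_gte(mean(zr$zmap[tube] == b$truth$zstar[tube]), 0.995)
})

test_that("rendered and truth spot counts are conserved by construction", {
  b <- get_bundle("default")
  expect_equal(length(b$truth$spots$rna1), sum(b$truth$counts[, 1]))
  percell <- table(factor(b$truth$spots$rna1$cell, levels = 1:b$params$n_cells))
  expect_equal(as.integer(percell), as.integer(b$truth$counts[, 1]))
})

test_that("on flat tissue every truth spot projects into its own cell", {
  b <- get_bundle("flat")
  ss <- b$truth$spots$rna1
  lab <- b$truth$cells$labels2d
  hit <- lab[cbind(round(ss$coords[, 2]) + 1, round(ss$coords[, 3]) + 1)]
  expect_true(all(hit == ss$cell))
})

test_that("per-cell counts are bimodal: otsu on counts recovers the classes", {
  b <- get_bundle("default")
  counts <- as.numeric(b$truth$counts[, 1])
  thr <- otsu_threshold(counts)
  pred <- ifelse(counts > thr, "high", "low")
  expect_gte(mean(pred == unname(b$truth$classes)), 0.95)
})

test_that("scoring truth against itself is perfect; empty predictions recall 0", {
  b <- get_bundle("small")
  sc <- score_cells(b$truth$cells, b$truth$cells)
  expect_equal(sc$mean_jaccard, 1)
  sn <- score_nuclei(b$truth$nuclei, b$truth$nuclei)
  expect_equal(sn$precision, 1)
  expect_equal(sn$recall, 1)
  ssc <- score_spots(b$truth$spots$rna1, b$truth$spots$rna1)
  expect_equal(ssc$f1, 1)

  none <- spot_set(matrix(numeric(0), 0, 3), "rna1")
  expect_equal(score_spots(none, b$truth$spots$rna1)$recall, 0)
})

test_that("a shuffled assignment scores near chance level", {
  b <- get_bundle("default")
  truth <- b$truth$spots$rna1
  set.seed(31)
  shuffled <- truth
  shuffled$cell <- sample(truth$cell)
  match <- score_spots(truth, truth)$match
  acc <- score_assignment(epiquant:::new_assignment(shuffled, "shuffled"),
                          truth, match)
  # chance is ~sum(p_c^2) for cell proportions p_c; binomial slack
  p <- as.numeric(table(truth$cell)) / length(truth)
  chance <- sum(p^2)
  expect_lt(abs(acc - chance), 4 * sqrt(chance / length(truth)))
})

test_that("a bundle writes its channels, truth and parameters to disk", {
  b <- get_bundle("small")
  d <- tempfile("bundle")
  write_bundle(b, d)
  expect_true(file.exists(file.path(d, "stack.tif")))
  expect_true(file.exists(file.path(d, "truth", "cells.tif")))
  expect_true(file.exists(file.path(d, "truth", "spots_rna1.csv")))
  pl <- yaml::read_yaml(file.path(d, "params.yaml"))
  expect_equal(pl$n_cells, 8)
  tr <- read_apical_map(file.path(d, "truth", "cells.tif"),
                        file.path(d, "truth", "cells_z.csv"),
                        b$params$spacing, b$params$shape[1])
  expect_equal(tr$labels2d, b$truth$cells$labels2d)
})
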