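square_map <- function() {
  lab <- matrix(0L, 20, 20)
  lab[5:14, 5:14] <- 1L       # 10x10 square
  grid <- voxel_grid(c(12, 20, 20), c(1, 0.2, 0.2))
  apical_cell_map(lab, c("1" = 2), grid)
}

test_that("cytoplasmic prisms average constant images exactly", {
  cells <- square_map()
  v <- volume_image(array(7, cells$grid$shape), cells$grid$spacing, "ihc")
  for (depth in c(0.5, 3, 50)) {
    m <- measure_cytoplasmic_intensity(v, cells, depth)
    expect_equal(m$mean, 7)
  }
  # depth below one Z step: a single plane, sum = plane pixels under the mask
  plane <- array(0, cells$grid$shape)
  plane[3, , ] <- matrix(runif(400), 20, 20)   # z = 2 (0-based)
  vi <- volume_image(plane, cells$grid$spacing, "x")
  m1 <- measure_cytoplasmic_intensity(vi, cells, depth = 0.5)
  expect_equal(m1$sum, sum(plane[3, , ][cells$labels2d == 1]))
  expect_equal(m1$n_voxels, 100L)
})

test_that("nuclear intensities are plain per-label means and sums", {
  g <- voxel_grid(c(6, 10, 10), c(1, 0.5, 0.5))
  lab <- array(0L, g$shape)
  lab[2, 3, 1:10] <- 4L                 # 10 voxels
  nuc <- nuclei_labels(lab, g)
  v <- volume_image(array(3, g$shape), g$spacing, "s")
  m <- measure_nuclear_intensity(v, nuc)
  expect_equal(m$sum, 30)
  expect_equal(m$mean, 3)
  cst <- measure_nuclear_intensity(volume_image(array(5, g$shape), g$spacing, "c"), nuc)
  expect_equal(cst$mean, 5)
})

test_that("simulated reporter levels are recovered within 10 percent", {
  b <- get_bundle("flat")
  cy <- measure_cytoplasmic_intensity(b$channels$ihc1, b$truth$cells, depth = 5)
  lev <- ifelse(b$truth$classes == "high", 80, 15) + b$params$background
  expect_true(all(abs(cy$mean - lev) / lev < 0.1))
  # two clearly separated modes
  expect_gt(min(cy$mean[b$truth$classes == "high"]),
            2 * max(cy$mean[b$truth$classes == "low"]))
})

test_that("morphometrics match closed forms on a digital square", {
  m <- morphometrics(square_map())
  expect_equal(m$area_um2, 4)                       # 100 px * 0.04
  expect_equal(m$perimeter_um, 8)                   # 40 steps * 0.2
  expect_equal(m$circularity, 4 * pi * 100 / 40^2, tolerance = 1e-9)
  expect_equal(m$centroid_z_um, 2)                  # cell_z * dz
})

test_that("interior Voronoi cells have about six neighbors", {
  b <- get_bundle("default")
  m <- morphometrics(b$truth$cells)
  lab <- b$truth$cells$labels2d
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  interior <- !(m$cell %in% border)
  expect_gt(sum(interior), 10)
  expect_gte(mean(m$n_neighbors[interior]), 5.5)
  expect_lte(mean(m$n_neighbors[interior]), 6.5)
})

test_that("classification pre-fill thresholds as documented", {
  v <- stats::setNames(c(1, 1, 1, 9, 9), 1:5)
  cl <- prefill_classification(v, method = "threshold", threshold = 5)
  expect_equal(as.character(cl), c("negative", "negative", "negative",
                                   "positive", "positive"))
  all_neg <- prefill_classification(v, "threshold", threshold = 50)
  expect_true(all(all_neg == "negative"))
  expect_error(prefill_classification(stats::setNames(rep(3, 5), 1:5), "otsu"),
               "manual threshold")
})

test_that("otsu pre-fill matches the generated classes on the simulator", {
  b <- get_bundle("flat")
  cy <- measure_cytoplasmic_intensity(b$channels$ihc1, b$truth$cells, depth = 5)
  cl <- prefill_classification(stats::setNames(cy$mean, cy$cell), "otsu")
  expect_gte(score_classes(cl, b$truth$classes), 0.95)
})

test_that("the cell table joins blocks, conserves counts, keeps empty fields", {
  f <- spot_set(rbind(c(2, 6, 6), c(2, 6, 7), c(2, 7, 6), c(3, 8, 8),
                      c(2, 10, 10), c(2, 11, 10), c(2, 2, 2)), "rna1",
                cell = c(1L, 1L, 1L, 1L, 1L, 0L, 0L))
  cells <- square_map()
  asg <- list(rna1 = epiquant:::new_assignment(f, "projection"))
  tab <- build_cell_table(cells, assignments = asg)
  expect_equal(sum(tab$count_rna1) + attr(tab, "unassigned")[["rna1"]],
               length(f))
  expect_true(is.na(tab$nucleus[1]))     # no pairing given -> empty field

  bad <- f; bad$cell[1] <- 99L
  expect_error(build_cell_table(cells, assignments =
    list(rna1 = epiquant:::new_assignment(bad, "projection"))), "99")
})

test_that("end-to-end counts correlate with the generating Poisson means", {
  fd <- get_flat_detection()
  b <- fd$bundle
  asg <- assign_mixed(fd$spots, b$truth$cells, b$truth$nuclei, fd$pairing, 5)
  tab <- build_cell_table(b$truth$cells, b$truth$nuclei, fd$pairing,
                          assignments = list(rna1 = asg))
  expect_gte(stats::cor(tab$count_rna1, unname(b$truth$lambda)), 0.8)
})

test_that("clustering separates well-separated blobs and honors invariances", {
  set.seed(21)
  x <- rbind(matrix(rnorm(40, 0, 1), 20, 2),
             matrix(rnorm(40, 8, 1), 20, 2))    # 4 sd guaranteed gap 8 sd
  tab <- data.frame(cell = 1:40, f1 = x[, 1], f2 = x[, 2])
  out <- cluster_cells(tab, c("f1", "f2"), k = 2)
  expect_equal(length(unique(out$cluster[1:20])), 1)
  expect_equal(length(unique(out$cluster[21:40])), 1)
  expect_false(out$cluster[1] == out$cluster[40])

  one <- cluster_cells(tab, c("f1", "f2"), k = 1)
  expect_true(all(one$cluster == 1))

  # duplicated feature column: same partition after standardisation (ward)
  tab$f1b <- 3 * tab$f1 + 5
  dup <- cluster_cells(tab, c("f1", "f1b", "f2"), k = 2, linkage = "ward")
  base <- cluster_cells(tab, c("f1", "f1", "f2"), k = 2, linkage = "ward")
  expect_equal(dup$cluster, base$cluster)

  # affine transforms of a column do not change the partition
  tab$g <- -2 * tab$f2 + 100
  aff <- cluster_cells(tab, c("f1", "g"), k = 2)
  expect_equal(aff$cluster, out$cluster)

  expect_error(cluster_cells(tab, "f1", k = 99), "usable")

  # missing feature rows are excluded and keep an empty cluster field
  tab$f1[3] <- NA
  mis <- cluster_cells(tab, c("f1", "f2"), k = 2)
  expect_true(is.na(mis$cluster[3]))
  expect_equal(attr(mis, "excluded"), 3L)
})
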