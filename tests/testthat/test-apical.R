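make_vol <- function(arr, spacing = c(1, 0.5, 0.5)) {
  volume_image(arr, spacing, "junctions")
}

test_that("projection finds single-plane signal and breaks ties to smaller Z", {
  a <- array(0, c(12, 10, 10)); a[8, , ] <- 1       # z = 7 (0-based)
  zr <- project_apical(make_vol(a), method = "max")
  expect_true(all(zr$projection == 1))
  expect_true(all(zr$zmap == 7))

  b <- array(0, c(12, 6, 6)); b[4, , ] <- 2; b[10, , ] <- 2   # z = 3 and 9
  zr2 <- project_apical(make_vol(b), method = "max")
  expect_true(all(zr2$zmap == 3))

  expect_error(project_apical(make_vol(a), z_range = c(5, 3)), "z_range")
  zr3 <- project_apical(make_vol(b), method = "max", z_range = c(6, 11))
  expect_true(all(zr3$zmap == 9))
})

test_that("projection tracks the curved apical surface within one voxel", {
  b <- get_bundle("curved")
  zr <- project_apical(b$channels$junctions, "local_peak", smooth_sigma = 1)
  tube <- apply(b$truth$clean_junctions, c(2, 3), max) > 60
  expect_lt(mean(abs(zr$zmap - b$truth$zstar)[tube]), 1)
})

test_that("watershed segmentation recovers the synthetic tessellation", {
  b <- get_bundle("default")
  zr <- project_apical(b$channels$junctions, "local_peak", smooth_sigma = 1)
  lab <- segment_cells_2d(zr, seed_h = 40, min_area = 5, max_area = 500,
                          smooth_sigma = 0.4)
  labs <- sort(unique(lab[lab > 0]))
  expect_length(labs, 50)
  sc <- score_cells(lab, b$truth$cells)
  expect_true(all(sc$table$jaccard >= 0.8))
  # labeled regions partition the non-ridge foreground
  expect_lte(sum(lab > 0), length(lab))
})

test_that("degenerate segmentation inputs behave as documented", {
  g <- voxel_grid(c(4, 16, 16), c(1, 0.5, 0.5))
  flatzr <- structure(list(projection = matrix(3, 16, 16),
                           zmap = matrix(1, 16, 16), grid = g,
                           method = "max"), class = "zref_map")
  expect_error(segment_cells_2d(flatzr, 1), "no seeds")

  b <- get_bundle("default")
  zr <- project_apical(b$channels$junctions, "local_peak", smooth_sigma = 1)
  lab <- segment_cells_2d(zr, seed_h = 40, min_area = 5000, max_area = 6000,
                          smooth_sigma = 0.4)
  expect_true(all(lab == 0))     # filter removed everything, no error
})

test_that("merge keeps the smaller label and conserves area; delete removes", {
  lab <- matrix(0L, 10, 10)
  lab[1:4, 1:4] <- 5L; lab[6:9, 6:9] <- 2L; lab[1:3, 7:9] <- 8L
  a5 <- sum(lab == 5); a2 <- sum(lab == 2)
  m <- merge_cells(lab, 5, 2)
  expect_false(any(m == 5))
  expect_equal(sum(m == 2), a5 + a2)
  expect_error(merge_cells(lab, 5, 99), "not present")

  d <- delete_cell(lab, 8)
  expect_setdiff <- setdiff(unique(lab[lab > 0]), unique(d[d > 0]))
  expect_equal(expect_setdiff, 8L)
  expect_error(delete_cell(lab, 99), "not present")
})

test_that("cell Z comes from the boundary band and is robust via the median", {
  g <- voxel_grid(c(50, 8, 8), c(1, 0.5, 0.5))
  lab <- matrix(0L, 8, 8); lab[3:6, 3:6] <- 1L
  zmap <- matrix(3, 8, 8)
  # an outlier inside the interior must not matter: band excludes it
  zmap[4:5, 4:5] <- 40
  zr <- structure(list(projection = matrix(1, 8, 8), zmap = zmap, grid = g,
                       method = "max"), class = "zref_map")
  m <- estimate_cell_z(lab, zr, stat = "median")
  expect_equal(unname(m$cell_z), 3)

  # median robustness on band values {3,3,3,40}
  expect_equal(stats::median(c(3, 3, 3, 40)), 3)
})

test_that("flat tissue gives constant cell Z; curved errors stay within 2 voxels", {
  b <- get_bundle("flat")
  zr <- project_apical(b$channels$junctions, "local_peak", smooth_sigma = 1)
  m <- estimate_cell_z(b$truth$cells$labels2d, zr)
  expect_lt(max(abs(m$cell_z - b$truth$cells$cell_z)), 0.51)

  pipe <- get_curved_pipeline()
  tab <- pipe$cell_match$table
  ok <- !is.na(tab$pred)
  err <- abs(pipe$cells$cell_z[as.character(tab$pred[ok])] -
               get_bundle("curved")$truth$cells$cell_z[as.character(tab$truth[ok])])
  expect_lte(max(err), 2)
})

test_that("cell Z estimation is invariant under relabeling", {
  b <- get_bundle("small")
  zr <- project_apical(b$channels$junctions, "local_peak", smooth_sigma = 1)
  lab <- b$truth$cells$labels2d
  m1 <- estimate_cell_z(lab, zr)
  set.seed(42)
  perm <- sample(100:200, length(cell_labels(b$truth$cells)))
  lab2 <- lab
  lab2[lab > 0] <- perm[lab[lab > 0]]
  m2 <- estimate_cell_z(lab2, zr)
  expect_equal(unname(m2$cell_z[as.character(perm)]),
               unname(m1$cell_z[as.character(seq_along(perm))]))
})
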