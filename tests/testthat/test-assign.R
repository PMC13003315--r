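# A small hand-built tissue: two square cells side by side, one nucleus
# under each, on an isotropic-lateral grid.
two_cell_fixture <- function() {
  ny <- nx <- 40; nz <- 30
  lab <- matrix(0L, ny, nx)
  lab[5:35, 3:19] <- 1L
  lab[5:35, 22:38] <- 2L
  grid <- voxel_grid(c(nz, ny, nx), c(1, 0.5, 0.5))
  cells <- apical_cell_map(lab, c("1" = 4, "2" = 4), grid)
  nl <- array(0L, grid$shape)
  nl[9:13, 16:24, 8:14] <- 1L
  nl[9:13, 16:24, 27:33] <- 2L
  nuclei <- nuclei_labels(nl, grid)
  pairing <- cell_pairing(c("1" = 1L, "2" = 2L), 0)
  list(cells = cells, nuclei = nuclei, pairing = pairing, grid = grid)
}

test_that("projection assigns by footprint at any Z and skips background", {
  f <- two_cell_fixture()
  ss <- spot_set(rbind(c(25, 10, 10),   # deep, over cell 1
                       c(5, 10, 30),    # shallow, over cell 2
                       c(12, 2, 2)),    # background corner
                 "rna")
  r <- assign_projection(ss, f$cells)
  expect_equal(r$spots$cell, c(1L, 2L, 0L))
  expect_equal(r$unassigned_count, 1)
  # invariant to spot Z
  ss2 <- ss; ss2$coords[, 1] <- c(1, 28, 3)
  expect_equal(assign_projection(ss2, f$cells)$spots$cell, r$spots$cell)
})

test_that("nearest-nucleus uses containment, surface distance and label ties", {
  f <- two_cell_fixture()
  ss <- spot_set(rbind(c(11, 20, 10),     # inside nucleus 1
                       c(18, 20, 30),     # below nucleus 2
                       c(11, 20, 19.5)),  # equidistant between the two
                 "rna")
  r <- assign_nearest_nucleus(ss, f$nuclei, f$pairing)
  expect_equal(r$spots$cell[1], 1L)
  expect_equal(r$spots$cell[2], 2L)
  expect_equal(r$spots$cell[3], 1L)       # tie -> lower nucleus label
  # unpaired nuclei leave spots unassigned
  half <- cell_pairing(c("1" = 1L), 0)
  r2 <- assign_nearest_nucleus(ss, f$nuclei, half)
  expect_equal(r2$spots$cell[2], 0L)
  # empty nuclei -> all unassigned
  empty <- nuclei_labels(array(0L, f$grid$shape), f$grid)
  r3 <- assign_nearest_nucleus(ss, empty, f$pairing)
  expect_true(all(r3$spots$cell == 0))
})

test_that("mixed reduces to its two limits", {
  f <- two_cell_fixture()
  set.seed(5)
  ss <- spot_set(cbind(runif(40, 5, 25), runif(40, 5, 35), runif(40, 3, 37)),
                 "rna")
  proj <- assign_projection(ss, f$cells)
  nn <- assign_nearest_nucleus(ss, f$nuclei, f$pairing)
  inf_cut <- assign_mixed(ss, f$cells, f$nuclei, f$pairing, depth_cut = Inf)
  hit <- proj$spots$cell > 0
  expect_equal(inf_cut$spots$cell[hit], proj$spots$cell[hit])
  zero_cut <- assign_mixed(ss, f$cells, f$nuclei, f$pairing, depth_cut = 0)
  below <- ss$coords[, 1] > 4     # strictly below the apical plane
  expect_equal(zero_cut$spots$cell[below], nn$spots$cell[below])
})

test_that("hull containment covers the cell body and rejects deep spots", {
  f <- two_cell_fixture()
  ss <- spot_set(rbind(c(8, 20, 10),     # between apical polygon and nucleus 1
                       c(28, 20, 10),    # far below both nuclei
                       c(6, 20, 30)),    # upper body of cell 2
                 "rna")
  r <- assign_hull(ss, f$cells, f$nuclei, f$pairing, pad = 0.5)
  expect_equal(r$spots$cell, c(1L, 0L, 2L))
})

test_that("degenerate hull support assigns nothing, with a warning", {
  f <- two_cell_fixture()
  no_pairs <- cell_pairing(stats::setNames(integer(0), character(0)), 0)
  ss <- spot_set(rbind(c(8, 20, 10)), "rna")
  expect_warning(r <- assign_hull(ss, f$cells, f$nuclei, no_pairs),
                 "degenerate")
  expect_equal(r$spots$cell, 0L)
})

test_that("hull decisions equal the brute-force half-space oracle", {
  f <- two_cell_fixture()
  set.seed(9)
  ss <- spot_set(cbind(runif(60, 2, 28), runif(60, 1, 39), runif(60, 1, 39)),
                 "rna")
  cm <- hull_containment(ss, f$cells, f$nuclei, f$pairing, pad = 0.5)
  for (i in seq_along(cm$labels)) {
    sup <- hull_support_points(f$cells, f$nuclei, f$pairing, cm$labels[i])
    sp <- f$grid$spacing
    for (s in seq_len(length(ss))) {
      o <- oracle_point_in_hull(sup, ss$coords[s, ] * sp, 0.5)
      expect_equal(cm$inside[s, i], o)
    }
  }
})

test_that("iterative assignment follows strict majorities and terminates", {
  # 1 unassigned spot whose 3 nearest assigned neighbors are all cell 4
  ss <- spot_set(rbind(c(5, 5, 5), c(5, 5, 6), c(5, 6, 5), c(5, 6, 6),
                       c(20, 30, 30)), "rna",
                 cell = c(0L, 4L, 4L, 4L, 9L))
  init <- epiquant:::new_assignment(ss, "seed")
  r <- assign_iterative(ss, init, k = 3, max_iter = 5)
  expect_equal(r$spots$cell[1], 4L)
  expect_equal(r$spots$cell[-1], ss$cell[-1])      # assigned spots frozen

  # a 2-2 tie among k = 4 neighbors stays unassigned
  tie <- spot_set(rbind(c(5, 5, 5), c(5, 5, 6), c(5, 6, 5),
                        c(5, 4, 5), c(5, 5, 4)), "rna",
                  cell = c(0L, 4L, 4L, 7L, 7L))
  r2 <- assign_iterative(tie, epiquant:::new_assignment(tie, "seed"), k = 4)
  expect_equal(r2$spots$cell[1], 0L)

  # nothing assigned in the base -> returned unchanged
  none <- spot_set(rbind(c(5, 5, 5)), "rna", cell = 0L)
  r3 <- assign_iterative(none, epiquant:::new_assignment(none, "seed"))
  expect_equal(r3$spots$cell, 0L)
})

test_that("iterative recovers hidden assignments on the simulator", {
  # neighborhood label propagation presumes enough assigned neighbors per
  # cell, so this runs in the uniformly high-expression regime
  b <- generate_tissue(tissue_params(seed = 1, nucleus_jitter = 0,
                                     lambda_high = 30, lambda_low = 30))
  truth <- b$truth$spots$rna1
  set.seed(13)
  hidden <- sample(length(truth), round(0.2 * length(truth)))
  start <- truth
  start$cell[hidden] <- 0L
  init <- epiquant:::new_assignment(start, "masked-truth")
  prev_un <- init$unassigned_count
  r <- assign_iterative(truth, init, k = 3, max_iter = 10,
                        spacing = b$params$spacing)
  expect_lte(r$unassigned_count, prev_un)          # monotone nonincreasing
  rec <- r$spots$cell[hidden]
  ok <- rec > 0
  expect_gte(mean(rec[ok] == truth$cell[hidden][ok]), 0.9)
})

test_that("every strategy conserves spot counts", {
  fd <- get_flat_detection()
  b <- fd$bundle
  res <- list(assign_projection(fd$spots, b$truth$cells),
              assign_nearest_nucleus(fd$spots, b$truth$nuclei, fd$pairing),
              assign_mixed(fd$spots, b$truth$cells, b$truth$nuclei,
                           fd$pairing, 5),
              assign_hull(fd$spots, b$truth$cells, b$truth$nuclei,
                          fd$pairing, 0.5))
  for (r in res) {
    per_cell <- table(r$spots$cell[r$spots$cell > 0])
    expect_equal(sum(per_cell) + r$unassigned_count, length(fd$spots))
  }
})

test_that("strategy comparison reports agreement, unassigned and accuracy", {
  fd <- get_flat_detection()
  b <- fd$bundle
  res <- list(assign_projection(fd$spots, b$truth$cells),
              assign_mixed(fd$spots, b$truth$cells, b$truth$nuclei,
                           fd$pairing, 5))
  cmp <- compare_strategies(res)
  expect_equal(diag(cmp$agreement), c(projection = 1, mixed = 1))
  expect_equal(cmp$agreement, t(cmp$agreement))
  expect_true(all(cmp$agreement >= 0 & cmp$agreement <= 1))

  # disjoint assignments agree on nothing
  a <- spot_set(matrix(1, 10, 3), "r", cell = rep(1L, 10))
  b2 <- spot_set(matrix(1, 10, 3), "r", cell = rep(2L, 10))
  cmp2 <- compare_strategies(list(epiquant:::new_assignment(a, "A"),
                                  epiquant:::new_assignment(b2, "B")))
  expect_equal(cmp2$agreement["A", "B"], 0)

  short <- spot_set(matrix(1, 3, 3), "r")
  expect_error(compare_strategies(list(epiquant:::new_assignment(a, "A"),
                                       epiquant:::new_assignment(short, "S"))),
               "different spot counts")
})
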