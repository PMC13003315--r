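render_ellipsoid <- function(arr, center, radii, spacing, value = 100) {
  d <- dim(arr)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    m <- sum((((c(z, y, x) - 1) - center) * spacing / radii)^2)
    if (m <= 1) arr[z, y, x] <- value
  }
  arr
}

test_that("a single noiseless ellipsoid yields one label at the right centroid", {
  sp <- c(1, 0.5, 0.5)
  a <- array(0, c(16, 32, 32))
  a <- render_ellipsoid(a, c(8, 15, 17), c(2, 3, 3), sp)
  nuc <- segment_nuclei(volume_image(a, sp, "nuclei"), radius = 2.5)
  expect_equal(nrow(nuc$props), 1)
  expect_lt(max(abs(c(nuc$props$z, nuc$props$y, nuc$props$x) - c(8, 15, 17))), 1)
})

test_that("two ellipsoids separated by more than 2 radii give two labels", {
  sp <- c(1, 0.5, 0.5)
  a <- array(0, c(16, 48, 48))
  a <- render_ellipsoid(a, c(8, 12, 12), c(2, 3, 3), sp)
  a <- render_ellipsoid(a, c(8, 34, 34), c(2, 3, 3), sp)
  nuc <- segment_nuclei(volume_image(a, sp, "nuclei"), radius = 2.5)
  expect_equal(nrow(nuc$props), 2)
})

test_that("an empty volume yields an empty result, not an error", {
  sp <- c(1, 0.5, 0.5)
  a <- array(0, c(8, 16, 16))
  nuc <- segment_nuclei(volume_image(a, sp, "nuclei"), radius = 2)
  expect_equal(nrow(nuc$props), 0)
  expect_error(segment_nuclei(volume_image(a, sp, "n"), radius = -1), "> 0")
})

test_that("simulated nuclei are recovered in count and position", {
  b <- get_bundle("default")
  nuc <- filter_nuclei(segment_nuclei(b$channels$nuclei, radius = 1.8),
                       min_volume = 5, max_volume = 200)
  n_true <- b$params$n_cells
  expect_gte(nrow(nuc$props), 0.9 * n_true)
  expect_lte(nrow(nuc$props), 1.1 * n_true)
  sn <- score_nuclei(nuc, b$truth$nuclei)
  expect_lte(sn$mean_centroid_error_um, 1)
})

test_that("output labels are connected components with exact volumes", {
  b <- get_bundle("small")
  nuc <- segment_nuclei(b$channels$nuclei, radius = 1.8)
  lab <- nuc$labels3d
  d <- as.integer(dim(lab))
  for (l in nuc$props$label) {
    cc <- label_components_cpp(as.vector(lab == l), d, TRUE)
    expect_equal(max(cc), 1)      # 26-connected, never split
  }
  counts <- table(lab[lab > 0])
  expect_equal(unname(nuc$props$volume_um3),
               as.numeric(counts[as.character(nuc$props$label)]) *
                 prod(nuc$grid$spacing))
})

test_that("volume filtering keeps the in-range nucleus and is idempotent/monotone", {
  sp <- c(1, 1, 1)
  g <- voxel_grid(c(30, 20, 20), sp)
  lab <- array(0L, g$shape)
  lab[1, 1, 1:10] <- 1L                 # 10 um^3
  lab[5:8, 4:8, 4:8] <- 2L              # 100 um^3
  lab[12:21, 8:17, 8:17] <- 3L          # 1000 um^3
  nuc <- nuclei_labels(lab, g)
  f <- filter_nuclei(nuc, 50, 500)
  expect_equal(f$props$label, 2L)
  expect_equal(filter_nuclei(f, 50, 500)$props, f$props)           # idempotent
  tight <- filter_nuclei(nuc, 90, 110)
  expect_true(all(tight$props$label %in% f$props$label))            # monotone
  expect_equal(filter_nuclei(nuc, 0, Inf)$props, nuc$props)         # identity
  zf <- filter_nuclei(nuc, 0, Inf, z_keep = c(0, 3))
  expect_equal(zf$props$label, 1L)
})

test_that("injected undersized speckles are exactly the filtered labels", {
  b <- generate_tissue(tissue_params(shape = c(24, 96, 96), n_cells = 8,
                                     seed = 7, n_speckles = 5))
  n_before <- nrow(b$truth$nuclei$props)
  expect_equal(n_before, 8 + 5)
  f <- filter_nuclei(b$truth$nuclei, min_volume = 5)
  expect_equal(n_before - nrow(f$props), 5)
  expect_true(all(f$props$label <= 8))
})
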