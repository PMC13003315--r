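render_spot <- function(arr, center, sigma_vox, amp = 100) {
  d <- dim(arr)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    arr[z, y, x] <- arr[z, y, x] +
      amp * exp(-sum((((c(z, y, x) - 1) - center) / sigma_vox)^2) / 2)
  }
  arr
}

test_that("a single noiseless Gaussian spot is localised to half a voxel", {
  sp <- c(1, 0.5, 0.5)
  a <- array(0, c(20, 40, 50))
  a <- render_spot(a, c(10.0, 20.0, 30.0), c(1, 1.2, 1.2))
  ss <- detect_spots(volume_image(a, sp, "rna"), c(1.7, 0.5), threshold = 1)
  expect_equal(length(ss), 1)
  expect_true(all(abs(ss$coords - c(10, 20, 30)) <= 0.5))
})

test_that("an empty volume yields no spots", {
  ss <- detect_spots(volume_image(array(0, c(8, 16, 16)), c(1, 0.5, 0.5), "r"),
                     c(1.7, 0.5), threshold = 1)
  expect_equal(length(ss), 0)
})

test_that("raising the threshold never adds spots, and shifts do not detect", {
  b <- get_bundle("spots400")
  ch <- b$channels$rna1
  n_prev <- Inf
  for (thr in c(5, 10, 20, 40)) {
    n <- length(detect_spots(ch, c(1.7, 0.5), threshold = thr))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  # additive intensity shifts leave value-threshold detections unchanged
  s1 <- detect_spots(ch, c(1.7, 0.5), threshold = 10)
  ch2 <- volume_image(ch$data + 37, ch$grid$spacing, "rna1")
  s2 <- detect_spots(ch2, c(1.7, 0.5), threshold = 10)
  expect_equal(s1$coords, s2$coords)
})

test_that("simulated spots at SNR 5 are recovered with high precision and recall", {
  b <- get_bundle("spots400")
  ss <- detect_spots(b$channels$rna1, c(1.7, 0.5), "auto")
  sc <- score_spots(ss, b$truth$spots$rna1, radius_vox = 2)
  expect_gte(sc$precision, 0.9)
  expect_gte(sc$recall, 0.9)
})

test_that("the knee threshold separates bimodal candidate responses", {
  set.seed(1)
  noise <- rnorm(100, 10, 1)
  signal <- rnorm(50, 50, 2)
  thr <- auto_threshold(c(noise, signal))
  expect_lte(mean(noise >= thr), 0.05)   # essentially all noise rejected
  expect_true(all(signal > thr))         # no signal lost
})

test_that("degenerate and undersized candidate sets are handled explicitly", {
  expect_equal(auto_threshold(rep(7, 25)), 7)
  expect_error(auto_threshold(rnorm(5)), "manual threshold")
})

test_that("the automatic threshold is close to the grid-search optimum", {
  b <- get_bundle("spots400")
  ch <- b$channels$rna1
  truth <- b$truth$spots$rna1
  auto <- detect_spots(ch, c(1.7, 0.5), "auto")
  f1_auto <- score_spots(auto, truth, 2)$f1
  f1_grid <- max(vapply(seq(4, 40, by = 2), function(t) {
    score_spots(detect_spots(ch, c(1.7, 0.5), t), truth, 2)$f1
  }, numeric(1)))
  expect_gte(f1_auto, f1_grid - 0.05)
})

test_that("spot edits apply removals before additions and invert cleanly", {
  set.seed(3)
  ss <- spot_set(cbind(runif(10, 1, 6), runif(10, 1, 14), runif(10, 1, 14)),
                 "rna", intensity = runif(10), cell = integer(10))
  out <- edit_spots(ss, add = rbind(c(2, 3, 4), c(3, 4, 5)), remove = 1)
  expect_equal(length(out), 11)
  expect_true(all(out$cell[10:11] == 0))

  gone <- edit_spots(ss, remove = 1:10)
  expect_equal(length(gone), 0)
  expect_error(edit_spots(ss, remove = 99), "out of range")

  roundtrip <- edit_spots(edit_spots(ss, add = rbind(c(1, 2, 3))),
                          remove = 11)
  expect_equal(roundtrip$coords, ss$coords)
  expect_equal(roundtrip$intensity, ss$intensity)
})
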