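# Single-molecule (smFISH) spot detection: scale-normalised 3D LoG filter,
# strict local maxima, automatic knee threshold, quadratic sub-voxel
# refinement.

#' Detect diffraction-limited 3D spots in an smFISH channel
#'
#' A LoG filter with per-axis sigma `radius / sqrt(3) / spacing` is applied;
#' candidates are the strict local maxima of the response in a 3x3x3
#' neighborhood (plateau ties keep the lexicographically smallest
#' coordinate; voxels within one voxel of a face are excluded so quadratic
#' refinement always has both neighbors). Maxima above the threshold
#' (`"auto"` = knee of the count-vs-threshold curve, see
#' [auto_threshold()]) are refined to sub-voxel coordinates by a per-axis
#' quadratic fit of the response, clamped to half a voxel.
#'
#' @param channel a [volume_image()].
#' @param spot_radius spot radius `c(axial, lateral)` in micrometres.
#' @param threshold `"auto"` or a numeric LoG-response threshold.
#' @return a [spot_set()] with `cell = 0` for all spots.
#' @export
detect_spots <- function(channel, spot_radius, threshold = "auto") {
  stopifnot(inherits(channel, "volume_image"))
  spot_radius <- as.numeric(spot_radius)
  if (length(spot_radius) == 1) spot_radius <- rep(spot_radius, 2)
  if (any(spot_radius <= 0)) stop("detect_spots: spot radii must be > 0")
  grid <- channel$grid
  sig_um <- c(spot_radius[1], spot_radius[2], spot_radius[2]) / sqrt(3)
  sig_vox <- sig_um / grid$spacing
  resp <- log_response3d(channel$data, sig_vox)$response
  cand <- local_maxima3d_cpp(as.numeric(resp), as.integer(grid$shape), -Inf)
  empty <- spot_set(matrix(numeric(0), 0, 3), channel$channel_name)
  if (nrow(cand) == 0) return(empty)
  vals <- resp[cbind(cand[, 1] + 1, cand[, 2] + 1, cand[, 3] + 1)]
  thr <- if (identical(threshold, "auto")) auto_threshold(vals) else
    as.numeric(threshold)
  keep <- vals >= thr & vals > 0
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  # quadratic (parabolic) refinement per axis on the response
  coords <- matrix(0, nrow(cand), 3)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ] + 1
    for (ax in 1:3) {
      lo <- p; hi <- p
      lo[ax] <- lo[ax] - 1; hi[ax] <- hi[ax] + 1
      fm <- resp[lo[1], lo[2], lo[3]]
      f0 <- resp[p[1], p[2], p[3]]
      fp <- resp[hi[1], hi[2], hi[3]]
      denom <- fm - 2 * f0 + fp
      off <- if (denom < 0) 0.5 * (fm - fp) / denom else 0
      coords[i, ax] <- cand[i, ax] + max(-0.5, min(0.5, off))
    }
  }
  inten <- channel$data[cbind(cand[, 1] + 1, cand[, 2] + 1, cand[, 3] + 1)]
  spot_set(coords, channel$channel_name, intensity = as.numeric(inten))
}

#' Automatic spot threshold at the knee of the survival curve
#'
#' Candidate LoG responses are swept by 100 evenly spaced thresholds between
#' their minimum and maximum; the number of surviving candidates per
#' threshold traces a decreasing curve whose knee — the point of maximum
#' distance below the chord joining its endpoints — separates the dense
#' noise shoulder from true spots. Because candidate counts span decades
#' (noise maxima vastly outnumber spots), the curve is taken on a log count
#' scale with both axes normalised, which places the knee at the foot of
#' the noise shoulder rather than inside its tail.
#'
#' @param response_maxima numeric vector of candidate response values
#'   (at least 10; fewer is an error instructing a manual threshold).
#' @return the threshold value.
#' @export
auto_threshold <- function(response_maxima) {
  v <- response_maxima[is.finite(response_maxima)]
  if (length(v) < 10) {
    stop("auto_threshold: fewer than 10 candidates; set a manual threshold")
  }
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(lo)  # degenerate chord: all candidates equal
  thr <- seq(lo, hi, length.out = 100)
  counts <- vapply(thr, function(t) sum(v >= t), numeric(1))
  x <- (thr - lo) / (hi - lo)
  y <- log10(counts + 1)
  y <- (y - y[100]) / max(y[1] - y[100], 1e-12)
  # signed distance below the chord from (x[1], y[1]) to (x[100], y[100]);
  # the knee is usually a short plateau, so take its far edge (the largest
  # threshold within 5% of the maximal distance) to step off the noise tail
  chord <- y[1] + (y[100] - y[1]) * (x - x[1]) / (x[100] - x[1])
  d <- chord - y
  thr[max(which(d >= max(d) * 0.95))]
}

#' Batch spot editing (add / remove)
#'
#' Removals are applied before additions. Added spots take their intensity
#' from `image` when provided (nearest voxel), otherwise missing, and start
#' unassigned (`cell = 0`).
#'
#' @param spots a [spot_set()].
#' @param add optional matrix of (z, y, x) coordinates to add.
#' @param remove optional integer indices to remove (1-based).
#' @param image optional [volume_image()] for intensities of added spots.
#' @return updated [spot_set()].
#' @export
edit_spots <- function(spots, add = NULL, remove = NULL, image = NULL) {
  stopifnot(inherits(spots, "spot_set"))
  coords <- spots$coords; inten <- spots$intensity; cell <- spots$cell
  if (!is.null(remove) && length(remove)) {
    remove <- as.integer(remove)
    if (any(remove < 1 | remove > nrow(coords))) {
      stop("edit_spots: remove index out of range")
    }
    keep <- setdiff(seq_len(nrow(coords)), remove)
    coords <- coords[keep, , drop = FALSE]
    inten <- inten[keep]; cell <- cell[keep]
  }
  if (!is.null(add) && NROW(add)) {
    add <- matrix(as.numeric(add), ncol = 3)
    newint <- rep(NA_real_, nrow(add))
    if (!is.null(image)) {
      p <- round(add) + 1
      newint <- image$data[p]
    }
    coords <- rbind(coords, add)
    inten <- c(inten, newint)
    cell <- c(cell, integer(nrow(add)))
  }
  spot_set(coords, spots$channel, inten, cell)
}
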