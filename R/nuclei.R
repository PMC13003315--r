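# 3D nuclei segmentation: anisotropy-aware LoG blob detection seeding a
# watershed on the inverted smoothed intensity, restricted to an Otsu
# foreground mask. External 3D label volumes (e.g. from learned segmenters, read
# with read_labels()) can be passed straight to filter_nuclei().

#' Segment nuclei in 3D with a LoG-seeded watershed
#'
#' Per-axis LoG sigma is `radius / sqrt(3)` divided by that axis's spacing
#' (the standard 3D blob-scale relation). Candidate maxima of the LoG
#' response above `threshold` (auto = Otsu on the response) seed a watershed
#' on the inverted smoothed intensity inside an Otsu foreground mask, so
#' touching nuclei do not fuse into one label.
#'
#' @param nuclear a [volume_image()] of the nuclear stain.
#' @param radius expected nucleus radius in micrometres (> 0).
#' @param threshold `"auto"` or a numeric LoG-response threshold.
#' @return a [nuclei_labels()] object; empty (0 nuclei) when no foreground.
#' @export
segment_nuclei <- function(nuclear, radius, threshold = "auto") {
  stopifnot(inherits(nuclear, "volume_image"))
  if (!is.numeric(radius) || radius <= 0) stop("segment_nuclei: radius must be > 0")
  grid <- nuclear$grid
  sig_vox <- (radius / sqrt(3)) / grid$spacing
  lg <- log_response3d(nuclear$data, sig_vox)
  empty <- nuclei_labels(array(0L, grid$shape), grid)
  if (diff(range(lg$smoothed)) == 0) return(empty)
  fg_thr <- otsu_threshold(as.numeric(lg$smoothed))
  fg <- lg$smoothed >= fg_thr
  if (!any(fg)) return(empty)
  thr <- if (identical(threshold, "auto")) {
    otsu_threshold(as.numeric(lg$response))
  } else as.numeric(threshold)
  cand <- local_maxima3d_cpp(as.numeric(lg$response), as.integer(grid$shape), thr)
  if (nrow(cand) > 0) {
    inside <- fg[cbind(cand[, 1] + 1, cand[, 2] + 1, cand[, 3] + 1)]
    cand <- cand[inside, , drop = FALSE]
  }
  if (nrow(cand) == 0) return(empty)
  # seeds ordered lexicographically by (z, y, x) for determinism
  ord <- order(cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  seeds <- array(0L, grid$shape)
  seeds[cbind(cand[, 1] + 1, cand[, 2] + 1, cand[, 3] + 1)] <- seq_len(nrow(cand))
  lab <- watershed_cpp(as.numeric(-lg$smoothed), as.integer(seeds),
                       as.logical(fg), as.integer(grid$shape), lines = FALSE)
  lab <- array(as.integer(lab), grid$shape)
  nuclei_labels(lab, grid, intensity = nuclear$data)
}

#' Filter nuclei by volume and Z position
#'
#' Removes labels whose volume lies outside `[min_volume, max_volume]` um^3
#' or whose centroid Z (0-based voxel units) falls outside `z_keep`.
#' Idempotent; properties are updated consistently. An empty result is not
#' an error.
#'
#' @param nuclei a [nuclei_labels()] object.
#' @param min_volume,max_volume volume bounds in um^3.
#' @param z_keep optional inclusive Z interval `c(lo, hi)` for centroids.
#' @return filtered [nuclei_labels()].
#' @export
filter_nuclei <- function(nuclei, min_volume = 0, max_volume = Inf,
                          z_keep = NULL) {
  stopifnot(inherits(nuclei, "nuclei_labels"), min_volume <= max_volume)
  p <- nuclei$props
  keep <- p$volume_um3 >= min_volume & p$volume_um3 <= max_volume
  if (!is.null(z_keep)) {
    keep <- keep & p$z >= z_keep[1] & p$z <= z_keep[2]
  }
  drop <- p$label[!keep]
  lab <- nuclei$labels3d
  if (length(drop)) lab[lab %in% drop] <- 0L
  out <- nuclei
  out$labels3d <- lab
  out$props <- p[keep, , drop = FALSE]
  rownames(out$props) <- NULL
  out
}
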