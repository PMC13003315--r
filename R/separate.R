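# Morphological separation of a channel co-staining nuclei and apical
# junctions. Junctions are thin sheets, nuclei are blobs: a grayscale
# opening with an ellipsoidal element of roughly half the nucleus radius
# erases the junctions but preserves the nuclear blobs; the residual (a
# white top-hat) is the junction estimate, so the two virtual channels sum
# exactly back to the input.

# voxel offsets of an anisotropy-aware ellipsoid of physical radii (um)
ellipsoid_offsets <- function(radii_um, spacing) {
  r_vox <- pmax(radii_um / spacing, 0)
  rz <- floor(r_vox[1]); ry <- floor(r_vox[2]); rx <- floor(r_vox[3])
  off <- expand.grid(z = -rz:rz, y = -ry:ry, x = -rx:rx)
  keep <- (off$z * spacing[1] / radii_um[1])^2 +
    (off$y * spacing[2] / radii_um[2])^2 +
    (off$x * spacing[3] / radii_um[3])^2 <= 1 + 1e-9
  as.matrix(off[keep, , drop = FALSE])
}

#' Split a co-stained channel into junction and nuclei estimates
#'
#' @param mixed a [volume_image()] containing both signals.
#' @param nucleus_radius expected nucleus radius in micrometres; a scalar
#'   or `c(axial, lateral)` — the element's per-axis radii are half of
#'   these, so oblate nuclei get a correspondingly flat element that never
#'   cuts their axial caps (junction walls are thin laterally, so a flat
#'   element still erases them).
#' @param junction_thickness junction sheet thickness in micrometres; must
#'   be smaller than the lateral nucleus radius.
#' @return list of two [volume_image()]s, `junctions` and `nuclei`, on the
#'   same grid; they satisfy `junctions + nuclei == mixed` voxelwise and
#'   both are non-negative.
#' @export
separate_junction_nuclei <- function(mixed, nucleus_radius,
                                     junction_thickness) {
  stopifnot(inherits(mixed, "volume_image"))
  if (length(nucleus_radius) == 1) nucleus_radius <- rep(nucleus_radius, 2)
  if (!(min(nucleus_radius) > junction_thickness && junction_thickness > 0)) {
    stop("separate_junction_nuclei: need nucleus_radius > junction_thickness > 0")
  }
  grid <- mixed$grid
  r_el <- c(nucleus_radius[1], nucleus_radius[2], nucleus_radius[2]) / 2
  ext <- 2 * floor(r_el / grid$spacing) + 1
  if (any(ext > grid$shape)) {
    stop("separate_junction_nuclei: structuring element larger than the volume")
  }
  off <- ellipsoid_offsets(r_el, grid$spacing)
  d <- as.integer(grid$shape)
  er <- minmax_filter_cpp(as.numeric(mixed$data), d, off, FALSE)
  op <- minmax_filter_cpp(er, d, off, TRUE)
  nuc <- array(op, grid$shape)
  jun <- mixed$data - nuc          # top-hat; >= 0 by anti-extensivity
  list(junctions = volume_image(jun, grid$spacing,
                                paste0(mixed$channel_name, "_junctions")),
       nuclei = volume_image(nuc, grid$spacing,
                             paste0(mixed$channel_name, "_nuclei")))
}
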