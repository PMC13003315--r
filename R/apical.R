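# Apical projection and 2.5D cell segmentation.
#
# The junction channel approximates a curved 2D sheet inside the 3D stack.
# We project it to 2D (per-pixel argmax along Z, optionally after Gaussian
# smoothing along Z), segment cells on the projection with a seeded
# watershed, and lift the 2D labels back to 2.5D by estimating each cell's
# Z coordinate from the junction signal on its boundary band.

#' Project the junction channel to 2D with a Z reference map
#'
#' `method = "max"` takes the per-pixel maximum and its argmax Z;
#' `"local_peak"` Gaussian-smooths along Z first (sigma in micrometres,
#' converted through dz) and returns the unsmoothed intensity at the argmax
#' of the smoothed profile. Argmax ties break toward the smallest Z.
#'
#' @param junction a [volume_image()] of the apical junction marker.
#' @param method `"max"` or `"local_peak"`.
#' @param smooth_sigma Gaussian sigma along Z in micrometres (local_peak).
#' @param z_range optional inclusive 0-based Z interval `c(lo, hi)` to search.
#' @return object of class `zref_map`: `projection` (ny x nx intensity),
#'   `zmap` (ny x nx argmax Z, 0-based), `grid`.
#' @export
project_apical <- function(junction, method = c("local_peak", "max"),
                           smooth_sigma = 1, z_range = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(junction, "volume_image"))
  nz <- junction$grid$shape[1]
  if (is.null(z_range)) z_range <- c(0, nz - 1)
  z_range <- as.integer(z_range)
  if (z_range[1] > z_range[2] || z_range[1] < 0 || z_range[2] > nz - 1) {
    stop("project_apical: empty or out-of-bounds z_range")
  }
  zs <- (z_range[1]:z_range[2]) + 1
  raw <- junction$data[zs, , , drop = FALSE]
  search <- raw
  if (method == "local_peak") {
    sz <- smooth_sigma / junction$grid$spacing[1]
    search <- smooth_gaussian3d(raw, c(sz, 0, 0))
  }
  d <- dim(search)
  m <- matrix(search, d[1], d[2] * d[3])           # planes x pixels
  amax <- max.col(t(m), ties.method = "first")     # first = smallest Z
  pick <- cbind(amax, seq_len(ncol(m)))
  proj <- matrix(matrix(raw, d[1], d[2] * d[3])[pick], d[2], d[3])
  zmap <- matrix(amax - 1 + z_range[1], d[2], d[3])
  structure(list(projection = proj, zmap = zmap, grid = junction$grid,
                 method = method),
            class = "zref_map")
}

#' @export
print.zref_map <- function(x, ...) {
  cat(sprintf("<zref_map (%s)> %dx%d, z in [%d, %d]\n", x$method,
              nrow(x$zmap), ncol(x$zmap), min(x$zmap), max(x$zmap)))
  invisible(x)
}

# seeds = connected components of the deep regional minima of f: a minimum
# of depth >= h satisfies (reconstruction-by-erosion of f+h over f) - f = h
hminima_seeds <- function(f, h) {
  d <- c(1L, dim(f))
  rec <- -reconstruct_dilation_cpp(as.numeric(-(f + h)), as.numeric(-f), d)
  deep <- (rec - as.numeric(f)) >= h * (1 - 1e-9)
  matrix(label_components_cpp(deep, d, TRUE), dim(f)[1], dim(f)[2])
}

#' Segment cells on the apical projection (seeded watershed)
#'
#' Classical fallback for epithelium-like projections: seeds are the
#' connected minima of the h-minima transform of the projection (depth
#' `seed_h`), flooded by a marker-seeded watershed whose ridge lines (the
#' junctions) become background 0. Regions with an area outside
#' `[min_area, max_area]` are removed. Label images from external segmenters
#' can be used instead via [read_labels()].
#'
#' @param zref a `zref_map` from [project_apical()].
#' @param seed_h h-minima depth in intensity units.
#' @param min_area,max_area area bounds in um^2.
#' @param smooth_sigma optional 2D Gaussian pre-smoothing of the projection
#'   in micrometres (0 = none), regularising pixel noise before seeding and
#'   flooding.
#' @return 2D integer label matrix (0 = background/ridges).
#' @export
segment_cells_2d <- function(zref, seed_h, min_area = 0, max_area = Inf,
                             smooth_sigma = 0) {
  proj <- zref$projection
  if (diff(range(proj)) == 0) {
    stop("segment_cells_2d: projection is constant, no seeds found; use a smaller seed_h")
  }
  if (smooth_sigma > 0) {
    sig_px <- smooth_sigma / zref$grid$spacing[2:3]
    proj <- smooth_gaussian3d(array(proj, c(1, dim(proj))),
                              c(0, sig_px))[1, , ]
  }
  seeds <- hminima_seeds(proj, seed_h)
  if (max(seeds) == 0) {
    stop("segment_cells_2d: no seeds found; use a smaller seed_h")
  }
  d <- c(1L, dim(proj))
  lab <- watershed_cpp(as.numeric(proj), as.integer(seeds),
                       rep(TRUE, length(proj)), d, lines = TRUE)
  lab <- matrix(lab, dim(proj)[1], dim(proj)[2])
  pxarea <- prod(zref$grid$spacing[2:3])
  sizes <- table(lab[lab > 0])
  bad <- as.integer(names(sizes))[as.numeric(sizes) * pxarea < min_area |
                                  as.numeric(sizes) * pxarea > max_area]
  if (length(bad)) lab[lab %in% bad] <- 0L
  lab
}

#' Merge two cells in a 2D label image
#'
#' The merged region keeps the smaller of the two labels.
#'
#' @param labels2d integer label matrix.
#' @param a,b labels to merge (both present).
#' @return updated label matrix.
#' @export
merge_cells <- function(labels2d, a, b) {
  for (l in c(a, b)) {
    if (!any(labels2d == l)) stop("merge_cells: label ", l, " not present")
  }
  keep <- min(a, b)
  labels2d[labels2d == max(a, b)] <- as.integer(keep)
  labels2d
}

#' Delete a cell from a 2D label image
#'
#' @param labels2d integer label matrix.
#' @param a label to delete (present).
#' @return updated label matrix with the region set to 0.
#' @export
delete_cell <- function(labels2d, a) {
  if (!any(labels2d == a)) stop("delete_cell: label ", a, " not present")
  labels2d[labels2d == a] <- 0L
  labels2d
}

# per-cell one-pixel-dilated boundary band (as row indices into the image);
# the band reaches onto ridge pixels, which carry the junction Z signal
cell_boundary_band <- function(labels2d, label) {
  idx <- which(labels2d == label, arr.ind = TRUE)
  ny <- nrow(labels2d); nx <- ncol(labels2d)
  r0 <- max(1, min(idx[, 1]) - 2); r1 <- min(ny, max(idx[, 1]) + 2)
  c0 <- max(1, min(idx[, 2]) - 2); c1 <- min(nx, max(idx[, 2]) + 2)
  sub <- labels2d[r0:r1, c0:c1, drop = FALSE] == label
  nr <- nrow(sub); nc <- ncol(sub)
  # interior = pixels whose 4-neighborhood is all inside the cell
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sub
  interior <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  boundary <- sub & !interior
  # image-edge pixels of the cell are boundary too (handled: pad is FALSE)
  pb <- matrix(FALSE, nr + 2, nc + 2)
  pb[2:(nr + 1), 2:(nc + 1)] <- boundary
  band <- pb[2:(nr + 1), 2:(nc + 1)]
  for (dy in -1:1) for (dx in -1:1) {
    band <- band | pb[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  }
  w <- which(band, arr.ind = TRUE)
  cbind(w[, 1] + r0 - 1, w[, 2] + c0 - 1)
}

#' Lift 2D cell labels to 2.5D by estimating per-cell Z
#'
#' The Z coordinate of each cell is the `stat` of the Z reference map over a
#' one-pixel-dilated band around the cell boundary — only the junctions
#' carry apical signal, so the boundary band, not the interior, is
#' informative. Values are clamped to [0, nz-1].
#'
#' @param labels2d 2D integer label matrix.
#' @param zref a `zref_map` with matching shape.
#' @param stat `"median"` (robust, default) or `"mean"`.
#' @return an [apical_cell_map()].
#' @export
estimate_cell_z <- function(labels2d, zref, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (!all(dim(labels2d) == dim(zref$zmap))) {
    stop("estimate_cell_z: labels2d and zmap shapes differ")
  }
  labs <- sort(unique(labels2d[labels2d > 0]))
  f <- if (stat == "median") stats::median else mean
  nz <- zref$grid$shape[1]
  cz <- vapply(labs, function(l) {
    band <- cell_boundary_band(labels2d, l)
    if (nrow(band) == 0) stop("estimate_cell_z: empty boundary band for label ", l)
    min(max(f(zref$zmap[band]), 0), nz - 1)
  }, numeric(1))
  apical_cell_map(labels2d, stats::setNames(cz, labs), zref$grid)
}
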