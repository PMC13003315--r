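# Shared domain types. Light S3 containers with validating constructors:
#  - voxel_grid:      image geometry (shape + spacing in um)
#  - volume_image:    one channel of a 3D stack
#  - apical_cell_map: 2D cell labels + per-cell Z coordinate (the 2.5D object)
#  - nuclei_labels:   3D label volume + per-nucleus properties
#  - spot_set:        sub-voxel 3D spot coordinates with channel/cell fields
#  - cell_pairing:    injective cell -> nucleus mapping with total cost

#' Voxel grid geometry
#'
#' @param shape integer triple (nz, ny, nx), all >= 1.
#' @param spacing physical voxel size (dz, dy, dx) in micrometres, all > 0.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3, length(spacing) == 3,
            all(shape >= 1), all(spacing > 0))
  structure(list(shape = shape, spacing = spacing), class = "voxel_grid")
}

#' One channel of a 3D fluorescence stack
#'
#' @param data 3D non-negative array indexed (z, y, x).
#' @param spacing voxel size (dz, dy, dx) in micrometres.
#' @param channel_name channel label.
#' @return an object of class `volume_image` with fields `data`, `grid`,
#'   `channel_name`.
#' @export
volume_image <- function(data, spacing, channel_name = "ch0") {
  stopifnot(length(dim(data)) == 3)
  if (!all(is.finite(data))) stop("volume_image: intensities must be finite")
  grid <- voxel_grid(dim(data), spacing)
  structure(list(data = data, grid = grid, channel_name = channel_name),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image '%s'> %s voxels, spacing %s um, range [%g, %g]\n",
              x$channel_name, paste(x$grid$shape, collapse = "x"),
              paste(x$grid$spacing, collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' 2.5D apical cell map: 2D labels with per-cell Z coordinates
#'
#' @param labels2d integer matrix (ny, nx); 0 is background.
#' @param cell_z numeric vector of Z coordinates (0-based voxel units), named
#'   by cell label; one entry per positive label in `labels2d`.
#' @param grid a [voxel_grid()] giving the parent stack geometry.
#' @return an object of class `apical_cell_map`.
#' @export
apical_cell_map <- function(labels2d, cell_z, grid) {
  stopifnot(is.matrix(labels2d), inherits(grid, "voxel_grid"))
  labs <- sort(unique(labels2d[labels2d > 0]))
  if (length(labs) > 0) {
    nm <- as.integer(names(cell_z))
    if (anyNA(nm) || !setequal(nm, labs)) {
      stop("apical_cell_map: cell_z must have exactly one entry per positive label")
    }
    cell_z <- cell_z[as.character(labs)]
    if (any(cell_z < 0 | cell_z > grid$shape[1] - 1)) {
      stop("apical_cell_map: cell_z out of [0, nz-1]")
    }
  } else {
    cell_z <- stats::setNames(numeric(0), character(0))
  }
  if (any(dim(labels2d) != grid$shape[2:3])) {
    stop("apical_cell_map: labels2d shape must match grid (ny, nx)")
  }
  structure(list(labels2d = labels2d, cell_z = cell_z, grid = grid),
            class = "apical_cell_map")
}

#' Labels present in an apical cell map
#' @param cells an `apical_cell_map`.
#' @return sorted integer vector of cell labels.
#' @export
cell_labels <- function(cells) as.integer(names(cells$cell_z))

#' @export
print.apical_cell_map <- function(x, ...) {
  cat(sprintf("<apical_cell_map> %d cells on %dx%d pixels, z in [%g, %g]\n",
              length(x$cell_z), nrow(x$labels2d), ncol(x$labels2d),
              if (length(x$cell_z)) min(x$cell_z) else NA,
              if (length(x$cell_z)) max(x$cell_z) else NA))
  invisible(x)
}

#' 3D nuclei labels with per-nucleus properties
#'
#' Properties are recomputed from the label volume: centroid (0-based voxel
#' units), volume in um^3 (voxel count x dz*dy*dx), and mean intensity when
#' an intensity volume is supplied.
#'
#' @param labels3d 3D integer array (z, y, x); 0 is background.
#' @param grid a [voxel_grid()].
#' @param intensity optional 3D array for per-nucleus mean intensity.
#' @return an object of class `nuclei_labels` with a `props` data.frame.
#' @export
nuclei_labels <- function(labels3d, grid, intensity = NULL) {
  stopifnot(length(dim(labels3d)) == 3, inherits(grid, "voxel_grid"))
  if (any(dim(labels3d) != grid$shape)) {
    stop("nuclei_labels: labels3d shape must match grid")
  }
  props <- nucleus_props(labels3d, grid, intensity)
  structure(list(labels3d = labels3d, grid = grid, props = props),
            class = "nuclei_labels")
}

nucleus_props <- function(labels3d, grid, intensity = NULL) {
  idx <- which(labels3d > 0)
  if (length(idx) == 0) {
    return(data.frame(label = integer(0), z = numeric(0), y = numeric(0),
                      x = numeric(0), volume_um3 = numeric(0),
                      mean_intensity = numeric(0)))
  }
  lab <- as.integer(labels3d[idx])
  d <- dim(labels3d)
  z <- (idx - 1) %% d[1]
  y <- ((idx - 1) %/% d[1]) %% d[2]
  x <- (idx - 1) %/% (d[1] * d[2])
  n <- tapply(rep(1, length(lab)), lab, sum)
  labs <- as.integer(names(n))
  vvox <- prod(grid$spacing)
  props <- data.frame(
    label = labs,
    z = as.numeric(tapply(z, lab, mean)),
    y = as.numeric(tapply(y, lab, mean)),
    x = as.numeric(tapply(x, lab, mean)),
    volume_um3 = as.numeric(n) * vvox,
    mean_intensity = if (is.null(intensity)) NA_real_ else
      as.numeric(tapply(intensity[idx], lab, mean))
  )
  props[order(props$label), , drop = FALSE]
}

#' @export
print.nuclei_labels <- function(x, ...) {
  cat(sprintf("<nuclei_labels> %d nuclei in %s voxels\n",
              nrow(x$props), paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' A set of detected 3D spots
#'
#' @param coords numeric matrix (n x 3) of sub-voxel (z, y, x) coordinates,
#'   0-based voxel units.
#' @param channel channel name.
#' @param intensity per-spot intensity (raw value at the nearest voxel).
#' @param cell per-spot assigned cell label; 0 = unassigned.
#' @return an object of class `spot_set`.
#' @export
spot_set <- function(coords, channel = "rna", intensity = NULL, cell = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3,
                   dimnames = list(NULL, c("z", "y", "x")))
  n <- nrow(coords)
  intensity <- if (is.null(intensity)) rep(NA_real_, n) else as.numeric(intensity)
  cell <- if (is.null(cell)) integer(n) else as.integer(cell)
  stopifnot(length(intensity) == n, length(cell) == n)
  structure(list(coords = coords, channel = channel,
                 intensity = intensity, cell = cell),
            class = "spot_set")
}

#' Number of spots in a spot set
#' @param x a `spot_set`.
#' @param ... unused.
#' @export
length.spot_set <- function(x) nrow(x$coords)

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set '%s'> %d spots (%d assigned)\n",
              x$channel, nrow(x$coords), sum(x$cell > 0)))
  invisible(x)
}

#' @export
as.data.frame.spot_set <- function(x, ...) {
  data.frame(z = x$coords[, 1], y = x$coords[, 2], x = x$coords[, 3],
             intensity = x$intensity, cell = x$cell)
}

#' Cell-nucleus pairing
#'
#' @param pairs integer vector of nucleus labels named by cell label;
#'   injective (no nucleus used twice).
#' @param cost achieved total pairing cost in micrometres.
#' @return an object of class `cell_pairing`.
#' @export
cell_pairing <- function(pairs, cost = 0) {
  pairs <- stats::setNames(as.integer(pairs), names(pairs))
  if (anyDuplicated(pairs)) stop("cell_pairing: mapping must be injective")
  structure(list(pairs = pairs, cost = as.numeric(cost)),
            class = "cell_pairing")
}

#' @export
print.cell_pairing <- function(x, ...) {
  cat(sprintf("<cell_pairing> %d pairs, total cost %.3f um\n",
              length(x$pairs), x$cost))
  invisible(x)
}

#' Relabel a label image to consecutive labels 1..n
#'
#' Never applied implicitly by the pipeline; labels are otherwise preserved
#' exactly as produced or read.
#'
#' @param labels integer label array (any dimensionality).
#' @return list with `labels` (relabelled array) and `map` (old labels,
#'   named by new).
#' @export
relabel_sequential <- function(labels) {
  old <- sort(unique(labels[labels > 0]))
  map <- stats::setNames(old, seq_along(old))
  out <- labels
  if (length(old)) {
    out[labels > 0] <- match(labels[labels > 0], old)
  }
  list(labels = out, map = map)
}
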