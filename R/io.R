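# TIFF and CSV readers/writers. All TIFFs are written as 16-bit multipage
# files (integer counts in [0, 65535]); label images round-trip exactly.
# The per-cell Z coordinate travels as a two-column CSV sidecar next to the
# label TIFF, since TIFF cannot carry a per-label scalar.

pages_to_array <- function(pages) {
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(length(pages), ny, nx))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (nrow(p) != ny || ncol(p) != nx) {
      stop("TIFF pages have inconsistent shapes")
    }
    arr[i, , ] <- p
  }
  arr
}

#' Read a 3D or multichannel TIFF stack
#'
#' Pages are interpreted as Z planes; for multichannel files the pages must
#' be channel-interleaved (z0c0, z0c1, ..., the ImageJ hyperstack default),
#' which is also how [write_stack()] writes them.
#'
#' @param path TIFF file.
#' @param spacing voxel size (dz, dy, dx) in micrometres.
#' @param n_channels number of channels interleaved in the file.
#' @param channel_names optional channel names (default ch0, ch1, ...).
#' @return list of [volume_image()] objects, one per channel.
#' @export
read_stack <- function(path, spacing, n_channels = 1, channel_names = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("cannot read TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  np <- length(pages)
  if (np %% n_channels != 0) {
    stop(sprintf("TIFF '%s' has %d pages, not divisible by n_channels = %d; pass the correct channel count",
                 path, np, n_channels))
  }
  nz <- np %/% n_channels
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_channels) - 1)
  out <- vector("list", n_channels)
  for (c in seq_len(n_channels)) {
    arr <- pages_to_array(pages[seq(c, np, by = n_channels)])
    out[[c]] <- volume_image(arr, spacing, channel_names[c])
  }
  names(out) <- channel_names
  out
}

#' Write channels as one interleaved multichannel 16-bit TIFF
#'
#' Intensities are rounded and clamped to [0, 65535]; the simulator already
#' produces integer counts so its stacks round-trip bit-exactly.
#'
#' @param channels a [volume_image()] or list of them (same grid).
#' @param path output TIFF path.
#' @export
write_stack <- function(channels, path) {
  if (inherits(channels, "volume_image")) channels <- list(channels)
  nz <- channels[[1]]$grid$shape[1]
  pages <- vector("list", nz * length(channels))
  k <- 1
  for (z in seq_len(nz)) {
    for (c in seq_along(channels)) {
      p <- channels[[c]]$data[z, , ]
      p <- pmin(pmax(round(p), 0), 65535)
      pages[[k]] <- p / 65535
      k <- k + 1
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read an integer label image (2D or 3D) from TIFF
#'
#' @param path TIFF path; must hold an unsigned-integer pixel type.
#' @return integer matrix (single page) or 3D array (z, y, x).
#' @export
read_labels <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
                    error = function(e) stop("cannot read TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  bits <- vapply(pages, function(p) {
    b <- attr(p, "bits.per.sample") %||% attr(p, "info")$bits.per.sample
    as.numeric(b %||% 16)
  }, numeric(1))
  if (any(bits > 16) ||
      any(vapply(pages, function(p) any(p %% 1 != 0), logical(1)))) {
    stop("read_labels: '", path, "' has a non-integer pixel type; labels must be integer TIFF")
  }
  if (length(pages) == 1) {
    matrix(as.integer(pages[[1]]), nrow(pages[[1]]), ncol(pages[[1]]))
  } else {
    arr <- pages_to_array(pages)
    storage.mode(arr) <- "integer"
    arr
  }
}

#' Write an integer label image (2D or 3D) as 16-bit TIFF
#'
#' @param labels integer matrix or 3D array; values in [0, 65535].
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  if (any(labels < 0) || any(labels %% 1 != 0) || max(labels) > 65535) {
    stop("write_labels: labels must be integers in [0, 65535]")
  }
  if (is.matrix(labels)) {
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16,
                    compression = "none")
  } else {
    pages <- lapply(seq_len(dim(labels)[1]), function(z) labels[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  }
  invisible(path)
}

#' @rdname read_apical_map
#' @param cells an [apical_cell_map()].
#' @param labels_path,cellz_path paths for the label TIFF and its Z sidecar.
#' @export
write_apical_map <- function(cells, labels_path, cellz_path) {
  write_labels(cells$labels2d, labels_path)
  write_csv_stable(data.frame(label = as.integer(names(cells$cell_z)),
                              z = as.numeric(cells$cell_z)), cellz_path)
  invisible(labels_path)
}

#' Read / write a 2.5D apical cell map (label TIFF + cell-Z CSV sidecar)
#'
#' Supports label images produced by external segmenters: any integer 2D
#' label TIFF plus a `label,z` CSV yields a valid map.
#'
#' @param spacing voxel size (dz, dy, dx) in micrometres.
#' @param nz number of Z planes of the parent stack.
#' @return an [apical_cell_map()].
#' @export
read_apical_map <- function(labels_path, cellz_path, spacing, nz) {
  labels2d <- read_labels(labels_path)
  if (!is.matrix(labels2d)) stop("read_apical_map: expected a 2D label image")
  cz <- utils::read.csv(cellz_path)
  grid <- voxel_grid(c(nz, dim(labels2d)), spacing)
  apical_cell_map(labels2d, stats::setNames(cz$z, cz$label), grid)
}

#' Write / read spots as CSV (columns z, y, x, intensity, cell)
#'
#' Coordinates are sub-voxel floats in 0-based voxel units.
#'
#' @param spots a [spot_set()].
#' @param path CSV path.
#' @export
write_spots <- function(spots, path) {
  write_csv_stable(as.data.frame(spots), path)
}

#' @rdname write_spots
#' @param channel channel name to attach on read.
#' @export
read_spots <- function(path, channel = "rna") {
  df <- utils::read.csv(path)
  spot_set(cbind(df$z, df$y, df$x), channel = channel,
           intensity = df$intensity, cell = df$cell)
}

#' Write the unified cell-by-cell table as CSV
#'
#' Column order is stable: identity, morphology, nucleus block, per-channel
#' spot counts, intensity blocks, class columns, cluster. Floats are written
#' at 6 significant digits; missing values (e.g. a cell without a nucleus)
#' become empty fields, never 0.
#'
#' @param table data.frame as produced by [build_cell_table()].
#' @param path CSV path.
#' @export
write_cell_table <- function(table, path) {
  write_csv_stable(table, path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, na.strings = "")
}
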