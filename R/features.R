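# Per-cell feature measurement and the unified cell-by-cell table.

# integer Z planes of the cytoplasmic prism of a cell
prism_planes <- function(cell_z, depth_um, dz, nz) {
  z_lo <- ceiling(cell_z - 1e-9)
  z_hi <- floor(cell_z + depth_um / dz + 1e-9)
  z_lo <- max(z_lo, 0); z_hi <- min(z_hi, nz - 1)
  if (z_lo > z_hi) integer(0) else z_lo:z_hi
}

#' Cytoplasmic intensity below the apical plane
#'
#' The measurement region of cell `c` is its 2D apical footprint extruded
#' downward from `cell_z[c]` over `depth` micrometres (clipped to the
#' volume) — consistent with the 2.5D scheme; there is no lateral shrinking
#' toward the basal side. Nuclear voxels are included unless
#' `exclude_nucleus` and a nuclei volume are given.
#'
#' @param channel a [volume_image()].
#' @param cells an [apical_cell_map()].
#' @param depth prism depth in micrometres (> 0).
#' @param nuclei optional [nuclei_labels()]; with `exclude_nucleus = TRUE`
#'   its voxels are removed from the prism.
#' @param exclude_nucleus logical flag (default FALSE).
#' @return data.frame: `cell`, `mean`, `sum`, `n_voxels`; empty regions give
#'   missing values.
#' @export
measure_cytoplasmic_intensity <- function(channel, cells, depth,
                                          nuclei = NULL,
                                          exclude_nucleus = FALSE) {
  stopifnot(depth > 0)
  labs <- cell_labels(cells)
  dz <- cells$grid$spacing[1]
  nz <- cells$grid$shape[1]
  res <- data.frame(cell = labs, mean = NA_real_, sum = NA_real_,
                    n_voxels = 0L)
  excl <- exclude_nucleus && !is.null(nuclei)
  for (i in seq_along(labs)) {
    l <- labs[i]
    px <- which(cells$labels2d == l)
    zs <- prism_planes(cells$cell_z[[as.character(l)]], depth, dz, nz)
    if (length(px) == 0 || length(zs) == 0) next
    tot <- 0; nvox <- 0
    for (z in zs) {
      plane <- channel$data[z + 1, , ]
      vals <- plane[px]
      if (excl) {
        nl <- nuclei$labels3d[z + 1, , ][px]
        vals <- vals[nl == 0]
      }
      tot <- tot + sum(vals)
      nvox <- nvox + length(vals)
    }
    if (nvox > 0) {
      res$mean[i] <- tot / nvox
      res$sum[i] <- tot
      res$n_voxels[i] <- nvox
    }
  }
  res
}

#' Nuclear intensity per segmented nucleus
#'
#' @param channel a [volume_image()].
#' @param nuclei a [nuclei_labels()] object.
#' @return data.frame: `nucleus`, `mean`, `sum`, `n_voxels`.
#' @export
measure_nuclear_intensity <- function(channel, nuclei) {
  idx <- which(nuclei$labels3d > 0)
  if (length(idx) == 0) {
    return(data.frame(nucleus = integer(0), mean = numeric(0),
                      sum = numeric(0), n_voxels = integer(0)))
  }
  lab <- nuclei$labels3d[idx]
  v <- channel$data[idx]
  s <- tapply(v, lab, sum)
  n <- tapply(v, lab, length)
  data.frame(nucleus = as.integer(names(s)), mean = as.numeric(s / n),
             sum = as.numeric(s), n_voxels = as.integer(n))
}

# boundary-step perimeter: edges between cell and non-cell pixels; an edge
# crossed along x has length dy and vice versa (anisotropic pixels)
cell_perimeter_um <- function(labels2d, label, spacing_yx) {
  m <- labels2d == label
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  core <- pad[2:(ny + 1), 2:(nx + 1)]
  steps_y <- sum(core & !pad[1:ny, 2:(nx + 1)]) +
    sum(core & !pad[3:(ny + 2), 2:(nx + 1)])     # edges crossed along y
  steps_x <- sum(core & !pad[2:(ny + 1), 1:nx]) +
    sum(core & !pad[2:(ny + 1), 3:(nx + 2)])     # edges crossed along x
  steps_y * spacing_yx[2] + steps_x * spacing_yx[1]
}

# neighbor pairs: direct 4-adjacency, plus cells meeting across a shared
# background (ridge) pixel within its 8-neighborhood
neighbor_pairs <- function(labels2d) {
  ny <- nrow(labels2d); nx <- ncol(labels2d)
  pairs <- matrix(integer(0), 0, 2)
  addp <- function(a, b) {
    ok <- a > 0 & b > 0 & a != b
    if (any(ok)) rbind(pairs, cbind(pmin(a[ok], b[ok]), pmax(a[ok], b[ok])))
    else pairs
  }
  pairs <- addp(labels2d[-ny, ], labels2d[-1, ])
  pairs <- addp(labels2d[, -nx], labels2d[, -1])
  bg <- which(labels2d == 0, arr.ind = TRUE)
  if (nrow(bg) > 0) {
    for (i in seq_len(nrow(bg))) {
      r <- bg[i, 1]; c <- bg[i, 2]
      nb <- labels2d[max(1, r - 1):min(ny, r + 1),
                     max(1, c - 1):min(nx, c + 1)]
      ls <- unique(nb[nb > 0])
      if (length(ls) >= 2) {
        cmb <- utils::combn(sort(ls), 2)
        pairs <- rbind(pairs, t(cmb))
      }
    }
  }
  unique(pairs)
}

#' Per-cell apical morphometrics
#'
#' Apical area (pixel count x dy*dx), boundary-step perimeter, circularity
#' 4*pi*A/P^2, centroid in micrometres (z from `cell_z`), neighbor count
#' (cells sharing a boundary edge, including across 1-pixel watershed
#' ridges), and nucleus volume/centroid when paired.
#'
#' @param cells an [apical_cell_map()].
#' @param nuclei optional [nuclei_labels()].
#' @param pairing optional [cell_pairing()].
#' @return data.frame with one row per cell.
#' @export
morphometrics <- function(cells, nuclei = NULL, pairing = NULL) {
  labs <- cell_labels(cells)
  sp <- cells$grid$spacing
  pxa <- sp[2] * sp[3]
  nb <- neighbor_pairs(cells$labels2d)
  res <- data.frame(cell = labs)
  res$centroid_x_um <- NA_real_; res$centroid_y_um <- NA_real_
  res$centroid_z_um <- NA_real_
  res$area_um2 <- NA_real_; res$perimeter_um <- NA_real_
  res$circularity <- NA_real_; res$n_neighbors <- 0L
  res$nucleus <- NA_integer_; res$nucleus_volume_um3 <- NA_real_
  res$nucleus_z_um <- NA_real_
  for (i in seq_along(labs)) {
    l <- labs[i]
    idx <- which(cells$labels2d == l, arr.ind = TRUE)
    a <- nrow(idx) * pxa
    p <- cell_perimeter_um(cells$labels2d, l, sp[2:3])
    res$area_um2[i] <- a
    res$perimeter_um[i] <- p
    res$circularity[i] <- 4 * pi * a / p^2
    res$centroid_y_um[i] <- mean(idx[, 1] - 1) * sp[2]
    res$centroid_x_um[i] <- mean(idx[, 2] - 1) * sp[3]
    res$centroid_z_um[i] <- cells$cell_z[[as.character(l)]] * sp[1]
    res$n_neighbors[i] <- sum(nb[, 1] == l | nb[, 2] == l)
    if (!is.null(pairing)) {
      nuc <- pairing$pairs[as.character(l)]
      if (!is.na(nuc)) {
        res$nucleus[i] <- as.integer(nuc)
        if (!is.null(nuclei)) {
          pr <- nuclei$props[nuclei$props$label == as.integer(nuc), ]
          if (nrow(pr) == 1) {
            res$nucleus_volume_um3[i] <- pr$volume_um3
            res$nucleus_z_um[i] <- pr$z * sp[1]
          }
        }
      }
    }
  }
  res
}

#' Pre-fill a binary classification from per-cell values
#'
#' Thresholds per-cell values (any channel intensity, count, ...) into
#' `positive` / `negative`. With `method = "otsu"` the threshold is computed
#' on a 256-bin histogram of the values; constant values are an error
#' instructing a manual threshold.
#'
#' @param values numeric vector named by cell label.
#' @param method `"otsu"` or `"threshold"`.
#' @param threshold numeric cutoff (required for `method = "threshold"`).
#' @param name class column name.
#' @return character vector (`"positive"`/`"negative"`) named by cell, with
#'   attributes `threshold` and `name`.
#' @export
prefill_classification <- function(values, method = c("otsu", "threshold"),
                                   threshold = NULL, name = "class") {
  method <- match.arg(method)
  if (method == "otsu") {
    if (length(values) < 2) stop("prefill_classification: need >= 2 cells for otsu")
    threshold <- otsu_threshold(values)
  } else if (is.null(threshold)) {
    stop("prefill_classification: method 'threshold' needs a threshold")
  }
  out <- ifelse(values > threshold, "positive", "negative")
  names(out) <- names(values)
  attr(out, "threshold") <- threshold
  attr(out, "name") <- name
  out
}

#' Assemble the unified cell-by-cell table
#'
#' One row per cell label, joining morphometrics, per-RNA-channel spot
#' counts from assignment results, cytoplasmic and nuclear intensity blocks,
#' and class columns. Missing blocks produce missing fields, never dropped
#' rows. Per channel, the unassigned spot count is recorded in the
#' `unassigned` attribute so that column sums + unassigned = total
#' detections.
#'
#' @param cells an [apical_cell_map()].
#' @param nuclei optional [nuclei_labels()].
#' @param pairing optional [cell_pairing()].
#' @param assignments named list of `assignment_result`s (names = channel).
#' @param cyto_intensity named list of data.frames from
#'   [measure_cytoplasmic_intensity()].
#' @param nuclear_intensity named list of data.frames from
#'   [measure_nuclear_intensity()] (joined through the pairing).
#' @param classes named list of class vectors from
#'   [prefill_classification()] (or any character vector named by cell).
#' @return data.frame of class `cell_table`.
#' @export
build_cell_table <- function(cells, nuclei = NULL, pairing = NULL,
                             assignments = list(), cyto_intensity = list(),
                             nuclear_intensity = list(), classes = list()) {
  labs <- cell_labels(cells)
  tab <- morphometrics(cells, nuclei, pairing)
  unassigned <- integer(0)
  for (ch in names(assignments)) {
    cl <- assignments[[ch]]$spots$cell
    extra <- setdiff(unique(cl[cl > 0]), labs)
    if (length(extra)) {
      stop("build_cell_table: assignment '", ch,
           "' references labels absent from the cell map: ",
           paste(extra, collapse = ", "))
    }
    cnt <- table(factor(cl[cl > 0], levels = labs))
    tab[[paste0("count_", ch)]] <- as.integer(cnt)
    unassigned[ch] <- sum(cl == 0)
  }
  for (ch in names(cyto_intensity)) {
    blk <- cyto_intensity[[ch]]
    extra <- setdiff(blk$cell, labs)
    if (length(extra)) {
      stop("build_cell_table: intensity block '", ch,
           "' references labels absent from the cell map: ",
           paste(extra, collapse = ", "))
    }
    tab[[paste0("cyto_mean_", ch)]] <- blk$mean[match(labs, blk$cell)]
    tab[[paste0("cyto_sum_", ch)]] <- blk$sum[match(labs, blk$cell)]
  }
  for (ch in names(nuclear_intensity)) {
    blk <- nuclear_intensity[[ch]]
    v <- rep(NA_real_, length(labs))
    if (!is.null(pairing)) {
      nuc <- pairing$pairs[as.character(labs)]
      v <- blk$mean[match(as.integer(nuc), blk$nucleus)]
    }
    tab[[paste0("nuc_mean_", ch)]] <- v
  }
  for (nm in names(classes)) {
    cl <- classes[[nm]]
    tab[[paste0("class_", nm)]] <- unname(cl[as.character(labs)])
  }
  tab$cluster <- NA_integer_
  attr(tab, "unassigned") <- unassigned
  class(tab) <- c("cell_table", class(tab))
  tab
}

#' Hierarchical clustering of cells from the table
#'
#' Selected feature columns are z-score standardised per column and
#' clustered agglomeratively (Euclidean distance; `ward` uses Ward's D2).
#' Rows with missing feature values are excluded from clustering and keep an
#' empty cluster field; their labels are reported in the `excluded`
#' attribute.
#'
#' @param table a cell table from [build_cell_table()].
#' @param features character vector of feature column names.
#' @param k number of clusters (1 <= k <= usable rows).
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @return the table with its `cluster` column filled (ids 1..k).
#' @export
cluster_cells <- function(table, features, k,
                          linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(k >= 1, all(features %in% names(table)))
  x <- as.matrix(table[, features, drop = FALSE])
  usable <- stats::complete.cases(x)
  if (k > sum(usable)) {
    stop("cluster_cells: k = ", k, " exceeds the ", sum(usable),
         " usable (complete) rows")
  }
  xs <- scale(x[usable, , drop = FALSE])
  xs[, apply(xs, 2, function(c) any(!is.finite(c)))] <- 0  # constant columns
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[linkage]
  hc <- stats::hclust(stats::dist(xs), method = method)
  ids <- stats::cutree(hc, k = k)
  table$cluster <- NA_integer_
  table$cluster[usable] <- as.integer(ids)
  attr(table, "excluded") <- table$cell[!usable]
  table
}
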