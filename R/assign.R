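# Assignment of 3D spots to cells that are defined only by their 2D apical
# footprints. Five strategies:
#   projection      — Z-projection of the spot onto the 2D labels
#   nearest_nucleus — closest nucleus (surface or centroid), via its paired cell
#   mixed           — projection for shallow spots, nearest nucleus below depth_cut
#   hull            — containment in a per-cell 3D convex hull (apical polygon
#                     at cell_z + paired nucleus extrema)
#   iterative       — unassigned spots adopt the strict-majority cell of their
#                     k nearest assigned neighbors, repeated to fixation
# All distances are physical (um) because of Z anisotropy.

new_assignment <- function(spots, strategy) {
  structure(list(spots = spots, strategy = strategy,
                 unassigned_count = sum(spots$cell == 0)),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("<assignment_result '%s'> %d spots, %d unassigned\n",
              x$strategy, length(x$spots), x$unassigned_count))
  invisible(x)
}

#' Assign spots by Z-projection onto the apical labels
#'
#' Each spot takes the 2D label at its rounded (y, x) position, at any Z;
#' spots over background (junction ridges) stay unassigned.
#'
#' @param spots a [spot_set()].
#' @param cells an [apical_cell_map()].
#' @return an `assignment_result`.
#' @export
assign_projection <- function(spots, cells) {
  out <- spots
  n <- length(spots)
  if (n > 0) {
    ny <- nrow(cells$labels2d); nx <- ncol(cells$labels2d)
    yy <- pmin(pmax(round(spots$coords[, 2]), 0), ny - 1) + 1
    xx <- pmin(pmax(round(spots$coords[, 3]), 0), nx - 1) + 1
    out$cell <- as.integer(cells$labels2d[cbind(yy, xx)])
  }
  new_assignment(out, "projection")
}

# boundary voxels of all nuclei (face connectivity), as (z,y,x) 0-based + label
nucleus_surface_voxels <- function(nuclei) {
  lab <- nuclei$labels3d
  d <- dim(lab)
  interior <- array(TRUE, d)
  same <- function(a, b) a == b
  # a voxel is interior if all 6 face neighbors share its label
  shift_cmp <- function(ax, s) {
    idx_a <- lapply(d, seq_len)
    idx_b <- idx_a
    if (s > 0) { idx_a[[ax]] <- 1:(d[ax] - 1); idx_b[[ax]] <- 2:d[ax] }
    else { idx_a[[ax]] <- 2:d[ax]; idx_b[[ax]] <- 1:(d[ax] - 1) }
    eq <- array(FALSE, d)
    eq[idx_a[[1]], idx_a[[2]], idx_a[[3]]] <-
      do.call(`[`, c(list(lab), idx_a)) == do.call(`[`, c(list(lab), idx_b))
    eq
  }
  for (ax in 1:3) {
    if (d[ax] > 1) {
      interior <- interior & shift_cmp(ax, 1) & shift_cmp(ax, -1)
    }
  }
  surf <- which(lab > 0 & !interior)
  z <- (surf - 1) %% d[1]
  y <- ((surf - 1) %/% d[1]) %% d[2]
  x <- (surf - 1) %/% (d[1] * d[2])
  list(coords = cbind(z, y, x), label = as.integer(lab[surf]))
}

#' Assign spots to the cell of their closest nucleus
#'
#' A spot whose voxel lies inside a nucleus has distance 0 to it; otherwise
#' the distance is to the nearest labeled voxel (`nucleus_distance =
#' "surface"`, the default, so large nuclei do not lose nearby spots) or to
#' the nucleus centroid. Distances are anisotropy-scaled micrometres; ties
#' go to the lower nucleus label. The nucleus maps to its paired cell;
#' nuclei without a paired cell leave the spot unassigned.
#'
#' @param spots a [spot_set()].
#' @param nuclei a [nuclei_labels()] object.
#' @param pairing a [cell_pairing()] consistent with `nuclei`.
#' @param nucleus_distance `"surface"` or `"centroid"`.
#' @return an `assignment_result`.
#' @export
assign_nearest_nucleus <- function(spots, nuclei, pairing,
                                   nucleus_distance = c("surface", "centroid")) {
  nucleus_distance <- match.arg(nucleus_distance)
  out <- spots
  n <- length(spots)
  if (n == 0 || nrow(nuclei$props) == 0) {
    if (n > 0) out$cell <- integer(n)
    return(new_assignment(out, "nearest_nucleus"))
  }
  sp <- nuclei$grid$spacing
  nuc_lab <- integer(n)
  # inside a nucleus -> that nucleus, distance 0
  vox <- round(spots$coords)
  d <- dim(nuclei$labels3d)
  vox[, 1] <- pmin(pmax(vox[, 1], 0), d[1] - 1)
  vox[, 2] <- pmin(pmax(vox[, 2], 0), d[2] - 1)
  vox[, 3] <- pmin(pmax(vox[, 3], 0), d[3] - 1)
  inside <- nuclei$labels3d[vox + 1]
  nuc_lab[inside > 0] <- inside[inside > 0]
  todo <- which(nuc_lab == 0)
  if (length(todo)) {
    if (nucleus_distance == "surface") {
      surf <- nucleus_surface_voxels(nuclei)
      ref <- sweep(surf$coords, 2, sp, `*`)
      rl <- surf$label
    } else {
      ref <- cbind(nuclei$props$z * sp[1], nuclei$props$y * sp[2],
                   nuclei$props$x * sp[3])
      rl <- nuclei$props$label
    }
    q <- sweep(spots$coords[todo, , drop = FALSE], 2, sp, `*`)
    nn <- nearest_point_label_cpp(q, ref, as.integer(rl))
    nuc_lab[todo] <- nn$label
  }
  # nucleus -> paired cell
  n2c <- stats::setNames(as.integer(names(pairing$pairs)),
                         as.character(pairing$pairs))
  cellv <- n2c[as.character(nuc_lab)]
  cellv[is.na(cellv)] <- 0L
  out$cell <- as.integer(cellv)
  new_assignment(out, "nearest_nucleus")
}

#' Depth-mixed assignment (projection above, nearest nucleus below)
#'
#' A spot's depth is `(z - cell_z[c*]) * dz`, with `c*` its projection cell
#' (infinite when the projection lands on background). Spots at depth up to
#' `depth_cut` keep the projection assignment; deeper spots take the
#' nearest-nucleus one.
#'
#' @param spots a [spot_set()].
#' @param cells an [apical_cell_map()].
#' @param nuclei,pairing see [assign_nearest_nucleus()].
#' @param depth_cut depth cutoff in micrometres (>= 0).
#' @param nucleus_distance passed to [assign_nearest_nucleus()].
#' @return an `assignment_result`.
#' @export
assign_mixed <- function(spots, cells, nuclei, pairing, depth_cut = 5,
                         nucleus_distance = "surface") {
  stopifnot(depth_cut >= 0)
  proj <- assign_projection(spots, cells)
  if (length(spots) == 0) return(new_assignment(spots, "mixed"))
  nuc <- assign_nearest_nucleus(spots, nuclei, pairing, nucleus_distance)
  dz <- cells$grid$spacing[1]
  pc <- proj$spots$cell
  depth <- rep(Inf, length(spots))
  hit <- pc > 0
  depth[hit] <- (spots$coords[hit, 1] -
                   cells$cell_z[as.character(pc[hit])]) * dz
  out <- spots
  out$cell <- ifelse(depth <= depth_cut, pc, nuc$spots$cell)
  out$cell <- as.integer(out$cell)
  new_assignment(out, "mixed")
}

# supporting half-spaces of the convex hull of 3D points, by enumeration of
# support triples; returns unit outward normals N and offsets d (inside:
# N %*% p <= d, up to pad). NULL when the points are degenerate (coplanar).
hull_halfspaces <- function(pts, tol = 1e-9) {
  pts <- unique(round(pts, 9))
  if (nrow(pts) < 4) return(NULL)
  tri <- utils::combn(nrow(pts), 3)
  p1 <- pts[tri[1, ], , drop = FALSE]
  p2 <- pts[tri[2, ], , drop = FALSE]
  p3 <- pts[tri[3, ], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(nrm^2))
  ok <- len > tol
  if (!any(ok)) return(NULL)
  nrm <- nrm[ok, , drop = FALSE] / len[ok]
  d0 <- rowSums(nrm * p1[ok, , drop = FALSE])
  # signed margins of all points under each candidate plane
  marg <- nrm %*% t(pts) - d0            # planes x points
  scale <- max(abs(pts)) + 1
  eps <- 1e-7 * scale
  if (all(abs(marg[1, ]) <= eps)) return(NULL)   # coplanar support
  above <- rowSums(marg > eps)
  below <- rowSums(marg < -eps)
  keepA <- above == 0                     # all points on or below: outward = nrm
  keepB <- below == 0                     # all on or above: outward = -nrm
  N <- rbind(nrm[keepA, , drop = FALSE], -nrm[keepB, , drop = FALSE])
  d <- c(d0[keepA], -d0[keepB])
  if (nrow(N) == 0) return(NULL)
  dedup <- !duplicated(round(cbind(N, d), 6))
  list(normals = N[dedup, , drop = FALSE], offsets = d[dedup])
}

#' Per-spot, per-cell hull containment decisions
#'
#' The machinery behind [assign_hull()], exposed so containment can be
#' audited pair by pair: a spot is inside a cell's padded hull when its
#' signed margin under every supporting half-space is at most `pad`.
#'
#' @inheritParams assign_hull
#' @return list: `inside` (spots x cells logical matrix), `labels` (column
#'   cell labels), `centroid_distance` (spots x cells, um, distance to the
#'   hull support centroid), `degenerate` (labels whose support was
#'   coplanar; their column is all-FALSE).
#' @export
hull_containment <- function(spots, cells, nuclei, pairing, pad = 0.5) {
  labs <- cell_labels(cells)
  n <- length(spots)
  sp <- cells$grid$spacing
  pts_um <- sweep(spots$coords, 2, sp, `*`)
  inside <- matrix(FALSE, n, length(labs))
  centd <- matrix(Inf, n, length(labs))
  degenerate <- integer(0)
  for (i in seq_along(labs)) {
    sup <- hull_support_points(cells, nuclei, pairing, labs[i])
    hs <- if (is.null(sup)) NULL else hull_halfspaces(sup)
    if (is.null(hs)) {
      degenerate <- c(degenerate, labs[i])
      next
    }
    marg <- hs$normals %*% t(pts_um) - hs$offsets   # planes x spots
    inside[, i] <- apply(marg, 2, max) <= pad
    cen <- colMeans(sup)
    centd[, i] <- sqrt(colSums((t(pts_um) - cen)^2))
  }
  if (length(degenerate)) {
    warning("hull_containment: degenerate hull for cell(s) ",
            paste(degenerate, collapse = ", "), "; they assign nothing")
  }
  list(inside = inside, labels = labs, centroid_distance = centd,
       degenerate = degenerate)
}

#' Hull support points of one cell (micrometres)
#'
#' Apical 2D convex-polygon vertices of the footprint boundary placed at
#' `cell_z`, plus the paired nucleus's 6 axis-extreme voxels — the minimal
#' volume construction available to the 2.5D pipeline.
#'
#' @param cells an [apical_cell_map()].
#' @param nuclei a [nuclei_labels()] object.
#' @param pairing a [cell_pairing()].
#' @param label cell label.
#' @return numeric matrix of (z, y, x) support points in um, or NULL for an
#'   absent label.
#' @export
hull_support_points <- function(cells, nuclei, pairing, label) {
  sp <- cells$grid$spacing
  idx <- which(cells$labels2d == label, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  v2 <- idx[grDevices::chull(idx[, 1], idx[, 2]), , drop = FALSE]
  apical <- cbind(cells$cell_z[[as.character(label)]] * sp[1],
                  (v2[, 1] - 1) * sp[2], (v2[, 2] - 1) * sp[3])
  nuc <- pairing$pairs[as.character(label)]
  nucpts <- NULL
  if (!is.na(nuc)) {
    w <- which(nuclei$labels3d == as.integer(nuc))
    if (length(w)) {
      d <- dim(nuclei$labels3d)
      z <- (w - 1) %% d[1]
      y <- ((w - 1) %/% d[1]) %% d[2]
      x <- (w - 1) %/% (d[1] * d[2])
      ext <- c(which.min(z), which.max(z), which.min(y), which.max(y),
               which.min(x), which.max(x))
      nucpts <- cbind(z[ext] * sp[1], y[ext] * sp[2], x[ext] * sp[3])
    }
  }
  rbind(apical, nucpts)
}

#' Assign spots by per-cell 3D convex-hull containment
#'
#' Each cell's volume is approximated by the convex hull of its apical
#' boundary polygon placed at `cell_z` plus the six axis-extreme voxels of
#' its paired nucleus (the minimal construction from the data the 2.5D
#' pipeline has). The hull is dilated by `pad` (each supporting half-space
#' offset outward, absorbing voxelisation). A spot inside exactly one hull
#' is assigned to it; inside several, to the cell with the nearest hull
#' centroid; inside none, unassigned. Cells with degenerate (coplanar)
#' support — e.g. no paired nucleus — assign nothing, with a warning.
#'
#' @param spots a [spot_set()].
#' @param cells an [apical_cell_map()].
#' @param nuclei,pairing see [assign_nearest_nucleus()].
#' @param pad hull dilation in micrometres (default 0.5).
#' @return an `assignment_result`.
#' @export
assign_hull <- function(spots, cells, nuclei, pairing, pad = 0.5) {
  out <- spots
  n <- length(spots)
  labs <- cell_labels(cells)
  if (n == 0 || length(labs) == 0) {
    return(new_assignment(out, "hull"))
  }
  cm <- hull_containment(spots, cells, nuclei, pairing, pad)
  inside <- cm$inside
  centd <- cm$centroid_distance
  cellv <- integer(n)
  hits <- rowSums(inside)
  one <- hits == 1
  if (any(one)) {
    cellv[one] <- labs[apply(inside[one, , drop = FALSE], 1, which.max)]
  }
  multi <- hits > 1
  if (any(multi)) {
    for (s in which(multi)) {
      cand <- which(inside[s, ])
      cellv[s] <- labs[cand[which.min(centd[s, cand])]]
    }
  }
  out$cell <- cellv
  new_assignment(out, "hull")
}

#' Iterative assignment from k-nearest assigned neighbors
#'
#' Starting from any base assignment, each unassigned spot repeatedly takes
#' the strict-majority cell among its `k` nearest assigned spots (um
#' distance) until no spot changes or `max_iter` rounds. Assigned spots are
#' frozen, so the unassigned count is non-increasing and the procedure
#' terminates.
#'
#' @param spots a [spot_set()] (coordinates used for distances).
#' @param initial an `assignment_result` providing the starting labels.
#' @param k neighborhood size (>= 1).
#' @param max_iter maximum number of passes.
#' @param spacing voxel size (dz, dy, dx) in micrometres, so neighbor
#'   distances are physical.
#' @return an `assignment_result`.
#' @export
assign_iterative <- function(spots, initial, k = 4, max_iter = 10,
                             spacing = c(1, 1, 1)) {
  stopifnot(k >= 1)
  cellv <- initial$spots$cell
  n <- length(spots)
  if (n == 0 || all(cellv == 0)) {
    out <- spots; if (n > 0) out$cell <- cellv
    return(new_assignment(out, "iterative"))
  }
  sp_um <- sweep(spots$coords, 2, spacing, `*`)
  for (iter in seq_len(max_iter)) {
    un <- which(cellv == 0)
    as_ <- which(cellv > 0)
    if (length(un) == 0 || length(as_) == 0) break
    changed <- FALSE
    newv <- cellv
    d2 <- outer(rowSums(sp_um[un, , drop = FALSE]^2),
                rowSums(sp_um[as_, , drop = FALSE]^2), "+") -
      2 * sp_um[un, , drop = FALSE] %*% t(sp_um[as_, , drop = FALSE])
    for (ii in seq_along(un)) {
      kk <- min(k, length(as_))
      nb <- as_[order(d2[ii, ])[seq_len(kk)]]
      tab <- sort(table(cellv[nb]), decreasing = TRUE)
      if (length(tab) == 1 || tab[1] > tab[2]) {   # strict majority
        newv[un[ii]] <- as.integer(names(tab)[1])
        changed <- TRUE
      }
    }
    cellv <- newv
    if (!changed) break
  }
  out <- spots
  out$cell <- cellv
  new_assignment(out, "iterative")
}

#' Compare assignment strategies
#'
#' @param results list of `assignment_result`s over the same spot set.
#' @param truth optional [spot_set()] with true cell labels for accuracy.
#' @return list with `agreement` (pairwise fraction of equal assignments
#'   over spots assigned by both strategies), `unassigned_fraction`, and
#'   `accuracy` when truth is given (fraction of truth-labeled spots
#'   assigned to the correct cell; unassigned counts as incorrect).
#' @export
compare_strategies <- function(results, truth = NULL) {
  ns <- vapply(results, function(r) length(r$spots), numeric(1))
  if (length(unique(ns)) != 1) {
    stop("compare_strategies: results cover different spot counts")
  }
  nms <- vapply(results, function(r) r$strategy, character(1))
  k <- length(results)
  agree <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    a <- results[[i]]$spots$cell; b <- results[[j]]$spots$cell
    both <- a > 0 & b > 0
    agree[i, j] <- if (any(both)) mean(a[both] == b[both]) else NA_real_
  }
  unfrac <- vapply(results, function(r)
    if (length(r$spots) > 0) r$unassigned_count / length(r$spots) else 0,
    numeric(1))
  names(unfrac) <- nms
  out <- list(agreement = agree, unassigned_fraction = unfrac)
  if (!is.null(truth)) {
    tc <- truth$cell
    out$accuracy <- vapply(results, function(r) {
      ok <- tc > 0
      if (!any(ok)) return(NA_real_)
      mean(r$spots$cell[ok] == tc[ok])
    }, numeric(1))
    names(out$accuracy) <- nms
  }
  out
}

#' Comparison list as a flat data.frame (for CSV export)
#' @param cmp result of [compare_strategies()].
#' @return data.frame with one row per strategy pair plus per-strategy rows.
#' @export
comparison_table <- function(cmp) {
  nms <- rownames(cmp$agreement)
  rows <- expand.grid(strategy_a = nms, strategy_b = nms,
                      stringsAsFactors = FALSE)
  rows$agreement <- as.vector(cmp$agreement)
  rows$unassigned_fraction_a <- cmp$unassigned_fraction[rows$strategy_a]
  if (!is.null(cmp$accuracy)) rows$accuracy_a <- cmp$accuracy[rows$strategy_a]
  rows
}
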