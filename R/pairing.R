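# Nucleus-to-cell pairing by minimum-cost bipartite matching.
#
# The solver is the classic O(n^3) potential-based Hungarian algorithm on a
# square cost matrix; forbidden pairs (cost > max_dist) and dummy padding
# carry a large constant, which yields the maximum-cardinality matching over
# admissible pairs with minimal total cost, without dummy entries being
# visible to callers.

BIG_COST <- 1e9

# Hungarian algorithm with potentials; cost is an n x m matrix (n <= m
# after internal transpose). Returns, for each row, the assigned column.
hungarian_lsap <- function(cost) {
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) {
    cost <- t(cost)
    transposed <- TRUE
  }
  n <- nrow(cost); m <- ncol(cost)
  INF <- Inf
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)        # p[j] = row matched to column j (0 = free)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1) break
    }
  }
  assign_row <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0) assign_row[p[j]] <- j
  if (transposed) {
    inv <- integer(m)
    inv[] <- 0L
    for (i in seq_len(n)) if (assign_row[i] > 0) inv[assign_row[i]] <- i
    # original orientation: rows were columns
    return(inv)
  }
  assign_row
}

#' Pair segmented nuclei to apical cell footprints
#'
#' Cost of a (cell, nucleus) pair is the Euclidean distance in micrometres
#' between the cell's apical anchor (its 2D centroid placed at `cell_z`) and
#' the nucleus centroid, with the lateral (y, x) terms at full weight and
#' the Z term down-weighted by `wz` — nuclei sit basally at variable depth
#' below their apex, so depth differences are less informative than lateral
#' offset. Pairs with cost above `max_dist` are forbidden; excess cells or
#' nuclei stay unmatched. Among equal-cost optima, lower (cell, nucleus)
#' label pairs are preferred via an infinitesimal perturbation.
#'
#' @param cells an [apical_cell_map()].
#' @param nuclei a [nuclei_labels()] object.
#' @param max_dist maximum admissible pair cost in micrometres (> 0).
#' @param wz weight of the Z term inside the distance (default 0.25).
#' @return a [cell_pairing()]: injective cell -> nucleus map and total cost.
#' @export
pair_nuclei_to_cells <- function(cells, nuclei, max_dist, wz = 0.25) {
  stopifnot(inherits(cells, "apical_cell_map"), inherits(nuclei, "nuclei_labels"))
  if (!is.numeric(max_dist) || max_dist <= 0) {
    stop("pair_nuclei_to_cells: max_dist must be > 0")
  }
  labs <- cell_labels(cells)
  np <- nuclei$props
  if (length(labs) == 0 || nrow(np) == 0) {
    return(cell_pairing(stats::setNames(integer(0), character(0)), 0))
  }
  sp <- cells$grid$spacing
  anchors <- t(vapply(labs, function(l) {
    idx <- which(cells$labels2d == l, arr.ind = TRUE)
    c(z = cells$cell_z[[as.character(l)]] * sp[1],
      y = mean(idx[, 1] - 1) * sp[2],
      x = mean(idx[, 2] - 1) * sp[3])
  }, numeric(3)))
  ncent <- cbind(np$z * sp[1], np$y * sp[2], np$x * sp[3])
  cost <- matrix(0, length(labs), nrow(np))
  for (i in seq_along(labs)) {
    dz <- anchors[i, 1] - ncent[, 1]
    dy <- anchors[i, 2] - ncent[, 2]
    dx <- anchors[i, 3] - ncent[, 3]
    cost[i, ] <- sqrt(dy^2 + dx^2 + (wz * dz)^2)
  }
  admissible <- cost <= max_dist
  work <- cost
  work[!admissible] <- BIG_COST
  # deterministic lexicographic preference among exact ties
  eps <- 1e-9 * (max_dist / (length(work) + 1))
  pert <- outer(seq_along(labs), seq_len(nrow(np)),
                function(i, j) (i - 1) * (nrow(np) + 1) + j)
  work <- work + eps * pert
  n <- max(dim(work))
  sq <- matrix(BIG_COST, n, n)
  sq[seq_len(nrow(work)), seq_len(ncol(work))] <- work
  asg <- hungarian_lsap(sq)
  pairs <- integer(0); nms <- character(0); total <- 0
  for (i in seq_along(labs)) {
    j <- asg[i]
    if (j >= 1 && j <= nrow(np) && admissible[i, j]) {
      pairs <- c(pairs, np$label[j])
      nms <- c(nms, as.character(labs[i]))
      total <- total + cost[i, j]
    }
  }
  cell_pairing(stats::setNames(pairs, nms), total)
}

#' Export a pairing as a two-column data.frame
#' @param pairing a [cell_pairing()].
#' @return data.frame with columns `cell`, `nucleus`.
#' @export
pairing_table <- function(pairing) {
  data.frame(cell = as.integer(names(pairing$pairs)),
             nucleus = as.integer(pairing$pairs))
}
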