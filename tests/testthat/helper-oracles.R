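# Independent oracles, deliberately written with different algorithms than
# the implementation they check.

# Exhaustive maximum-cardinality minimum-cost partial matching respecting
# forbidden pairs, by dynamic programming over column subsets. Independent
# of the package's Hungarian solver.
brute_force_matching <- function(cost, admissible) {
  nr <- nrow(cost); nc <- ncol(cost)
  nmask <- bitwShiftL(1L, nc)
  best_card <- matrix(-1L, nr + 1, nmask)
  best_cost <- matrix(Inf, nr + 1, nmask)
  best_card[1, 1] <- 0L
  best_cost[1, 1] <- 0
  for (i in seq_len(nr)) {
    for (mask in 0:(nmask - 1)) {
      c0 <- best_card[i, mask + 1]
      if (c0 < 0) next
      w0 <- best_cost[i, mask + 1]
      # skip row i
      if (c0 > best_card[i + 1, mask + 1] ||
          (c0 == best_card[i + 1, mask + 1] && w0 < best_cost[i + 1, mask + 1])) {
        best_card[i + 1, mask + 1] <- c0
        best_cost[i + 1, mask + 1] <- w0
      }
      # assign row i to an admissible free column
      for (j in seq_len(nc)) {
        bit <- bitwShiftL(1L, j - 1)
        if (bitwAnd(mask, bit) != 0 || !admissible[i, j]) next
        m2 <- bitwOr(mask, bit)
        c2 <- c0 + 1L
        w2 <- w0 + cost[i, j]
        if (c2 > best_card[i + 1, m2 + 1] ||
            (c2 == best_card[i + 1, m2 + 1] && w2 < best_cost[i + 1, m2 + 1])) {
          best_card[i + 1, m2 + 1] <- c2
          best_cost[i + 1, m2 + 1] <- w2
        }
      }
    }
  }
  cmax <- max(best_card[nr + 1, ])
  list(cardinality = cmax,
       cost = min(best_cost[nr + 1, best_card[nr + 1, ] == cmax]))
}

# Scalar brute-force half-space containment check: enumerates all support
# triples, keeps planes with every support point on one side, and tests the
# query's margin against each supporting plane.
oracle_point_in_hull <- function(support, query, pad) {
  n <- nrow(support)
  if (n < 4) return(FALSE)
  scale <- max(abs(support)) + 1
  eps <- 1e-7 * scale
  found_plane <- FALSE
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    u <- support[j, ] - support[i, ]
    v <- support[k, ] - support[i, ]
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    len <- sqrt(sum(nrm^2))
    if (len <= 1e-9) next
    nrm <- nrm / len
    d <- sum(nrm * support[i, ])
    sides <- support %*% nrm - d
    if (all(sides <= eps)) {
      found_plane <- TRUE
      if (sum(nrm * query) - d > pad) return(FALSE)
    }
    if (all(sides >= -eps)) {
      found_plane <- TRUE
      if (d - sum(nrm * query) > pad) return(FALSE)
    }
  }
  found_plane
}

# Geometric helpers: a toy map with one square cell per anchor, and one
# single-voxel nucleus per point.
toy_instance <- function(cell_yx, nuc_zyx, nz = 30, ny = 64, nx = 64,
                         spacing = c(1, 1, 1), cell_z = 2) {
  lab <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(cell_yx))) {
    y <- cell_yx[i, 1]; x <- cell_yx[i, 2]
    lab[(y - 1):(y + 1) + 1, (x - 1):(x + 1) + 1] <- i
  }
  grid <- voxel_grid(c(nz, ny, nx), spacing)
  cells <- apical_cell_map(lab, stats::setNames(rep(cell_z, nrow(cell_yx)),
                                                seq_len(nrow(cell_yx))), grid)
  nl <- array(0L, grid$shape)
  for (i in seq_len(nrow(nuc_zyx))) {
    nl[nuc_zyx[i, 1] + 1, nuc_zyx[i, 2] + 1, nuc_zyx[i, 3] + 1] <- i
  }
  list(cells = cells, nuclei = nuclei_labels(nl, grid))
}

pairing_cost_matrix <- function(cells, nuclei, wz = 0.25) {
  labs <- cell_labels(cells)
  sp <- cells$grid$spacing
  anchors <- t(vapply(labs, function(l) {
    idx <- which(cells$labels2d == l, arr.ind = TRUE)
    c(cells$cell_z[[as.character(l)]] * sp[1],
      mean(idx[, 1] - 1) * sp[2], mean(idx[, 2] - 1) * sp[3])
  }, numeric(3)))
  np <- nuclei$props
  cost <- matrix(0, length(labs), nrow(np))
  for (i in seq_along(labs)) {
    cost[i, ] <- sqrt((anchors[i, 2] - np$y * sp[2])^2 +
                        (anchors[i, 3] - np$x * sp[3])^2 +
                        (wz * (anchors[i, 1] - np$z * sp[1]))^2)
  }
  cost
}

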