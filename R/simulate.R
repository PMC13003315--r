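# Synthetic epithelium generator with complete ground truth.
#
# The tissue model: a Voronoi tessellation of seed points (one Lloyd
# relaxation step) defines polygonal cells; the apical surface is a cosine
# dome of configurable peak height (0 = flat); junctions fluoresce as a
# Gaussian tube along the Voronoi edges at the surface; each cell carries
# one ellipsoidal nucleus offset basally below its apex; cell bodies are
# columnar along the local surface normal, so on a curved sheet deep
# content is laterally displaced relative to the apical footprint; per cell
# and RNA channel, a Poisson count of diffraction-limited spots is placed
# uniformly in the cell's column between the apical surface and the nucleus
# bottom + 2 um; channels get background, optional shot (Poisson) noise and
# Gaussian read noise, and are quantised to integer camera counts.

#' Parameters of the synthetic tissue
#'
#' Defaults are desk-scale: a (40, 256, 256) voxel stack at (1.0, 0.2, 0.2)
#' um spacing (51 x 51 um field) with 50 cells; spot amplitude 50 over
#' Gaussian read noise sd 10 gives SNR 5.
#'
#' @param shape stack shape (nz, ny, nx).
#' @param spacing voxel size (dz, dy, dx) in um.
#' @param n_cells number of cells (>= 1).
#' @param curvature peak height of the apical dome in um (0 = flat).
#' @param junction_thickness Gaussian tube sigma of the junction signal, um.
#' @param junction_intensity,nucleus_intensity,spot_amplitude,background
#'   intensity levels (camera counts).
#' @param nucleus_radii nucleus `c(axial, lateral)` radii in um.
#' @param nucleus_depth nucleus centre depth below the apex, um.
#' @param nucleus_jitter lateral nucleus jitter as a fraction of the cell
#'   inradius (draw is uniform up to this fraction).
#' @param n_rna_channels number of smFISH channels.
#' @param lambda_high,lambda_low Poisson means of the two cell populations.
#' @param frac_high fraction of high-expressing cells.
#' @param spot_sigma spot PSF `c(axial, lateral)` sigma in um.
#' @param spot_margin minimal lateral distance of spots from junctions, um
#'   (transcripts are cytoplasmic; the membrane region is excluded).
#' @param gaussian_noise_sd read noise sd; `poisson_noise` adds shot noise.
#' @param ihc_high,ihc_low optional cytoplasmic reporter levels tied to the
#'   high/low class (NULL = no IHC channel).
#' @param n_speckles undersized bright speckles added to the nuclear channel
#'   (with their own truth labels), for testing size filters.
#' @param seed RNG seed.
#' @return a `tissue_params` list.
#' @export
tissue_params <- function(shape = c(40, 256, 256),
                          spacing = c(1.0, 0.2, 0.2),
                          n_cells = 50,
                          curvature = 0,
                          junction_thickness = 0.3,
                          junction_intensity = 120,
                          nucleus_intensity = 100,
                          spot_amplitude = 50,
                          background = 10,
                          nucleus_radii = c(1.5, 2.0),
                          nucleus_depth = 5,
                          nucleus_jitter = 0.2,
                          n_rna_channels = 1,
                          lambda_high = 30,
                          lambda_low = 3,
                          frac_high = 0.5,
                          spot_sigma = c(1.0, 0.3),
                          spot_margin = 0.5,
                          gaussian_noise_sd = 10,
                          poisson_noise = TRUE,
                          ihc_high = NULL,
                          ihc_low = NULL,
                          n_speckles = 0,
                          seed = 1) {
  p <- as.list(environment())
  stopifnot(p$n_cells >= 1, p$frac_high >= 0, p$frac_high <= 1,
            all(c(p$junction_intensity, p$nucleus_intensity,
                  p$spot_amplitude, p$background) >= 0))
  structure(p, class = "tissue_params")
}

shift_zeropad <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0, ny, nx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Voronoi labels of pixel grid for seed points (rows sy, sx in 0-based px)
voronoi_labels <- function(seeds, ny, nx) {
  yv <- matrix(0:(ny - 1), ny, nx)
  xv <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  best <- matrix(Inf, ny, nx)
  lab <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(seeds))) {
    d2 <- (yv - seeds[i, 1])^2 + (xv - seeds[i, 2])^2
    take <- d2 < best
    best[take] <- d2[take]
    lab[take] <- i
  }
  lab
}

# pixels whose label differs from a 4-neighbor (both sides of each edge)
edge_mask <- function(lab) {
  ny <- nrow(lab); nx <- ncol(lab)
  e <- matrix(FALSE, ny, nx)
  dif <- lab[-ny, ] != lab[-1, ]
  e[-ny, ][dif] <- TRUE; e[-1, ][dif] <- TRUE
  dif <- lab[, -nx] != lab[, -1]
  e[, -nx][dif] <- TRUE; e[, -1][dif] <- TRUE
  e
}

#' Generate a synthetic tissue bundle with ground truth
#'
#' @param params a [tissue_params()] list.
#' @return a `tissue_bundle`: `channels` (named list of [volume_image()]:
#'   `junctions`, `nuclei`, `rna1`..., optionally `ihc1`), `truth` (cells as
#'   an [apical_cell_map()], nuclei as [nuclei_labels()] including any
#'   speckles, per-channel truth [spot_set()]s with true cell ids, per-cell
#'   high/low `classes`, per-cell expected `lambda`, the apical surface
#'   `zstar`, clean junction/nuclei renders), and `params`.
#' @export
generate_tissue <- function(params) {
  p <- params
  nz <- p$shape[1]; ny <- p$shape[2]; nx <- p$shape[3]
  sp <- p$spacing
  grid <- voxel_grid(p$shape, sp)
  set.seed(p$seed)

  # --- cells: Voronoi + one Lloyd step, retried if a cell cannot host a
  # nucleus. Nuclei are anchored at the generating seeds of the final
  # tessellation: every point of a Voronoi cell is then closest to its own
  # nucleus, which makes the flat centered limit genuinely unambiguous.
  r_lat_px <- p$nucleus_radii[2] / sp[3]
  lab <- NULL
  for (attempt in 1:5) {
    seeds <- cbind(runif(p$n_cells, 2, ny - 3), runif(p$n_cells, 2, nx - 3))
    l0 <- voronoi_labels(seeds, ny, nx)
    cent <- cbind(tapply(matrix(0:(ny - 1), ny, nx)[TRUE], l0, mean),
                  tapply(matrix(0:(nx - 1), ny, nx, byrow = TRUE)[TRUE], l0, mean))
    l1 <- voronoi_labels(cent, ny, nx)
    # inradius check: distance from the generating seed to the nearest edge
    em <- edge_mask(l1)
    ew <- which(em, arr.ind = TRUE) - 1
    inr <- vapply(seq_len(p$n_cells), function(c) {
      sqrt(min((ew[, 1] - cent[c, 1])^2 + (ew[, 2] - cent[c, 2])^2))
    }, numeric(1))
    if (all(inr >= 0.5 * r_lat_px) &&
        all(tabulate(l1, p$n_cells) > 0)) {
      lab <- l1; centroids <- cent; inradius_px <- inr
      break
    }
  }
  if (is.null(lab)) {
    stop("generate_tissue: cells too small to host a nucleus after 5 attempts; reduce n_cells or nucleus_radii")
  }

  # --- apical surface (cosine dome, peak height = curvature)
  yv <- matrix(0:(ny - 1), ny, nx)
  xv <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  y0 <- (ny - 1) / 2; x0 <- (nx - 1) / 2
  r_um <- sqrt(((yv - y0) * sp[2])^2 + ((xv - x0) * sp[3])^2)
  R_um <- min(ny * sp[2], nx * sp[3]) / 2
  bump <- 0.5 * (1 + cos(pi * pmin(r_um / R_um, 1)))
  z_base <- round(0.65 * (nz - 1))   # integral, so the flat limit's argmax is exact
  zstar <- z_base - (p$curvature / sp[1]) * bump
  zstar <- pmin(pmax(zstar, 2), nz - 3)

  # --- junction channel: Gaussian tube along Voronoi edges at z*(y,x)
  em <- edge_mask(lab)
  sig_j <- p$junction_thickness
  w <- ceiling(3 * sig_j / min(sp[2:3]))
  tube <- matrix(0, ny, nx)
  E <- em * 1
  for (dy in -w:w) for (dx in -w:w) {
    g <- exp(-((dy * sp[2])^2 + (dx * sp[3])^2) / (2 * sig_j^2))
    if (g < 1e-4) next
    tube <- pmax(tube, shift_zeropad(E, dy, dx) * g)
  }
  sig_jz <- max(sig_j, 0.6 * sp[1])
  clean_j <- array(0, p$shape)
  for (z in 0:(nz - 1)) {
    clean_j[z + 1, , ] <- p$junction_intensity * tube *
      exp(-((z - zstar) * sp[1])^2 / (2 * sig_jz^2))
  }

  # truth cell z: mean surface height over each cell's boundary pixels
  bnd <- em
  cz <- vapply(seq_len(p$n_cells), function(c) {
    px <- bnd & (lab == c)
    if (!any(px)) px <- lab == c
    mean(zstar[px])
  }, numeric(1))
  cz <- pmin(pmax(cz, 0), nz - 1)
  truth_cells <- apical_cell_map(lab, stats::setNames(cz, seq_len(p$n_cells)),
                                 grid)

  # --- cell bodies are columnar along the local surface normal: on a curved
  # sheet, nuclei and deep transcripts are laterally displaced relative to
  # the apical footprint (the projection strategy's failure mode). The unit
  # inward normal of z_um = h(y_um, x_um) is (1, -dh/dy, -dh/dx)/norm.
  h_um <- zstar * sp[1]
  hy <- (rbind(h_um[-1, ], h_um[ny, ]) - rbind(h_um[1, ], h_um[-ny, ])) /
    (2 * sp[2])
  hx <- (cbind(h_um[, -1], h_um[, nx]) - cbind(h_um[, 1], h_um[, -nx])) /
    (2 * sp[3])
  cell_normal <- function(c) {
    iy <- round(centroids[c, 1]) + 1; ix <- round(centroids[c, 2]) + 1
    v <- c(1, -hy[iy, ix], -hx[iy, ix])
    v / sqrt(sum(v^2))
  }
  normals <- t(vapply(seq_len(p$n_cells), cell_normal, numeric(3)))

  # --- nuclei: one ellipsoid per cell, offset basally along the normal,
  # laterally jittered
  r_ax <- p$nucleus_radii[1]; r_lat <- p$nucleus_radii[2]
  clean_n <- array(0, p$shape)
  truth_lab3 <- array(0L, p$shape)
  nuc_centers <- matrix(0, p$n_cells, 3)   # (z, y, x) voxel units
  for (c in seq_len(p$n_cells)) {
    th <- runif(1, 0, 2 * pi)
    rj <- runif(1, 0, p$nucleus_jitter) * inradius_px[c]
    apex_z <- zstar[round(centroids[c, 1]) + 1, round(centroids[c, 2]) + 1]
    disp <- p$nucleus_depth * normals[c, ] / sp     # um along normal -> voxels
    cyx <- centroids[c, ] + disp[2:3] + rj * c(sin(th), cos(th))
    cyx[1] <- min(max(cyx[1], 1), ny - 2)
    cyx[2] <- min(max(cyx[2], 1), nx - 2)
    znc <- apex_z + disp[1]
    znc <- min(znc, nz - 2 - r_ax / sp[1])
    nuc_centers[c, ] <- c(znc, cyx)
    wz <- ceiling((r_ax + 0.5) / sp[1]); wy <- ceiling((r_lat + 0.5) / sp[2])
    wxx <- ceiling((r_lat + 0.5) / sp[3])
    zs <- max(0, floor(znc - wz)):min(nz - 1, ceiling(znc + wz))
    ys <- max(0, floor(cyx[1] - wy)):min(ny - 1, ceiling(cyx[1] + wy))
    xs <- max(0, floor(cyx[2] - wxx)):min(nx - 1, ceiling(cyx[2] + wxx))
    zz <- array(rep(zs, times = length(ys) * length(xs)),
                c(length(zs), length(ys), length(xs)))
    yy <- array(rep(rep(ys, each = length(zs)), times = length(xs)),
                c(length(zs), length(ys), length(xs)))
    xx <- array(rep(xs, each = length(zs) * length(ys)),
                c(length(zs), length(ys), length(xs)))
    m <- sqrt(((zz - znc) * sp[1] / r_ax)^2 + ((yy - cyx[1]) * sp[2] / r_lat)^2 +
                ((xx - cyx[2]) * sp[3] / r_lat)^2)
    blob <- p$nucleus_intensity / (1 + exp((m - 1) / 0.1))
    sl <- clean_n[zs + 1, ys + 1, xs + 1]
    clean_n[zs + 1, ys + 1, xs + 1] <- pmax(sl, blob)
    tl <- truth_lab3[zs + 1, ys + 1, xs + 1]
    put <- m <= 1 & tl == 0
    tl[put] <- c
    truth_lab3[zs + 1, ys + 1, xs + 1] <- tl
  }
  # undersized speckles with their own truth labels (for size filtering)
  if (p$n_speckles > 0) {
    r_sp <- 0.5
    for (s in seq_len(p$n_speckles)) {
      repeat {
        pz <- runif(1, 2, nz - 3); py <- runif(1, 4, ny - 5); px <- runif(1, 4, nx - 5)
        if (truth_lab3[round(pz) + 1, round(py) + 1, round(px) + 1] == 0) break
      }
      wz <- ceiling(r_sp / sp[1] + 1); wy <- ceiling(r_sp / sp[2] + 1)
      zs <- max(0, floor(pz - wz)):min(nz - 1, ceiling(pz + wz))
      ys <- max(0, floor(py - wy)):min(ny - 1, ceiling(py + wy))
      xs <- max(0, floor(px - wy)):min(nx - 1, ceiling(px + wy))
      zz <- array(rep(zs, times = length(ys) * length(xs)),
                  c(length(zs), length(ys), length(xs)))
      yy <- array(rep(rep(ys, each = length(zs)), times = length(xs)),
                  c(length(zs), length(ys), length(xs)))
      xx <- array(rep(xs, each = length(zs) * length(ys)),
                  c(length(zs), length(ys), length(xs)))
      m <- sqrt(((zz - pz) * sp[1] / r_sp)^2 + ((yy - py) * sp[2] / r_sp)^2 +
                  ((xx - px) * sp[3] / r_sp)^2)
      blob <- p$nucleus_intensity / (1 + exp((m - 1) / 0.1))
      sl <- clean_n[zs + 1, ys + 1, xs + 1]
      clean_n[zs + 1, ys + 1, xs + 1] <- pmax(sl, blob)
      tl <- truth_lab3[zs + 1, ys + 1, xs + 1]
      put <- m <= 1 & tl == 0
      tl[put] <- p$n_cells + s
      truth_lab3[zs + 1, ys + 1, xs + 1] <- tl
    }
  }
  truth_nuclei <- nuclei_labels(truth_lab3, grid, intensity = clean_n)

  # --- RNA channels: two Poisson populations, spots uniform in cell prisms
  classes <- ifelse(runif(p$n_cells) < p$frac_high, "high", "low")
  lambda <- ifelse(classes == "high", p$lambda_high, p$lambda_low)
  # eligible spot pixels: at least spot_margin um from any junction edge
  moff <- ellipsoid_offsets(c(min(sp), p$spot_margin, p$spot_margin),
                            c(min(sp), sp[2], sp[3]))
  moff <- moff[moff[, 1] == 0, , drop = FALSE]
  interior <- matrix(TRUE, ny, nx)
  for (k in seq_len(nrow(moff))) {
    interior <- interior &
      (shift_zeropad(lab, moff[k, 2], moff[k, 3]) == lab)
  }
  cell_px <- lapply(seq_len(p$n_cells), function(c) {
    w <- which(interior & lab == c, arr.ind = TRUE)
    if (nrow(w) == 0) w <- which(lab == c, arr.ind = TRUE)
    w
  })
  sig_s <- c(p$spot_sigma[1], p$spot_sigma[2], p$spot_sigma[2])
  sig_vox <- sig_s / sp
  wrad <- pmax(ceiling(3 * sig_vox), 1)
  rna <- vector("list", p$n_rna_channels)
  truth_spots <- vector("list", p$n_rna_channels)
  truth_counts <- matrix(0L, p$n_cells, p$n_rna_channels)
  for (ch in seq_len(p$n_rna_channels)) {
    vol <- array(0, p$shape)
    counts <- rpois(p$n_cells, lambda)
    truth_counts[, ch] <- counts
    coords <- matrix(numeric(0), 0, 3)
    owner <- integer(0)
    for (c in seq_len(p$n_cells)) {
      if (counts[c] == 0) next
      px <- cell_px[[c]]
      pick <- sample.int(nrow(px), counts[c], replace = TRUE)
      sy0 <- px[pick, 1] - 1 + runif(counts[c], -0.49, 0.49)
      sx0 <- px[pick, 2] - 1 + runif(counts[c], -0.49, 0.49)
      sz0 <- zstar[px[pick, , drop = FALSE]]
      # uniform depth along the cell's normal, apex to nucleus bottom + 2 um
      t_max <- p$nucleus_depth + r_ax + 2
      t <- runif(counts[c], 0, t_max)
      sz <- pmin(pmax(sz0 + t * normals[c, 1] / sp[1], 1), nz - 2)
      sy <- pmin(pmax(sy0 + t * normals[c, 2] / sp[2], 1), ny - 2)
      sx <- pmin(pmax(sx0 + t * normals[c, 3] / sp[3], 1), nx - 2)
      coords <- rbind(coords, cbind(sz, sy, sx))
      owner <- c(owner, rep(c, counts[c]))
    }
    # render Gaussian spots
    for (s in seq_len(nrow(coords))) {
      cz_ <- coords[s, 1]; cy_ <- coords[s, 2]; cx_ <- coords[s, 3]
      zs <- max(0, floor(cz_ - wrad[1])):min(nz - 1, ceiling(cz_ + wrad[1]))
      ys <- max(0, floor(cy_ - wrad[2])):min(ny - 1, ceiling(cy_ + wrad[2]))
      xs <- max(0, floor(cx_ - wrad[3])):min(nx - 1, ceiling(cx_ + wrad[3]))
      gz <- exp(-((zs - cz_) * sp[1])^2 / (2 * sig_s[1]^2))
      gy <- exp(-((ys - cy_) * sp[2])^2 / (2 * sig_s[2]^2))
      gx <- exp(-((xs - cx_) * sp[3])^2 / (2 * sig_s[3]^2))
      vol[zs + 1, ys + 1, xs + 1] <- vol[zs + 1, ys + 1, xs + 1] +
        p$spot_amplitude * outer(outer(gz, gy), gx)
    }
    rna[[ch]] <- vol
    truth_spots[[ch]] <- spot_set(coords, paste0("rna", ch), cell = owner)
  }

  # --- optional IHC channel: cytoplasmic reporter tied to the class
  clean_ihc <- NULL
  if (!is.null(p$ihc_high)) {
    lev <- ifelse(classes == "high", p$ihc_high,
                  if (is.null(p$ihc_low)) 0 else p$ihc_low)
    lvmap <- matrix(lev[lab], ny, nx)
    depth_vox <- (p$nucleus_depth + r_ax + 2) / sp[1]
    clean_ihc <- array(0, p$shape)
    for (z in 0:(nz - 1)) {
      inz <- (z >= zstar) & (z <= zstar + depth_vox)
      clean_ihc[z + 1, , ] <- lvmap * inz
    }
  }

  degrade <- function(clean) {
    v <- clean + p$background
    if (p$poisson_noise) v <- array(rpois(length(v), pmax(v, 0)), dim(v))
    if (p$gaussian_noise_sd > 0) {
      v <- v + array(rnorm(length(v), 0, p$gaussian_noise_sd), dim(v))
    }
    pmin(pmax(round(v), 0), 65535)
  }
  channels <- list(junctions = volume_image(degrade(clean_j), sp, "junctions"),
                   nuclei = volume_image(degrade(clean_n), sp, "nuclei"))
  for (ch in seq_len(p$n_rna_channels)) {
    channels[[paste0("rna", ch)]] <-
      volume_image(degrade(rna[[ch]]), sp, paste0("rna", ch))
  }
  if (!is.null(clean_ihc)) {
    channels$ihc1 <- volume_image(degrade(clean_ihc), sp, "ihc1")
  }
  names(truth_spots) <- paste0("rna", seq_len(p$n_rna_channels))
  # co-stained acquisition: both structures imaged through one detector,
  # hence a single background/noise realisation; the noiseless render is
  # kept alongside so separation fidelity can be judged apart from noise
  mixed <- volume_image(degrade(clean_j + clean_n), sp, "mixed")
  mixed_clean <- volume_image(round(clean_j + clean_n + p$background), sp,
                              "mixed_clean")

  structure(list(
    channels = channels,
    mixed = mixed,
    mixed_clean = mixed_clean,
    truth = list(cells = truth_cells, nuclei = truth_nuclei,
                 spots = truth_spots, classes = stats::setNames(classes, seq_len(p$n_cells)),
                 lambda = stats::setNames(lambda, seq_len(p$n_cells)),
                 counts = truth_counts, zstar = zstar,
                 nucleus_centers = nuc_centers,
                 clean_junctions = clean_j, clean_nuclei = clean_n),
    params = p), class = "tissue_bundle")
}

#' @export
print.tissue_bundle <- function(x, ...) {
  cat(sprintf("<tissue_bundle> %d cells, channels: %s\n",
              x$params$n_cells, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Co-stained junction + nuclei channel of a bundle
#'
#' The summed clean junction and nuclei renders degraded by one pass of the
#' acquisition noise model — a co-stained acquisition has a single detector
#' noise realisation. Input for [separate_junction_nuclei()].
#' @param bundle a `tissue_bundle`.
#' @param noise with noise (the acquired channel) or the noiseless render
#'   (for judging separation fidelity independently of acquisition noise —
#'   at the default noise level the Pearson correlation of even a perfect
#'   separator with the clean components is capped near 0.64 by the noise
#'   itself).
#' @return a [volume_image()].
#' @export
mixed_channel <- function(bundle, noise = TRUE) {
  if (noise) bundle$mixed else bundle$mixed_clean
}

#' Write a tissue bundle to a directory
#'
#' Channels go into one interleaved multichannel `stack.tif`; truth labels,
#' spot tables, classes and parameters are written alongside under
#' `truth/`.
#'
#' @param bundle a `tissue_bundle`.
#' @param dir output directory (created).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_stack(bundle$channels, file.path(dir, "stack.tif"))
  write_apical_map(bundle$truth$cells,
                   file.path(dir, "truth", "cells.tif"),
                   file.path(dir, "truth", "cells_z.csv"))
  write_labels(bundle$truth$nuclei$labels3d, file.path(dir, "truth", "nuclei.tif"))
  for (ch in names(bundle$truth$spots)) {
    write_spots(bundle$truth$spots[[ch]],
                file.path(dir, "truth", paste0("spots_", ch, ".csv")))
  }
  write_csv_stable(data.frame(cell = as.integer(names(bundle$truth$classes)),
                              class = as.character(bundle$truth$classes),
                              lambda = as.numeric(bundle$truth$lambda)),
                   file.path(dir, "truth", "classes.csv"))
  pl <- bundle$params
  pl$channel_names <- names(bundle$channels)
  yaml::write_yaml(pl, file.path(dir, "params.yaml"))
  invisible(dir)
}
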