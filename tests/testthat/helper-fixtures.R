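# Shared fixtures: simulated bundles are expensive, so they are generated
# once per session and cached. All bundles use fixed seeds.

.bundle_cache <- new.env(parent = emptyenv())

get_bundle <- function(name) {
  if (!exists(name, envir = .bundle_cache)) {
    b <- switch(
      name,
      # flat, nuclei centered on their Voronoi seeds: the unambiguous limit
      flat = generate_tissue(tissue_params(seed = 1, nucleus_jitter = 0,
                                           ihc_high = 80, ihc_low = 15)),
      # default conditions (lateral nucleus jitter, two populations)
      default = generate_tissue(tissue_params(seed = 1)),
      # 10 um apical dome: the projection strategy's failure regime
      curved = generate_tissue(tissue_params(seed = 1, curvature = 10)),
      # ~400 expected spots in one channel at SNR 5
      spots400 = generate_tissue(tissue_params(seed = 1, lambda_high = 8,
                                               lambda_low = 8)),
      # small tissue for fast pipeline tests
      small = generate_tissue(tissue_params(shape = c(24, 96, 96),
                                            n_cells = 8, seed = 3)),
      stop("unknown fixture bundle: ", name))
    assign(name, b, envir = .bundle_cache)
  }
  get(name, envir = .bundle_cache)
}

# segment the curved bundle once (projection -> cells -> nuclei -> pairing
# -> detected spots), shared by the curved-tissue tests
get_curved_pipeline <- function() {
  if (!exists("curved_pipe", envir = .bundle_cache)) {
    b <- get_bundle("curved")
    zr <- project_apical(b$channels$junctions, "local_peak", smooth_sigma = 1)
    lab <- segment_cells_2d(zr, seed_h = 40, min_area = 5, max_area = 500,
                            smooth_sigma = 0.4)
    cells <- estimate_cell_z(lab, zr)
    nuc <- filter_nuclei(segment_nuclei(b$channels$nuclei, radius = 1.8),
                         min_volume = 5, max_volume = 200)
    pairing <- pair_nuclei_to_cells(cells, nuc, max_dist = 15)
    spots <- detect_spots(b$channels$rna1, c(1.7, 0.5), "auto")
    match <- score_spots(spots, b$truth$spots$rna1, 2)$match
    cellmatch <- score_cells(cells, b$truth$cells)
    assign("curved_pipe",
           list(bundle = b, zref = zr, cells = cells, nuclei = nuc,
                pairing = pairing, spots = spots, spot_match = match,
                cell_match = cellmatch),
           envir = .bundle_cache)
  }
  get("curved_pipe", envir = .bundle_cache)
}

# detected spots + truth pairing on the flat bundle, shared across tests
get_flat_detection <- function() {
  if (!exists("flat_det", envir = .bundle_cache)) {
    b <- get_bundle("flat")
    spots <- detect_spots(b$channels$rna1, c(1.7, 0.5), "auto")
    pairing <- pair_nuclei_to_cells(b$truth$cells, b$truth$nuclei,
                                    max_dist = 15)
    match <- score_spots(spots, b$truth$spots$rna1, 2)$match
    assign("flat_det", list(bundle = b, spots = spots, pairing = pairing,
                            spot_match = match),
           envir = .bundle_cache)
  }
  get("flat_det", envir = .bundle_cache)
}

# per-strategy agreement with generation truth over matched spots the
# strategy assigned (truth labels given directly or through a label map)
assigned_agreement <- function(result, truth_spots, match, cell_map = NULL) {
  pc <- result$spots$cell[match$a]
  tc <- truth_spots$cell[match$b]
  if (!is.null(cell_map)) {
    pc <- ifelse(pc > 0 & as.character(pc) %in% names(cell_map),
                 cell_map[as.character(pc)], 0L)
  }
  mean((pc == tc)[pc > 0])
}
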