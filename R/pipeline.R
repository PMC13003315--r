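# Config-driven pipeline: each stage reads its inputs from the working
# directory, writes outputs with stable filenames, and appends to a run
# log. `eq_run_all()` executes stages in dependency order, skipping stages
# whose outputs are newer than their inputs unless forced. All randomness
# flows from one top-level seed; stages derive sub-seeds deterministically
# from the stage name.

#' Default pipeline configuration
#'
#' One section per stage, mirroring the corresponding function's
#' parameters. Unknown keys in a user config are an error, never silently
#' ignored.
#'
#' @return nested list of defaults.
#' @export
eq_default_config <- function() {
  list(
    workdir = "epiquant_run",
    seed = 1,
    simulate = list(enabled = TRUE, shape = c(40, 256, 256),
                    spacing = c(1.0, 0.2, 0.2), n_cells = 50, curvature = 0,
                    n_rna_channels = 1, lambda_high = 30, lambda_low = 3,
                    frac_high = 0.5, ihc_high = NULL, ihc_low = NULL,
                    gaussian_noise_sd = 10, poisson_noise = TRUE),
    inputs = list(stack = NULL, spacing = NULL, n_channels = NULL,
                  junction_channel = "junctions", nuclear_channel = "nuclei",
                  rna_channels = NULL, ihc_channels = NULL),
    project = list(method = "local_peak", smooth_sigma = 1, z_range = NULL),
    segment = list(seed_h = 40, min_area = 5, max_area = 500,
                   smooth_sigma = 0.4, z_stat = "median"),
    nuclei = list(radius = 1.8, threshold = "auto", min_volume = 5,
                  max_volume = 200, z_keep = NULL),
    pair = list(max_dist = 15, wz = 0.25),
    spots = list(radius_axial = 1.7, radius_lateral = 0.5,
                 threshold = "auto"),
    assign = list(strategies = c("projection", "nearest_nucleus", "mixed",
                                 "hull", "iterative"),
                  depth_cut = 5, pad = 0.5, k = 4, max_iter = 10,
                  base = "mixed", nucleus_distance = "surface"),
    separate = list(enabled = FALSE, nucleus_radius = c(1.5, 3),
                    junction_thickness = 0.5),
    features = list(cyto_depth = 5, exclude_nucleus = FALSE,
                    classify_channel = NULL, classify_method = "otsu",
                    classify_threshold = NULL),
    cluster = list(enabled = FALSE, features = NULL, k = 2, linkage = "ward")
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    full <- if (path == "") k else paste0(path, ".", k)
    if (!k %in% names(base)) {
      stop("unknown config key: ", full)
    }
    if (is.list(base[[k]]) && is.list(user[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], full)
    } else {
      base[k] <- user[k]   # preserves explicit NULLs
    }
  }
  base
}

#' Load a pipeline config from YAML, applying dotted-key overrides
#'
#' @param path YAML file (NULL = defaults only).
#' @param overrides character vector of `section.key=value` overrides, e.g.
#'   `c("spots.threshold=12", "seed=7")`.
#' @return validated config list.
#' @export
eq_load_config <- function(path = NULL, overrides = character()) {
  cfg <- eq_default_config()
  if (!is.null(path)) {
    user <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop("cannot parse config '", path, "': ", conditionMessage(e)))
    cfg <- merge_config(cfg, user)
  }
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad override (need key=value): ", ov)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- yaml::yaml.load(kv[2])
    node <- list(val)
    for (k in rev(keys)) node <- stats::setNames(list(node[[1]]), k)[1]
    # rebuild nested list
    wrap <- val
    for (k in rev(keys)) wrap <- stats::setNames(list(wrap), k)
    cfg <- merge_config(cfg, wrap)
  }
  cfg
}

stage_seed <- function(cfg, stage) {
  (cfg$seed * 1000 + sum(utf8ToInt(stage))) %% .Machine$integer.max
}

log_line <- function(wd, msg) {
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
      file = file.path(wd, "run_log.txt"), append = TRUE)
}

outputs_fresh <- function(outs, ins) {
  if (!all(file.exists(outs))) return(FALSE)
  ins <- ins[file.exists(ins)]
  if (!length(ins)) return(TRUE)
  min(file.mtime(outs)) >= max(file.mtime(ins))
}

# load channels written by the simulate stage (or external inputs)
load_channels <- function(cfg) {
  wd <- cfg$workdir
  py <- file.path(wd, "params.yaml")
  if (file.exists(py)) {
    pl <- yaml::read_yaml(py)
    return(read_stack(file.path(wd, "stack.tif"), unlist(pl$spacing),
                      n_channels = length(pl$channel_names),
                      channel_names = unlist(pl$channel_names)))
  }
  if (is.null(cfg$inputs$stack)) {
    stop("no stack found: run the 'simulate' stage first or set inputs.stack")
  }
  read_stack(cfg$inputs$stack, unlist(cfg$inputs$spacing),
             n_channels = cfg$inputs$n_channels %||% 1)
}

load_cells <- function(cfg, channels) {
  f1 <- file.path(cfg$workdir, "cells_labels.tif")
  f2 <- file.path(cfg$workdir, "cells_z.csv")
  if (!file.exists(f1) || !file.exists(f2)) {
    stop("missing cell map: run the 'segment' stage first")
  }
  grid <- channels[[1]]$grid
  read_apical_map(f1, f2, grid$spacing, grid$shape[1])
}

load_nuclei <- function(cfg, channels) {
  f <- file.path(cfg$workdir, "nuclei_labels.tif")
  if (!file.exists(f)) stop("missing nuclei labels: run the 'nuclei' stage first")
  lab <- read_labels(f)
  nuc_ch <- channels[[cfg$inputs$nuclear_channel]] %||% channels$nuclei
  nuclei_labels(lab, channels[[1]]$grid, intensity = nuc_ch$data)
}

load_pairing <- function(cfg) {
  f <- file.path(cfg$workdir, "pairing.csv")
  if (!file.exists(f)) stop("missing pairing: run the 'pair' stage first")
  df <- utils::read.csv(f)
  cell_pairing(stats::setNames(df$nucleus, df$cell), NA_real_)
}

rna_channel_names <- function(cfg, channels) {
  nm <- cfg$inputs$rna_channels
  if (!is.null(nm)) return(nm)
  grep("^rna", names(channels), value = TRUE)
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `project`, `segment`, `nuclei`, `pair`, `spots`,
#' `assign`, `separate`, `features`, `table` (alias of `features`),
#' `cluster`, `compare`.
#'
#' @param stage stage name.
#' @param cfg config list from [eq_load_config()].
#' @param force rerun even when outputs are newer than inputs.
#' @return invisibly, the paths written.
#' @export
eq_run_stage <- function(stage, cfg, force = FALSE) {
  wd <- cfg$workdir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  paths <- switch(
    stage,
    simulate = {
      outs <- file.path(wd, c("stack.tif", "params.yaml"))
      if (!force && outputs_fresh(outs, character(0))) return(invisible(outs))
      sim <- cfg$simulate
      sim$enabled <- NULL
      sim$seed <- stage_seed(cfg, "simulate")
      bundle <- generate_tissue(do.call(tissue_params, sim))
      write_bundle(bundle, wd)
      file.copy(file.path(wd, "params.yaml"), file.path(wd, "params.yaml"))
      outs
    },
    project = {
      ins <- file.path(wd, "stack.tif")
      outs <- file.path(wd, c("projection.tif", "zmap.tif"))
      if (!force && outputs_fresh(outs, ins)) return(invisible(outs))
      ch <- load_channels(cfg)
      zr <- project_apical(ch[[cfg$inputs$junction_channel]],
                           method = cfg$project$method,
                           smooth_sigma = cfg$project$smooth_sigma,
                           z_range = cfg$project$z_range)
      write_labels(matrix(as.integer(round(zr$projection)),
                          nrow(zr$projection)), outs[1])
      write_labels(matrix(as.integer(zr$zmap), nrow(zr$zmap)), outs[2])
      outs
    },
    segment = {
      ins <- file.path(wd, c("projection.tif", "zmap.tif"))
      outs <- file.path(wd, c("cells_labels.tif", "cells_z.csv"))
      if (!force && outputs_fresh(outs, ins)) return(invisible(outs))
      if (!all(file.exists(ins))) stop("missing projection: run 'project' first")
      ch <- load_channels(cfg)
      grid <- ch[[1]]$grid
      zr <- structure(list(projection = read_labels(ins[1]) * 1,
                           zmap = read_labels(ins[2]) * 1,
                           grid = grid, method = cfg$project$method),
                      class = "zref_map")
      lab <- segment_cells_2d(zr, cfg$segment$seed_h, cfg$segment$min_area,
                              cfg$segment$max_area,
                              smooth_sigma = cfg$segment$smooth_sigma)
      cells <- estimate_cell_z(lab, zr, stat = cfg$segment$z_stat)
      write_apical_map(cells, outs[1], outs[2])
      outs
    },
    nuclei = {
      ins <- file.path(wd, "stack.tif")
      outs <- file.path(wd, c("nuclei_labels.tif", "nuclei_props.csv"))
      if (!force && outputs_fresh(outs, ins)) return(invisible(outs))
      ch <- load_channels(cfg)
      nuc <- segment_nuclei(ch[[cfg$inputs$nuclear_channel]],
                            radius = cfg$nuclei$radius,
                            threshold = cfg$nuclei$threshold)
      nuc <- filter_nuclei(nuc, cfg$nuclei$min_volume, cfg$nuclei$max_volume,
                           cfg$nuclei$z_keep)
      write_labels(nuc$labels3d, outs[1])
      write_csv_stable(nuc$props, outs[2])
      outs
    },
    pair = {
      ins <- file.path(wd, c("cells_labels.tif", "cells_z.csv",
                             "nuclei_labels.tif"))
      outs <- file.path(wd, "pairing.csv")
      if (!force && outputs_fresh(outs, ins)) return(invisible(outs))
      ch <- load_channels(cfg)
      pairing <- pair_nuclei_to_cells(load_cells(cfg, ch),
                                      load_nuclei(cfg, ch),
                                      max_dist = cfg$pair$max_dist,
                                      wz = cfg$pair$wz)
      write_csv_stable(pairing_table(pairing), outs)
      outs
    },
    spots = {
      ins <- file.path(wd, "stack.tif")
      ch <- load_channels(cfg)
      rna <- rna_channel_names(cfg, ch)
      outs <- file.path(wd, paste0("spots_", rna, ".csv"))
      if (!force && outputs_fresh(outs, ins)) return(invisible(outs))
      for (i in seq_along(rna)) {
        ss <- detect_spots(ch[[rna[i]]],
                           c(cfg$spots$radius_axial, cfg$spots$radius_lateral),
                           threshold = cfg$spots$threshold)
        write_spots(ss, outs[i])
      }
      outs
    },
    assign = {
      ch <- load_channels(cfg)
      rna <- rna_channel_names(cfg, ch)
      strat <- cfg$assign$strategies
      outs <- c(outer(rna, strat, function(r, s)
        file.path(wd, paste0("assigned_", r, "_", s, ".csv"))))
      ins <- c(file.path(wd, paste0("spots_", rna, ".csv")),
               file.path(wd, c("cells_labels.tif", "cells_z.csv",
                               "nuclei_labels.tif", "pairing.csv")))
      if (!force && outputs_fresh(outs, ins)) return(invisible(outs))
      cells <- load_cells(cfg, ch)
      nuclei <- load_nuclei(cfg, ch)
      pairing <- load_pairing(cfg)
      for (r in rna) {
        spots <- read_spots(file.path(wd, paste0("spots_", r, ".csv")), r)
        res <- run_strategies(spots, cells, nuclei, pairing, cfg$assign)
        for (s in names(res)) {
          write_spots(res[[s]]$spots,
                      file.path(wd, paste0("assigned_", r, "_", s, ".csv")))
        }
      }
      outs
    },
    separate = {
      ins <- file.path(wd, "stack.tif")
      outs <- file.path(wd, c("separated_junctions.tif",
                              "separated_nuclei.tif"))
      if (!force && outputs_fresh(outs, ins)) return(invisible(outs))
      ch <- load_channels(cfg)
      mixed <- volume_image(ch[[cfg$inputs$junction_channel]]$data +
                              ch[[cfg$inputs$nuclear_channel]]$data,
                            ch[[1]]$grid$spacing, "mixed")
      sep <- separate_junction_nuclei(mixed, cfg$separate$nucleus_radius,
                                      cfg$separate$junction_thickness)
      write_stack(sep$junctions, outs[1])
      write_stack(sep$nuclei, outs[2])
      outs
    },
    features = ,
    table = {
      ch <- load_channels(cfg)
      rna <- rna_channel_names(cfg, ch)
      strat0 <- cfg$assign$strategies[1]
      ins <- c(file.path(wd, paste0("assigned_", rna, "_", strat0, ".csv")),
               file.path(wd, c("cells_labels.tif", "cells_z.csv",
                               "nuclei_labels.tif", "pairing.csv")))
      outs <- file.path(wd, "cell_table.csv")
      if (!force && outputs_fresh(outs, ins)) return(invisible(outs))
      cells <- load_cells(cfg, ch)
      nuclei <- load_nuclei(cfg, ch)
      pairing <- load_pairing(cfg)
      assignments <- lapply(rna, function(r) {
        sp <- read_spots(file.path(wd, paste0("assigned_", r, "_", strat0,
                                              ".csv")), r)
        new_assignment(sp, strat0)
      })
      names(assignments) <- rna
      meas_ch <- unique(c(rna, cfg$inputs$ihc_channels,
                          intersect("ihc1", names(ch))))
      cyto <- lapply(meas_ch, function(r) {
        measure_cytoplasmic_intensity(ch[[r]], cells, cfg$features$cyto_depth,
                                      nuclei = nuclei,
                                      exclude_nucleus = cfg$features$exclude_nucleus)
      })
      names(cyto) <- meas_ch
      nucint <- lapply(meas_ch, function(r)
        measure_nuclear_intensity(ch[[r]], nuclei))
      names(nucint) <- meas_ch
      classes <- list()
      clch <- cfg$features$classify_channel
      if (!is.null(clch)) {
        vals <- stats::setNames(cyto[[clch]]$mean, cyto[[clch]]$cell)
        classes[[clch]] <- prefill_classification(
          vals, method = cfg$features$classify_method,
          threshold = cfg$features$classify_threshold, name = clch)
      }
      tab <- build_cell_table(cells, nuclei, pairing, assignments, cyto,
                              nucint, classes)
      write_cell_table(tab, outs)
      outs
    },
    cluster = {
      ins <- file.path(wd, "cell_table.csv")
      outs <- file.path(wd, "cell_table_clustered.csv")
      if (!force && outputs_fresh(outs, ins)) return(invisible(outs))
      if (!file.exists(ins)) stop("missing cell table: run 'features' first")
      tab <- read_cell_table(ins)
      feats <- cfg$cluster$features %||%
        grep("^count_", names(tab), value = TRUE)
      tab <- cluster_cells(tab, feats, cfg$cluster$k, cfg$cluster$linkage)
      write_cell_table(tab, outs)
      outs
    },
    compare = {
      ch <- load_channels(cfg)
      rna <- rna_channel_names(cfg, ch)
      strat <- cfg$assign$strategies
      ins <- c(outer(rna, strat, function(r, s)
        file.path(wd, paste0("assigned_", r, "_", s, ".csv"))))
      outs <- file.path(wd, paste0("comparison_", rna, ".csv"))
      if (!force && outputs_fresh(outs, ins)) return(invisible(outs))
      for (i in seq_along(rna)) {
        res <- lapply(strat, function(s) {
          sp <- read_spots(file.path(wd, paste0("assigned_", rna[i], "_", s,
                                                ".csv")), rna[i])
          new_assignment(sp, s)
        })
        write_csv_stable(comparison_table(compare_strategies(res)), outs[i])
      }
      outs
    },
    stop("unknown stage: ", stage)
  )
  log_line(wd, sprintf("stage %s done in %.1fs (seed %d)", stage,
                       as.numeric(difftime(Sys.time(), t0, units = "secs")),
                       stage_seed(cfg, stage)))
  invisible(paths)
}

# run the configured assignment strategies on one channel
run_strategies <- function(spots, cells, nuclei, pairing, acfg) {
  out <- list()
  for (s in acfg$strategies) {
    out[[s]] <- switch(
      s,
      projection = assign_projection(spots, cells),
      nearest_nucleus = assign_nearest_nucleus(spots, nuclei, pairing,
                                               acfg$nucleus_distance),
      mixed = assign_mixed(spots, cells, nuclei, pairing, acfg$depth_cut,
                           acfg$nucleus_distance),
      hull = assign_hull(spots, cells, nuclei, pairing, acfg$pad),
      iterative = {
        base <- out[[acfg$base]]
        if (is.null(base)) {
          base <- assign_mixed(spots, cells, nuclei, pairing, acfg$depth_cut,
                               acfg$nucleus_distance)
        }
        assign_iterative(spots, base, acfg$k, acfg$max_iter,
                         spacing = cells$grid$spacing)
      },
      stop("unknown assignment strategy: ", s))
  }
  out
}

#' Run the whole pipeline in dependency order
#'
#' @param cfg config list from [eq_load_config()].
#' @param force rerun all stages even when outputs are up to date.
#' @return invisibly, the working directory.
#' @export
eq_run_all <- function(cfg, force = FALSE) {
  stages <- c(if (isTRUE(cfg$simulate$enabled)) "simulate",
              "project", "segment", "nuclei", "pair", "spots", "assign",
              if (isTRUE(cfg$separate$enabled)) "separate",
              "features",
              if (isTRUE(cfg$cluster$enabled)) "cluster",
              "compare")
  for (s in stages) eq_run_stage(s, cfg, force = force)
  invisible(cfg$workdir)
}

#' Command-line entry point
#'
#' Dispatches `epiquant <stage|run-all> [--config file] [--force]
#' [section.key=value ...]`; used by the `inst/cli/epiquant.R` script.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success).
#' @export
eq_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: epiquant <simulate|project|segment|nuclei|pair|spots|assign|separate|features|table|cluster|compare|run-all> [--config cfg.yaml] [--force] [key=value ...]\n")
    return(invisible(1L))
  }
  stage <- args[1]
  rest <- args[-1]
  cfgpath <- NULL
  force <- FALSE
  if ("--force" %in% rest) { force <- TRUE; rest <- setdiff(rest, "--force") }
  ci <- which(rest == "--config")
  if (length(ci)) {
    cfgpath <- rest[ci + 1]
    rest <- rest[-c(ci, ci + 1)]
  }
  status <- tryCatch({
    cfg <- eq_load_config(cfgpath, overrides = rest)
    if (stage == "run-all") eq_run_all(cfg, force = force)
    else eq_run_stage(stage, cfg, force = force)
    0L
  }, error = function(e) {
    message("epiquant: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
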