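# Scoring predictions against simulator ground truth.

#' Match predicted 2D cell labels to truth by overlap
#'
#' @param pred 2D integer label matrix (or [apical_cell_map()]).
#' @param truth_cells truth [apical_cell_map()].
#' @return list: `table` (per truth cell: best predicted label, Jaccard),
#'   `mean_jaccard`, `n_matched` (Jaccard >= 0.5), `map` (named vector
#'   predicted label -> truth label for matched pairs).
#' @export
score_cells <- function(pred, truth_cells) {
  if (inherits(pred, "apical_cell_map")) pred <- pred$labels2d
  tl <- truth_cells$labels2d
  both <- pred > 0 & tl > 0
  labs_t <- cell_labels(truth_cells)
  n_t <- tabulate(tl[tl > 0], max(tl))
  n_p <- tabulate(pred[pred > 0], max(max(pred), 1))
  ov <- table(truth = tl[both], pred = pred[both])
  res <- data.frame(truth = labs_t, pred = NA_integer_, jaccard = 0)
  map <- integer(0); mapn <- character(0)
  for (i in seq_along(labs_t)) {
    t <- labs_t[i]
    row <- ov[rownames(ov) == as.character(t), , drop = FALSE]
    if (nrow(row) == 0 || ncol(row) == 0) next
    inter <- as.numeric(row)
    pl <- as.integer(colnames(ov))
    jac <- inter / (n_t[t] + n_p[pl] - inter)
    j <- which.max(jac)
    res$pred[i] <- pl[j]
    res$jaccard[i] <- jac[j]
    if (jac[j] >= 0.5) { map <- c(map, t); mapn <- c(mapn, as.character(pl[j])) }
  }
  list(table = res, mean_jaccard = mean(res$jaccard),
       n_matched = sum(res$jaccard >= 0.5),
       map = stats::setNames(map, mapn))
}

#' Nucleus detection precision/recall by centroid matching
#'
#' Greedy nearest matching of predicted to truth centroids within
#' `radius_um` (default 2 um).
#'
#' @param pred,truth [nuclei_labels()] objects on the same grid.
#' @param radius_um match radius in micrometres.
#' @return list: `precision`, `recall`, `mean_centroid_error_um`, `n_pred`,
#'   `n_truth`.
#' @export
score_nuclei <- function(pred, truth, radius_um = 2) {
  sp <- truth$grid$spacing
  a <- cbind(pred$props$z * sp[1], pred$props$y * sp[2], pred$props$x * sp[3])
  b <- cbind(truth$props$z * sp[1], truth$props$y * sp[2], truth$props$x * sp[3])
  m <- greedy_match_points(a, b, radius_um)
  err <- if (length(m$a)) sqrt(rowSums((a[m$a, , drop = FALSE] -
                                          b[m$b, , drop = FALSE])^2)) else numeric(0)
  list(precision = if (nrow(a)) length(m$a) / nrow(a) else NA_real_,
       recall = if (nrow(b)) length(m$a) / nrow(b) else 0,
       mean_centroid_error_um = if (length(err)) mean(err) else NA_real_,
       n_pred = nrow(a), n_truth = nrow(b))
}

#' Spot detection precision/recall/F1 by greedy matching
#'
#' Matching is greedy nearest in voxel units within `radius_vox` (default
#' 2 voxels).
#'
#' @param pred,truth [spot_set()]s.
#' @param radius_vox match radius in voxels.
#' @return list: `precision`, `recall`, `f1`, `match` (index pairs).
#' @export
score_spots <- function(pred, truth, radius_vox = 2) {
  m <- greedy_match_points(pred$coords, truth$coords, radius_vox)
  np <- length(pred); nt <- length(truth)
  prec <- if (np) length(m$a) / np else NA_real_
  rec <- if (nt) length(m$a) / nt else 0
  f1 <- if (!is.na(prec) && prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1, match = m)
}

#' Assignment accuracy against truth
#'
#' For predicted spots matched to truth spots, the fraction assigned to the
#' correct cell. When the assignment ran on segmented (not truth) labels,
#' pass the `map` from [score_cells()] to translate predicted labels.
#'
#' @param result an `assignment_result` on the predicted spots.
#' @param truth_spots truth [spot_set()] with true cell ids.
#' @param match spot match from [score_spots()] (`pred` vs `truth`).
#' @param cell_map optional named vector predicted label -> truth label.
#' @return fraction correct among matched spots (unassigned = incorrect).
#' @export
score_assignment <- function(result, truth_spots, match, cell_map = NULL) {
  if (length(match$a) == 0) return(NA_real_)
  pc <- result$spots$cell[match$a]
  tc <- truth_spots$cell[match$b]
  if (!is.null(cell_map)) {
    pc <- ifelse(pc > 0 & as.character(pc) %in% names(cell_map),
                 cell_map[as.character(pc)], 0L)
  }
  mean(pc == tc)
}

#' Agreement of predicted classes with truth classes
#'
#' @param pred,truth character vectors named by cell; `pred` may use
#'   positive/negative and `truth` high/low — the orientation maximising
#'   agreement is scored (class labels are arbitrary).
#' @return agreement fraction over shared cells.
#' @export
score_classes <- function(pred, truth) {
  cells <- intersect(names(pred), names(truth))
  if (!length(cells)) return(NA_real_)
  p <- pred[cells] %in% c("positive", "high")
  t <- truth[cells] %in% c("positive", "high")
  max(mean(p == t), mean(p != t))
}

#' Score a set of predictions against a bundle's ground truth
#'
#' Convenience umbrella over the individual scorers.
#'
#' @param bundle a `tissue_bundle`.
#' @param cells optional predicted labels / [apical_cell_map()].
#' @param nuclei optional predicted [nuclei_labels()].
#' @param spots optional named list of predicted [spot_set()]s per channel.
#' @param assignments optional named list (channel) of lists (strategy) of
#'   `assignment_result`s.
#' @param classes optional named character vector of predicted classes.
#' @param radius_um,radius_vox match radii for nuclei and spots.
#' @return nested list of metric records.
#' @export
score_against_truth <- function(bundle, cells = NULL, nuclei = NULL,
                                spots = NULL, assignments = NULL,
                                classes = NULL, radius_um = 2,
                                radius_vox = 2) {
  out <- list()
  cmap <- NULL
  if (!is.null(cells)) {
    out$cells <- score_cells(cells, bundle$truth$cells)
    cmap <- out$cells$map
  }
  if (!is.null(nuclei)) {
    out$nuclei <- score_nuclei(nuclei, bundle$truth$nuclei, radius_um)
  }
  if (!is.null(spots)) {
    out$spots <- lapply(names(spots), function(ch) {
      score_spots(spots[[ch]], bundle$truth$spots[[ch]], radius_vox)
    })
    names(out$spots) <- names(spots)
  }
  if (!is.null(assignments)) {
    out$assignment <- lapply(names(assignments), function(ch) {
      sm <- out$spots[[ch]]$match
      vapply(assignments[[ch]], function(r) {
        score_assignment(r, bundle$truth$spots[[ch]], sm, cmap)
      }, numeric(1))
    })
    names(out$assignment) <- names(assignments)
  }
  if (!is.null(classes)) {
    out$classes <- score_classes(classes, bundle$truth$classes)
  }
  out
}
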