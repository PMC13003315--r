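---
title: "Quantifying multimodal 3D epithelium images at single-cell resolution"
author: "epiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multimodal 3D epithelium images at single-cell resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiquant)
```

## The problem and the 2.5D model

Multiplexed imaging of epithelia routinely combines an apical junction
marker (outlining cells as a 2D mesh embedded in 3D), a nuclear stain,
single-molecule FISH channels in which individual transcripts appear as
diffraction-limited dots, and immunohistochemistry channels. Turning such a
stack into per-cell biology requires cell segmentation, 3D nucleus
segmentation, 3D spot detection, and — the step with no off-the-shelf
answer — deciding which cell each nucleus and each spot belongs to, when
cells are only delineated at their apical surface.

epiquant follows the 2.5D scheme appropriate for sheet-like tissues: cells
are segmented on a 2D projection of the junction channel, and each 2D label
additionally carries a Z coordinate ("2D labels with 3D coordinates"). This
is an approximation: it assumes one cell layer and will misestimate
measures such as surface area where the sheet is strongly curved. The
assignment strategies below exist precisely because the 2.5D footprint
under-determines where a cell's 3D volume is.

All public coordinates are 0-based voxel indices, ordered (z, y, x);
physical quantities are obtained by multiplying with the voxel spacing
(dz, dy, dx) in µm. Distances used in any decision are always physical,
never voxel counts, because axial sampling is typically 5x coarser than
lateral.

## Projection and 2.5D segmentation

`project_apical()` reduces the junction channel to a 2D intensity image
plus a Z reference map. `method = "max"` takes the per-pixel maximum and
its argmax; `"local_peak"` (default in the pipeline) smooths each Z profile
with a Gaussian (`smooth_sigma`, µm, default 1) before the argmax, which
suppresses spurious maxima from shot noise while reporting the unsmoothed
intensity. Argmax ties break toward the smallest Z — a documented,
deterministic choice.

`segment_cells_2d()` is a classical seeded watershed intended as a
built-in fallback: seeds are the connected minima of the h-minima transform
of the projection (depth `seed_h`; cell interiors are intensity basins
between bright junction ridges), flooding runs on the projection, and the
watershed lines — the junctions — become background 0. Regions outside
`[min_area, max_area]` µm² are removed after flooding, before any Z
estimation. An optional 2D pre-smoothing (`smooth_sigma`, default 0.4 µm
in the pipeline configuration) regularises pixel noise; at the default
acquisition noise the h-minima depth alone would otherwise need to absorb
basin-internal noise pits. Label images from dedicated segmenters
(Cellpose, Epyseg, ...) are first-class input instead, via `read_labels()`
plus a two-column `label,z` CSV sidecar — TIFF cannot carry a per-label
scalar, so the sidecar convention is this package's own.

`estimate_cell_z()` lifts labels to 2.5D. Only the junctions carry apical
signal, so the Z statistic (median by default; mean available) is taken
over a one-pixel-dilated band around each cell's boundary, not over its
interior. The median makes single misprojected pixels irrelevant.

## Nucleus segmentation and pairing

`segment_nuclei()` is a classical blob detector with the output contract
of a learned segmenter, so externally produced 3D label volumes can be
substituted at any time: a scale-normalised Laplacian-of-Gaussian filter
with per-axis sigma `radius / sqrt(3) / spacing` (the standard relation
between a 3D blob's radius and its LoG scale), candidate maxima above a
threshold (Otsu on the response by default), and a marker-seeded watershed
on the inverted smoothed intensity inside an Otsu foreground mask so that
touching nuclei do not merge. `filter_nuclei()` implements the
filter-then-correct stage with volume bounds and an optional Z window; the
bounds are this package's choice of criteria, since size and depth are the
two failure axes of blob detection in practice.

`pair_nuclei_to_cells()` solves a minimum-cost bipartite matching
(Hungarian algorithm, O(n³) potential form, implemented in the package).
The cost of a (cell, nucleus) pair is the Euclidean distance in µm between
the cell's apical anchor — its 2D centroid placed at `cell_z` — and the
nucleus centroid, with the Z term down-weighted by `wz = 0.25`: nuclei sit
basally at variable depth below their apex, so lateral offset is the
informative term. Pairs costlier than `max_dist` (default 15 µm) are
forbidden; the solver then returns the maximum number of admissible pairs
at minimal total cost, leaving excess cells or nuclei unmatched rather than
inventing dummy partners. Exact cost ties prefer lower (cell, nucleus)
label pairs through an infinitesimal perturbation.

## Spot detection

`detect_spots()` uses the same scale-normalised LoG filter with separate
axial and lateral radii. Candidates are strict local maxima in a 3×3×3
neighborhood; plateau ties keep only the lexicographically smallest
coordinate, and voxels within one voxel of a stack face are excluded so
that the per-axis quadratic (parabolic) sub-voxel refinement always has
both neighbors. Refinement can move a spot at most half a voxel per axis.

The automatic threshold (`auto_threshold()`) sweeps 100 evenly spaced
thresholds over the candidate responses and finds the knee of the
surviving-count curve — the point of maximal distance below the chord
joining the curve's endpoints. Two numerical choices matter. First, the
counts are taken on a log scale: noise maxima outnumber true spots by
orders of magnitude, and on a linear scale the chord construction lands
inside the noise tail rather than at its foot. Second, the knee of a real
curve is a short plateau, not a corner; the implementation returns the
largest threshold whose chord distance is within 5 % of the maximum, i.e.
the far edge of the knee, which steps off the last stragglers of the noise
tail. On simulated channels this threshold is consistently within 0.05 F1
of the best threshold found by grid search.

## Spot-to-cell assignment: five strategies

Spots live in 3D; cells are apical footprints. The package implements five
assignment strategies plus machinery to compare them:

* **projection** — the spot takes the 2D label under its rounded (y, x),
  at any depth. Exact when cells are vertical prisms; degrades with tissue
  curvature, where a deep spot sits laterally displaced from its cell's
  footprint.
* **nearest_nucleus** — the spot goes to the cell paired with its closest
  nucleus. Distance is zero inside a nucleus, otherwise the distance to
  the nearest labeled voxel (surface mode, default — large nuclei must not
  lose nearby spots to small ones; centroid mode available as
  `nucleus_distance = "centroid"`). Ties take the lower nucleus label.
* **mixed** — spot depth is measured vertically from its projection cell's
  apical plane; shallow spots (≤ `depth_cut`, default 5 µm) keep the
  projection assignment, deep spots take the nearest-nucleus one. Spots
  whose projection lands on background count as infinitely deep.
* **hull** — each cell's volume is approximated by the convex hull of its
  apical boundary polygon at `cell_z` plus the six axis-extreme voxels of
  its paired nucleus: the minimal volume construction available from 2.5D
  data. The hull is dilated by offsetting each supporting half-space by
  `pad` (0.5 µm, absorbing voxelisation). A spot inside several hulls goes
  to the nearest hull centroid; below every nucleus, it stays unassigned —
  the hull strategy is deliberately conservative in depth. Cells without a
  paired nucleus have coplanar support and assign nothing (with a
  warning). The supporting half-spaces are found by enumerating support
  triples and keeping planes with all support points on one side; tests
  verify every (spot, cell) decision against an independently coded
  half-space oracle.
* **iterative** — starting from any base assignment (default mixed),
  each unassigned spot repeatedly adopts the strict-majority cell among
  its k nearest assigned spots. Assigned spots are frozen, so the
  unassigned count is non-increasing and the procedure terminates; a tied
  vote leaves the spot unassigned for that round. This neighborhood
  propagation presumes expression dense enough that a spot's neighbors are
  mostly its own cell's.

`compare_strategies()` reports pairwise agreement over spots assigned by
both strategies, per-strategy unassigned fractions, and accuracy when
ground truth is available. Agreement is intentionally conditioned on
assignment: strategies differ in coverage by design (the hull strategy
abstains below the nuclei), and coverage is reported separately rather
than folded into the agreement number.

## Intensities, classification, the cell table, clustering

Cytoplasmic intensity is measured in the cell's apical footprint extruded
`depth` µm downward from its apical plane — consistent with the 2.5D
scheme, with no lateral shrinking toward the basal side. Nuclear voxels
are included by default (`exclude_nucleus` flag available). Nuclear
intensity is the per-nucleus mean/sum, joined to cells through the
pairing. Binary classifications are pre-filled from any per-cell value by
Otsu's threshold (256 bins) or a manual cutoff; multi-class labels enter
via CSV import. `build_cell_table()` joins morphometrics (area, boundary
-step perimeter, circularity 4πA/P², centroid, neighbor count, nucleus
volume), per-channel spot counts, intensity blocks and class columns into
one row per cell; missing blocks yield empty fields, never dropped rows,
and 0 is never used as a missing-value sentinel because it is a legal
count. Per channel, assigned counts plus the unassigned count always equal
total detections. `cluster_cells()` z-scores the chosen feature columns and
cuts an agglomerative tree (Euclidean distance; Ward's D2, average or
complete linkage) at k clusters; rows with missing features are excluded
and reported, never imputed silently.

## Separating co-stained junctions and nuclei

When junctions and nuclei share one acquisition channel,
`separate_junction_nuclei()` splits them with grayscale morphology:
junctions are thin (a wall ~1 µm across), nuclei are blobs, so an opening
with an ellipsoidal element of half the nucleus radius per axis erases the
former and preserves the latter. The nuclei estimate is the opening; the
junction estimate is the residual (a white top-hat), so the two virtual
channels sum back to the input exactly and both are non-negative
(anti-extensivity of opening; border handling ignores out-of-volume
offsets precisely to preserve this). The element honors both voxel
anisotropy and nucleus shape: for oblate nuclei the element is
correspondingly flat, which matters — a round element as tall as the
nucleus erodes its axial caps into the junction estimate. With the default
simulated acquisition noise, the Pearson correlation of even a perfect
separator with the clean components is capped near 0.64 by the noise
itself (the junction signal is sparse, the noise is everywhere), so
separation fidelity is evaluated on the noiseless summed render, where the
morphological split reaches r ≈ 0.94 (junctions) and 0.97 (nuclei); the
exactness of the decomposition is asserted on the noisy channel.

## The synthetic tissue generator

`generate_tissue()` renders a complete multimodal stack with ground truth,
so every stage is testable without external data. Default geometry:
40×256×256 voxels at (1.0, 0.2, 0.2) µm — a 51×51 µm field, 40 µm deep —
with 50 cells; all validation runs finish in minutes on one CPU.

* **Cells** — Voronoi tessellation of uniform seeds after one Lloyd
  relaxation step; the tessellation is regenerated (up to 5 times) if any
  cell's inradius cannot host a nucleus.
* **Apical surface** — a cosine dome of configurable peak height
  (`curvature`, µm; 0 = flat), its base plane at an integral Z so the flat
  limit's argmax is exact.
* **Columnar geometry** — nuclei and transcripts populate a column along
  the *local surface normal*, not a vertical prism. This is the crucial
  modelling choice: with vertical prisms the projection strategy would be
  exact under any curvature and the failure mode that motivates the other
  strategies could never be exercised. On a 10 µm dome, deep content is
  laterally displaced by several µm relative to the apical footprint.
* **Nuclei** — one ellipsoid per cell (default radii 1.5 µm axial ×
  2.0 µm lateral — oblate, like the cells' aspect at this packing
  density), centred `nucleus_depth` = 5 µm below the apex along the
  normal, laterally jittered up to 20 % of the cell inradius. Nuclei are
  anchored at the tessellation's generating seeds, so with zero jitter
  every point of a cell is provably closest to its own nucleus — the
  unambiguous limit in which all five strategies must coincide, used by
  the concordance checks.
* **Transcripts** — per cell and channel, a Poisson count with mean
  λ_high = 30 or λ_low = 3 by a Bernoulli(0.5) cell class; spots uniform
  in the column from the apical surface to 2 µm below the nucleus bottom,
  with a 0.5 µm lateral margin from the junctions (transcripts are
  cytoplasmic; the membrane region is excluded). Rendered as 3D Gaussians
  of σ = (1.0, 0.3) µm — slightly wider than the diffraction limit, i.e. a
  PSF properly sampled by the (1.0, 0.2) µm grid; a critically sampled PSF
  would make sub-voxel rendering, not the detector, the recall bottleneck.
* **Noise** — constant background (10 counts), optional shot noise
  (Poisson), Gaussian read noise (sd 10; spot amplitude 50 gives SNR 5),
  then quantisation to integer camera counts in [0, 65535] — which is also
  why simulator TIFFs round-trip bit-exactly.
* **Extras** — an optional IHC channel fills each cell's column with a
  class-tied reporter level; `n_speckles` adds undersized bright blobs
  with their own truth labels for testing size filters; the co-stained
  mixed channel is rendered with a *single* noise realisation (summing two
  independently noisy channels would double noise and background, which no
  real co-stained acquisition has).

What the simulator does not emulate: optical PSF structure beyond
Gaussians, photobleaching, depth-dependent attenuation, multi-layer or
pseudostratified epithelia, segmentation-relevant junction gaps, and
transcript clustering within cells. Passing its checks therefore
demonstrates the correctness and internal consistency of the algorithms
under controlled geometry and noise — not performance on any particular
real tissue.

## Validation design

The test suite anchors every stage to the generator's truth:
matching optimality is checked against an exhaustive dynamic-programming
oracle on 200 random instances; hull containment against a scalar
half-space enumeration on every (spot, cell) pair of a full bundle; flat
centered tissue must produce ≥ 99 % truth agreement for all five
strategies; on the 10 µm dome, mixed and hull must not fall below pure
projection; detection at SNR 5 must reach precision and recall 0.90; the
cell table must conserve counts exactly; separation must decompose exactly
and correlate ≥ 0.8 with each clean component; Otsu pre-fill must match
the generated classes ≥ 95 %; the end-to-end table's counts must correlate
r ≥ 0.8 with the generating Poisson means; and two pipeline runs with one
configuration must produce byte-identical CSVs. Agreement-based checks
score matched spots that a strategy assigned, with unassigned fractions
reported separately, matching `compare_strategies()` semantics — the
generator intentionally places a band of spots below the hull strategy's
reach. `scripts/acceptance.R` recomputes all of these quantities from
scratch.

Problem sizes were chosen so the full suite and the acceptance script each
run in a few minutes on a single CPU: 50-cell default bundles, one
~400-spot channel for detection metrics, 8-cell bundles for pipeline
plumbing and determinism checks.

## Known limitations

Single cell layer only; one nucleus per cell (no division figures); no
dense-spot decomposition (overlapping transcripts in very high expressors
merge, which is why detection recall is quoted on the ~8-per-cell regime
and count recovery as a correlation, not an exact count); the built-in
watershed is a fallback, not a competitor to trained segmenters; no soft
or probabilistic assignment; hierarchical clustering is a convenience, not
a statistical analysis.
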