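---
title: "Quantifying vessel tortuosity around lung nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vessel tortuosity around lung nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qvtools)
```

## The problem and the pipeline

Malignant lung adenocarcinomas tend to recruit and deform their feeding
vasculature, while benign granulomas — their most common radiographic
mimics — tend to leave it comparatively straight. `qvtools` turns that
morphological observation into numbers. Given a CT volume in Hounsfield
units (HU) and a nodule mask, the pipeline runs four stages:

1. **Lung isolation** (`segment_lungs`). Voxels below an air threshold
   (default −400 HU) are labelled; connected components touching the
   volume border are exterior air and are discarded; the remaining large
   components are the lung fields; a morphological closing (ball radius
   3 mm) re-includes vessels and nodules embedded in the parenchyma.
2. **Vessel segmentation** (`region_grow_vasculature`). From the nodule's
   centre of gravity plus `n_random_seeds = 10` random nodule voxels, a
   region grows voxel by voxel. A frontier voxel is accepted iff its HU is
   at least the running region mean plus the offset `S` (HU). The frontier
   is processed best-first by HU with ties broken by linear index, so the
   first rejection is the global frontier maximum and growth stops there;
   the result is deterministic given the seed. More negative `S` is more
   permissive and grows larger volumes, so the grown volume is empirically
   non-increasing over the grid `S ∈ {−150, −100, −50, 0, 50}`. Growth is
   confined to the lung mask (plus the nodule) and capped at `max_voxels`
   (reaching the cap flags truncation rather than failing).
3. **Centerline extraction** (`extract_tree`). See below.
4. **Feature computation** (`compute_qvt`) and the analysis stack: mRMR
   selection, ICC stability, cross-validated classification, k-means and
   consensus clustering.

All geometry is carried in world millimetres — voxel `(i, j, k)` (0-based)
sits at `origin + index · spacing` — so anisotropic spacing is handled
uniformly and no metric is ever computed in voxel units.

## Centerline extraction

The skeletonization is a minimal-path scheme on the segmented mask:

* a spacing-aware Euclidean distance map `D` (Felzenszwalb's separable
  algorithm, compiled) gives each foreground voxel its distance to the
  boundary;
* a front is propagated (Dijkstra on the 26-connected grid graph, a
  discrete fast-marching approximation) from the most interior voxel, with
  speed `(D / D_max)^p`; the exponent `p` (`centeredness_power`, default
  6) makes boundary-hugging paths expensive so minimal paths run along the
  vessel centre;
* branches are peeled iteratively: the farthest still-uncovered voxel by
  arrival time is back-traced along the steepest arrival-time descent
  until it meets the existing skeleton; territory within
  `D + endpoint_tolerance_mm` of the new branch is marked covered;
  iteration stops when every remaining voxel is within the tolerance of
  covered territory.

Three details matter numerically. First, a back-trace that starts at a
tube end-cap corner picks up an off-axis hook before it reaches the medial
axis; the leading points are trimmed while the arc travelled is shorter
than the running maximum of `D` (the medial axis of a capped tube starts
one radius from the cap). Second, surface bumps can spawn short terminal
spurs; terminal chains shorter than `1.5 · D(attach) + tolerance` are
pruned and any degree-2 junction left behind is merged back into a single
branch. Third, `centeredness_power` defaults to 6 rather than a smaller
exponent because weaker centring leaves a residual off-axis hook at tube
ends that exceeds a one-voxel-diagonal deviation budget on straight-tube
phantoms; the exponent is exposed for experimentation. Polylines are
lightly smoothed (3-point moving average, endpoints fixed, reverted where
smoothing would exit the mask) and resampled to a uniform arc-length step
(default: the smallest voxel spacing) because windowed torsion and
three-point curvature are step-sensitive.

A mask that is a blob rather than a tube yields branches shorter than
`min_branch_length` (default 5 points); these are kept in the tree but
excluded from statistics, and a case with no eligible branch is flagged
degenerate and emits zeros rather than NaNs, keeping cohort tables
rectangular.

## The 35 features

Branch torsion is the chord-to-arc ratio; point curvature is the Menger
curvature (inverse circumradius) of consecutive point triples; point
torsion is the chord-to-arc ratio of a 5-point sliding window — the
windowed form is used instead of the Frenet-frame torsion because it stays
stable on noisy voxel-scale polylines and matches the chord/arc definition
of branch torsion. The canonical vector is:

| slots | content |
|---|---|
| 1–5 | mean, sd, min, max, median of branch torsion |
| 6–10 | the same statistics of per-branch **mean** point curvature |
| 11–15 | the same statistics of per-branch **max** point curvature |
| 16–17 | eligible branch count; bifurcation count |
| 18–20 | vasculature volume in the VOI (mm³); volume/VOI ratio; volume/bounding-box ratio |
| 21–28 | normalized point-curvature histogram, 8 equal bins on [0, 0.5] mm⁻¹, last bin open above |
| 29–35 | normalized point-torsion histogram, 7 equal bins on [0, 1] |

The histogram bin counts (8 + 7) were chosen so the descriptor totals
exactly 35 entries; all edges live in `qvt_config()` and can be changed
without touching code. Volume features are computed inside the VOI (the
nodule bounding box dilated by `voi_margin_mm`, default 10 mm), the
default reading of where such measurements are taken; the VOI is
configurable. Useful invariants, all under test: torsion features are
rigid-motion and scale invariant; curvature features are rigid-motion
invariant and scale as 1/s; histograms sum to 1 whenever any point
contributes.

## The analysis stack

* **mRMR** (`mrmr_select`): greedy difference form — the first pick
  maximizes MI(feature; label); each next pick maximizes MI(f; label) −
  mean MI(f; picked), ties broken by column order. Continuous features are
  discretized at mean ± 1 sd (sample sd, inclusive boundaries); features
  with at most three distinct values are used as categories directly,
  because re-thresholding a balanced two-valued feature at mean ± sd would
  collapse it into a single level (the sample sd of a balanced ±a vector
  exceeds a) and hide a perfectly informative feature from the selector.
* **ICC** (`icc`): two-way random effects, absolute agreement, single
  measurement — ICC(2,1) — from the mean-squares decomposition, clipped to
  [−1, 1]; ICC > 0.7 is labelled high stability, 0.4–0.7 moderate.
  Absolute agreement penalizes systematic test–retest offsets, which is
  the behaviour wanted for scanner-stability screening.
* **Classification** (`train_evaluate`): stratified 3-fold CV with
  fold-internal z-scoring (scaler fit on training folds only). The SVM's
  RBF grid (cost × gamma scale) is selected by a 2-fold *inner* CV inside
  each training fold, so the reported fold AUCs carry no selection
  optimism; the locked-down model refits all rows with the
  across-folds majority choice. In the study pipeline the label-driven
  mRMR selection is likewise rerun inside every training fold (the
  ICC stability filter may restrict the candidate pool beforehand, since
  it uses retest agreement, not labels), so the reported CV AUC is free of
  feature-selection leakage and sits at chance level on label-free null
  cohorts; the locked model carries the selection made on all rows. AUC is
  the rank (Mann–Whitney) form with ties counted ½. Folds are built on
  sorted case ids, making the result invariant to row order at a fixed
  seed.
* **Clustering**: seeded k-means (restarts, best inertia) with a Pearson
  chi-squared test of cluster–label association, and co-occurrence
  consensus clustering over k ∈ {2, 3, 4} × {euclidean (k-means),
  cityblock, correlation (both via PAM on the distance matrix)} × 20
  k-means restarts; the consensus matrix is re-clustered by
  average-linkage hierarchical clustering into two dominant groups, and
  purity against the labels is reported. P-values are reported raw by
  default, matching the convention of reporting per-feature significance
  without multiple-testing correction; a Benjamini–Hochberg adjustment is
  a one-liner via `p.adjust` on the returned values.

## The phantom generator

`make_phantom_case` builds the scene the pipeline expects: a 64³ volume at
0.5 mm isotropic spacing with a 2-voxel exterior air shell (−1000 HU), a
soft-tissue body (+40 HU), an ellipsoidal lung cavity (−850 HU), a
spherical nodule (radius 3 mm, +50 HU) at the root of a randomly grown
vessel tree (tube radius 1.2 mm, +50 HU, 2 bifurcations by default), and
Gaussian noise (σ = 20 HU). Tortuosity is injected as sinusoidal
centerline displacement with integer half-waves, so branches stay attached
at bifurcations and the effect of the amplitude knob on chord/arc torsion
is monotone and analytically checkable. Voxels are foreground iff their
centre lies within the tube radius of the centerline, with segments
rasterized as open cylinders — so a straight tube's mask volume converges
to the analytic πr²L rather than to a capsule volume with spurious
end-caps.

`make_cohort` plants the class effect: per-case tortuosity amplitudes are
drawn from N(2.2, 0.4) mm for the adeno-like class and N(0.4, 0.15) mm for
the granuloma-like class (truncated at 0). These defaults represent a
strongly separated regime — the situation where the descriptor should
succeed — and were chosen so the two amplitude distributions are several
standard deviations apart at a tube radius of 1.2 mm; a null experiment
passes identical distributions for both classes. `make_test_retest`
produces a same-geometry re-acquisition: the noise field is re-drawn and
the scene can be rigidly shifted by a sub-voxel amount (trilinear
resampling), with masks and truth tree carried through the shift.

What the phantoms do **not** emulate: parenchymal texture, airways,
contrast enhancement, vessel radius tapering, breathing deformation, or
scanner-specific reconstruction kernels. Passing phantom tests therefore
demonstrates the correctness of the geometry, segmentation logic and
statistics on idealized vasculature — not clinical performance on patient
scans, which requires real cohorts.

Slice-thickness experiments resample each case along z by averaging the
native slices inside each output slab (a box slice-sensitivity profile)
rather than by point interpolation: point sampling at 5 mm steps can
entirely skip thin structures such as the phantom's body wall, which is a
sampling artifact, whereas slab averaging reproduces the real
partial-volume dilution that makes thin vessels fade at thick slice
spacing. The nodule mask is propagated as the slab union so seeds remain
inside the nodule.

## Determinism and problem sizes

Every stochastic step consumes a seed derived from a single master seed by
stable string hashing (`derive_seed`), so a study is bit-reproducible from
one integer. The shipped tests and the acceptance script run on cohorts of
60 phantom cases (30 per class) at 64³ × 0.5 mm, with a 10-case
test–retest subset and a 1 mm vs 5 mm slice-thickness comparison — sizes
chosen to exercise every stage end to end while a full run stays in the
minutes range on a single core. Larger volumes and cohorts scale linearly
in voxels and cases; the compiled kernels (distance transform, region
growing, front propagation, rasterization) dominate the per-case cost.

## Known limitations

* The region-growing acceptance rule is pinned to
  `HU ≥ running mean + S`; other readings of a "mean difference" rule
  (e.g. symmetric bands) would change the S-response curve.
* The exact identity of all 35 descriptor entries follows the named
  feature families (torsion statistics, branch-mean and branch-max
  curvature statistics, branching counts, volume ratios, point
  histograms); the histogram bin edges are a documented reconstruction,
  configurable in `qvt_config()`, not an asserted canonical set.
* Cycles in the segmented mask are broken implicitly by the minimal-path
  tree; no explicit loop handling or vessel-radius estimation is done.
* The DICOM reader covers uncompressed explicit-VR little-endian,
  axis-aligned, 16-bit series — the common CT export case — and refuses
  anything else explicitly rather than guessing.
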