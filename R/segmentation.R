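# Lung isolation, seeded region growing of nodule-associated vasculature, and
# VOI definition.

#' Region-growing configuration
#'
#' @param S_hu mean-difference acceptance offset in HU: a candidate voxel is
#'   accepted iff its HU is at least the running region mean plus `S_hu`.
#'   More negative values are more permissive and grow larger volumes.
#' @param connectivity 6 or 26.
#' @param max_voxels growth cap; reaching it flags the result as truncated.
#' @param n_random_seeds extra random seed voxels drawn inside the nodule.
#' @param rng_seed seed for the random seed draw.
#' @return An object of class `region_grow_config`.
#' @export
region_grow_config <- function(S_hu = -50, connectivity = 26,
                               max_voxels = 200000L, n_random_seeds = 10L,
                               rng_seed = 1L) {
  stopifnot(max_voxels > 0, connectivity %in% c(6, 26), n_random_seeds >= 0)
  structure(list(S_hu = S_hu, connectivity = as.integer(connectivity),
                 max_voxels = as.integer(max_voxels),
                 n_random_seeds = as.integer(n_random_seeds),
                 rng_seed = as.integer(rng_seed)),
            class = "region_grow_config")
}

# morphology via the distance transform ---------------------------------------

dilate_mm <- function(vals, spacing, r_mm) {
  if (r_mm <= 0) return(vals)
  d2 <- cpp_edt_sq(as.integer(!vals), dim(vals), spacing)
  vals | array(d2 <= r_mm^2, dim = dim(vals))
}

erode_mm <- function(vals, spacing, r_mm) {
  if (r_mm <= 0) return(vals)
  d2 <- cpp_edt_sq(as.integer(vals), dim(vals), spacing)
  array(vals & d2 > r_mm^2, dim = dim(vals))
}

close_mm <- function(vals, spacing, r_mm) {
  erode_mm(dilate_mm(vals, spacing, r_mm), spacing, r_mm)
}

#' Isolate lung fields from a HU volume
#'
#' Multi-threshold scheme: voxels below `air_threshold_hu` are air-like;
#' connected components touching the volume border are exterior air and are
#' discarded; the remaining large components are the lung fields. A
#' morphological closing then re-includes vessels and nodules interior to the
#' lung.
#'
#' @param volume an [image_volume()].
#' @param air_threshold_hu HU below which a voxel is air-like (default -400).
#' @param body_threshold_hu HU above which a voxel counts as body tissue
#'   (documented for completeness; the enclosure test is the border-contact
#'   test).
#' @param closing_radius_mm radius of the closing ball (default 3 mm).
#' @param min_component_frac keep air components at least this fraction of
#'   the largest interior component.
#' @return A [binary_mask()] of the lung fields.
#' @export
segment_lungs <- function(volume, air_threshold_hu = -400,
                          body_threshold_hu = -200, closing_radius_mm = 3,
                          min_component_frac = 0.05) {
  stopifnot(inherits(volume, "image_volume"))
  dm <- dim(volume$values)
  low <- volume$values < air_threshold_hu
  if (!any(low)) stopf("segment_lungs: no lung field found (no voxels below %g HU)",
                       air_threshold_hu)
  lab <- array(cpp_label_components(as.integer(low), dm, 6L), dim = dm)
  border_labels <- unique(c(lab[1, , ], lab[dm[1], , ], lab[, 1, ], lab[, dm[2], ],
                            lab[, , 1], lab[, , dm[3]]))
  border_labels <- border_labels[border_labels != 0]
  interior <- lab
  interior[interior %in% border_labels] <- 0L
  if (!any(interior > 0)) stopf("segment_lungs: no lung field found (all air-like regions touch the border)")
  sizes <- tabulate(interior[interior > 0])
  keep <- which(sizes >= max(min_component_frac * max(sizes), 10))
  mask <- array(interior %in% keep, dim = dm)
  mask <- close_mm(mask, volume$spacing, closing_radius_mm)
  binary_mask(mask, volume$spacing, volume$origin)
}

#' Centre of gravity of a nodule mask
#'
#' @param nodule_mask a nonempty [binary_mask()].
#' @return Length-3 world point (mm): the unweighted centroid of the
#'   foreground voxel centres.
#' @export
nodule_centroid <- function(nodule_mask) {
  stopifnot(inherits(nodule_mask, "binary_mask"))
  if (!any(nodule_mask$values)) stopf("nodule_centroid: empty mask")
  lin <- which(nodule_mask$values) - 1L
  ijk <- lin_to_ijk(lin, dim(nodule_mask$values))
  as.numeric(colMeans(ijk_to_world(ijk, nodule_mask$spacing, nodule_mask$origin)))
}

#' Grow nodule-associated vasculature from nodule seeds
#'
#' Seeds are the nodule centre-of-gravity voxel plus `n_random_seeds` voxels
#' drawn at random inside the nodule. Growth is best-first by HU with ties
#' broken by linear index; a frontier voxel is accepted iff its HU is at
#' least the running region mean plus `S_hu`. When a lung mask is supplied,
#' growth is confined to it (plus the nodule itself).
#'
#' @param volume an [image_volume()].
#' @param nodule_mask nonempty [binary_mask()] aligned with `volume`.
#' @param cfg a [region_grow_config()].
#' @param lung_mask optional [binary_mask()] confining the growth; `NULL`
#'   grows over the whole grid.
#' @return A [binary_mask()] of the grown region with attributes
#'   `truncated` (cap reached) and `n_voxels`.
#' @export
region_grow_vasculature <- function(volume, nodule_mask, cfg = region_grow_config(),
                                    lung_mask = NULL) {
  stopifnot(inherits(volume, "image_volume"), inherits(nodule_mask, "binary_mask"))
  check_aligned(volume, nodule_mask)
  if (!any(nodule_mask$values)) stopf("region_grow_vasculature: empty nodule mask")
  dm <- dim(volume$values)

  centroid <- nodule_centroid(nodule_mask)
  cvox <- world_to_ijk(matrix(centroid, 1), volume$spacing, volume$origin)
  cvox <- pmin(pmax(cvox, 0), matrix(dm - 1L, 1))
  seeds <- ijk_to_lin(cvox, dm)
  nodvox <- which(nodule_mask$values) - 1L
  # snap the centroid onto the nodule if rounding left it outside
  if (!nodule_mask$values[seeds + 1L]) {
    ijk <- lin_to_ijk(nodvox, dm)
    w <- ijk_to_world(ijk, volume$spacing, volume$origin)
    seeds <- nodvox[which.min(rowSums(sweep(w, 2, centroid)^2))]
  }
  if (cfg$n_random_seeds > 0) {
    set.seed(cfg$rng_seed)
    extra <- nodvox[sample.int(length(nodvox),
                               min(cfg$n_random_seeds, length(nodvox)))]
    seeds <- unique(c(seeds, extra))
  }
  allowed <- if (is.null(lung_mask)) {
    array(TRUE, dim = dm)
  } else {
    check_aligned(volume, lung_mask)
    lung_mask$values | nodule_mask$values
  }
  res <- cpp_region_grow(as.numeric(volume$values), as.integer(allowed), dm,
                         as.integer(seeds), cfg$S_hu, cfg$connectivity,
                         cfg$max_voxels)
  out <- binary_mask(array(res$mask == 1L, dim = dm), volume$spacing,
                     volume$origin)
  attr(out, "truncated") <- isTRUE(res$truncated)
  attr(out, "n_voxels") <- res$n_voxels
  out
}

#' Volume of interest around a nodule
#'
#' Tight bounding box of the nodule mask dilated by `margin_mm` (converted
#' per axis via the spacing) and clipped to the grid.
#'
#' @param nodule_mask nonempty [binary_mask()].
#' @param margin_mm margin in mm (>= 0).
#' @return An [roi()].
#' @export
define_voi <- function(nodule_mask, margin_mm = 10) {
  stopifnot(inherits(nodule_mask, "binary_mask"), margin_mm >= 0)
  if (!any(nodule_mask$values)) stopf("define_voi: empty nodule mask")
  dm <- dim(nodule_mask$values)
  lin <- which(nodule_mask$values) - 1L
  ijk <- lin_to_ijk(lin, dm)
  marg <- as.integer(ceiling(margin_mm / nodule_mask$spacing - 1e-9))
  lower <- pmax(apply(ijk, 2, min) - marg, 0L)
  upper <- pmin(apply(ijk, 2, max) + 1L + marg, dm)
  roi(lower, upper)
}

#' Sensitivity of the feature vector to the segmentation parameter S
#'
#' Re-segments one case at every S in `S_list`, recomputes the full feature
#' vector for each segmentation, and reports the Pearson correlation between
#' the per-S feature vectors.
#'
#' @param volume,nodule_mask the case.
#' @param S_list numeric vector of S values (HU), nonempty.
#' @param cfg a [region_grow_config()] (its `S_hu` is overridden per run).
#' @param lung_mask optional lung mask passed to the region growing.
#' @param voi_margin_mm VOI margin around the nodule.
#' @param qvt_cfg a [qvt_config()].
#' @return A list with `masks` (per S), `features` (matrix `length(S_list) x
#'   35`), and `corr` (S-by-S Pearson correlation of feature vectors).
#' @export
sensitivity_to_S <- function(volume, nodule_mask,
                             S_list = c(-150, -100, -50, 0, 50),
                             cfg = region_grow_config(), lung_mask = NULL,
                             voi_margin_mm = 10, qvt_cfg = qvt_config()) {
  if (length(S_list) == 0) stopf("sensitivity_to_S: empty S_list")
  voi <- define_voi(nodule_mask, voi_margin_mm)
  masks <- list(); feats <- NULL
  for (S in S_list) {
    cfg$S_hu <- S
    m <- region_grow_vasculature(volume, nodule_mask, cfg, lung_mask)
    tree <- if (any(m$values)) extract_tree(m) else vessel_tree(list(), degenerate = TRUE)
    fv <- compute_qvt(tree, m, voi, qvt_cfg)
    masks[[as.character(S)]] <- m
    feats <- rbind(feats, fv)
  }
  rownames(feats) <- as.character(S_list)
  corr <- matrix(1, length(S_list), length(S_list),
                 dimnames = list(S_list, S_list))
  if (length(S_list) > 1) {
    for (i in seq_along(S_list)) for (j in seq_along(S_list)) {
      if (i != j) corr[i, j] <- safe_cor(feats[i, ], feats[j, ])
    }
  }
  list(masks = masks, features = feats, corr = corr)
}

#' Per-feature S-sensitivity over a phantom cohort
#'
#' For each feature, the Pearson correlation across cases between the feature
#' values obtained at two segmentation settings S1 and S2.
#'
#' @param cases list of `phantom_case` objects.
#' @param S_list S values (HU).
#' @param cfg,voi_margin_mm,qvt_cfg as in [sensitivity_to_S()].
#' @param use_lung_mask compute and use a lung mask per case.
#' @return A list with `feature_corr` (array `S x S x feature`) and
#'   `mean_corr` (S-by-S mean over features).
#' @export
sensitivity_to_S_cohort <- function(cases, S_list = c(-100, -50, 0),
                                    cfg = region_grow_config(),
                                    voi_margin_mm = 10,
                                    qvt_cfg = qvt_config(),
                                    use_lung_mask = TRUE) {
  if (length(S_list) == 0) stopf("sensitivity_to_S_cohort: empty S_list")
  nS <- length(S_list)
  per_case <- lapply(cases, function(cs) {
    lung <- if (use_lung_mask) segment_lungs(cs$volume) else NULL
    sensitivity_to_S(cs$volume, cs$nodule_mask, S_list, cfg, lung,
                     voi_margin_mm, qvt_cfg)$features
  })
  nf <- ncol(per_case[[1]])
  fc <- array(1, dim = c(nS, nS, nf),
              dimnames = list(S_list, S_list, colnames(per_case[[1]])))
  for (f in seq_len(nf)) {
    vals <- vapply(per_case, function(m) m[, f], numeric(nS))  # nS x ncases
    for (i in seq_len(nS)) for (j in seq_len(nS)) {
      if (i != j) fc[i, j, f] <- safe_cor(vals[i, ], vals[j, ])
    }
  }
  list(feature_corr = fc, mean_corr = apply(fc, c(1, 2), mean, na.rm = TRUE))
}

# correlation that tolerates constant vectors (returns 1 when both constant,
# 0 when only one is)
safe_cor <- function(x, y) {
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 && sy == 0) return(1)
  if (sx == 0 || sy == 0) return(0)
  cor(x, y)
}
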