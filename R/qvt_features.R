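# The 35-element quantitative vessel tortuosity descriptor.
#
# Torsion of a branch is the chord-to-arc ratio (1 = straight, -> 0 =
# convoluted); curvature of an interior centerline point is the Menger
# curvature, the inverse circumradius of the circle through the point and its
# two neighbours. The descriptor collects first-order statistics of these
# over branches, branching counts, vasculature volume measurements inside the
# VOI, and pooled point histograms of curvature and torsion.

#' Feature-extraction configuration
#'
#' @param torsion_window odd point count (>= 3) of the sliding window used
#'   for point-level torsion.
#' @param curvature_hist_edges bin edges (mm^-1) of the point-curvature
#'   histogram; the last bin is open above. Default 8 equal bins on \[0, 0.5\].
#' @param torsion_hist_edges bin edges of the point-torsion histogram.
#'   Default 7 equal bins on \[0, 1\].
#' @param min_branch_length minimum polyline points for a branch to enter the
#'   statistics.
#' @return An object of class `qvt_config`.
#' @export
qvt_config <- function(torsion_window = 5L,
                       curvature_hist_edges = seq(0, 0.5, length.out = 9),
                       torsion_hist_edges = seq(0, 1, length.out = 8),
                       min_branch_length = 5L) {
  stopifnot(torsion_window >= 3, torsion_window %% 2 == 1,
            all(diff(curvature_hist_edges) > 0), all(diff(torsion_hist_edges) > 0),
            min_branch_length >= 2)
  structure(list(torsion_window = as.integer(torsion_window),
                 curvature_hist_edges = curvature_hist_edges,
                 torsion_hist_edges = torsion_hist_edges,
                 min_branch_length = as.integer(min_branch_length)),
            class = "qvt_config")
}

#' Canonical names of the 35 features
#'
#' @param cfg a [qvt_config()] (bin counts determine histogram names).
#' @return Character vector of length 35 (for the default configuration).
#' @export
qvt_feature_names <- function(cfg = qvt_config()) {
  stats <- c("mean", "std", "min", "max", "median")
  nc <- length(cfg$curvature_hist_edges) - 1
  nt <- length(cfg$torsion_hist_edges) - 1
  c(paste0("qvt_torsion_", stats),
    paste0("qvt_curvMean_", stats),
    paste0("qvt_curvMax_", stats),
    "qvt_nBranches", "qvt_nBifurcations",
    "qvt_vesselVolume", "qvt_volVoiRatio", "qvt_volBBoxRatio",
    paste0("qvt_curvHist_", seq_len(nc)),
    paste0("qvt_torsHist_", seq_len(nt)))
}

#' Menger curvature of three points
#'
#' Inverse of the circumradius of the circle through the three points:
#' `4 * Area / (|p1p2| |p2p3| |p1p3|)`. Collinear points give 0.
#'
#' @param p1,p2,p3 length-3 points (mm).
#' @return Curvature in mm^-1.
#' @export
menger_curvature <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p2; w <- p3 - p1
  a <- sqrt(sum(u^2)); b <- sqrt(sum(v^2)); cl <- sqrt(sum(w^2))
  if (a == 0 || b == 0 || cl == 0) stopf("menger_curvature: coincident points")
  cr <- c(u[2] * w[3] - u[3] * w[2],
          u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  2 * sqrt(sum(cr^2)) / (a * b * cl)
}

# vectorized Menger curvature over all interior points of a polyline
polyline_curvatures <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(numeric(0))
  p1 <- pts[1:(n - 2), , drop = FALSE]
  p2 <- pts[2:(n - 1), , drop = FALSE]
  p3 <- pts[3:n, , drop = FALSE]
  u <- p2 - p1; v <- p3 - p2; w <- p3 - p1
  a <- sqrt(rowSums(u^2)); b <- sqrt(rowSums(v^2)); cl <- sqrt(rowSums(w^2))
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  k <- 2 * sqrt(rowSums(cr^2)) / (a * b * cl)
  k[!is.finite(k)] <- 0
  k
}

#' Chord-to-arc torsion of a whole branch
#'
#' @param branch `n x 3` point matrix (mm) with positive arc length.
#' @return Dimensionless value in \[0, 1\]; 1 for a straight branch, 0 for a
#'   closed loop.
#' @export
branch_torsion <- function(branch) {
  branch <- matrix(as.numeric(branch), ncol = 3)
  arc <- polyline_arclength(branch)
  if (!is.finite(arc) || arc <= 0) stopf("branch_torsion: zero arc length")
  chord <- sqrt(sum((branch[nrow(branch), ] - branch[1, ])^2))
  min(1, chord / arc)
}

#' Windowed point-level torsion
#'
#' Chord-to-arc ratio of the `window`-point sub-polyline centred at `index`.
#' Points without a full half-window on each side contribute nothing.
#'
#' @param branch `n x 3` point matrix.
#' @param index 1-based point index.
#' @param window odd window size (>= 3).
#' @return Value in \[0, 1\], or `NA` if the window does not fit.
#' @export
point_torsion <- function(branch, index, window = 5L) {
  stopifnot(window >= 3, window %% 2 == 1)
  half <- window %/% 2L
  n <- nrow(branch)
  if (index - half < 1 || index + half > n) return(NA_real_)
  branch_torsion(branch[(index - half):(index + half), , drop = FALSE])
}

branch_point_torsions <- function(branch, window) {
  half <- window %/% 2L
  n <- nrow(branch)
  if (n < window) return(numeric(0))
  vapply((1 + half):(n - half), function(i) point_torsion(branch, i, window),
         numeric(1))
}

stats5 <- function(x) {
  if (length(x) == 0) return(c(mean = 0, std = 0, min = 0, max = 0, median = 0))
  c(mean = mean(x), std = if (length(x) > 1) sd(x) else 0,
    min = min(x), max = max(x), median = median(x))
}

hist_norm <- function(x, edges) {
  nb <- length(edges) - 1
  if (length(x) == 0) return(rep(0, nb))
  b <- findInterval(x, edges, rightmost.closed = TRUE)
  b[b < 1] <- 1
  b[b > nb] <- nb  # last bin open above
  tabulate(b, nbins = nb) / length(x)
}

#' Compute the 35 QVT features for one case
#'
#' @param tree a [vessel_tree()] of the segmented vasculature centerlines.
#' @param vessel_mask the segmented vasculature [binary_mask()].
#' @param voi an [roi()] around the nodule; volume features are computed
#'   inside it.
#' @param cfg a [qvt_config()].
#' @return Named numeric vector of length 35 (see [qvt_feature_names()]),
#'   with attribute `degenerate = TRUE` when the tree had no eligible branch.
#'   All entries are finite; degenerate statistics are 0, never NaN.
#' @export
compute_qvt <- function(tree, vessel_mask, voi, cfg = qvt_config()) {
  stopifnot(inherits(tree, "vessel_tree"), inherits(vessel_mask, "binary_mask"),
            inherits(voi, "roi"))
  dm <- dim(vessel_mask$values)
  if (any(voi$upper > dm)) stopf("compute_qvt: VOI exceeds the mask grid")
  nms <- qvt_feature_names(cfg)

  if (length(tree$branches) == 0) {
    out <- setNames(rep(0, length(nms)), nms)
    attr(out, "degenerate") <- TRUE
    return(out)
  }

  elig <- Filter(function(b) nrow(b) >= cfg$min_branch_length, tree$branches)
  degenerate <- length(elig) == 0

  if (degenerate) {
    tors <- curv_mean <- curv_max <- numeric(0)
    pt_curv <- pt_tors <- numeric(0)
  } else {
    tors <- vapply(elig, branch_torsion, numeric(1))
    curv_list <- lapply(elig, polyline_curvatures)
    curv_mean <- vapply(curv_list, mean, numeric(1))
    curv_max <- vapply(curv_list, max, numeric(1))
    pt_curv <- unlist(curv_list)
    pt_tors <- unlist(lapply(elig, branch_point_torsions,
                             window = cfg$torsion_window))
    pt_tors <- pt_tors[is.finite(pt_tors)]
  }

  ix <- roi_index(voi)
  sub <- vessel_mask$values[ix$x, ix$y, ix$z, drop = FALSE]
  voxvol <- prod(vessel_mask$spacing)
  vol_mm3 <- sum(sub) * voxvol
  voi_mm3 <- roi_volume_mm3(voi, vessel_mask$spacing)
  bbox_ratio <- 0
  if (any(sub)) {
    lin <- which(sub) - 1L
    ijk <- lin_to_ijk(lin, dim(sub))
    ext <- (apply(ijk, 2, max) - apply(ijk, 2, min) + 1) * vessel_mask$spacing
    bbox_ratio <- vol_mm3 / prod(ext)
  }

  out <- c(stats5(tors), stats5(curv_mean), stats5(curv_max),
           length(elig), nrow(tree$bifurcations),
           vol_mm3, vol_mm3 / voi_mm3, bbox_ratio,
           hist_norm(pt_curv, cfg$curvature_hist_edges),
           hist_norm(pt_tors, cfg$torsion_hist_edges))
  out <- setNames(as.numeric(out), nms)
  out[!is.finite(out)] <- 0
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}
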