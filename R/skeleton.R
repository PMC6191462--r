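# Centerline extraction from a vessel mask.
#
# Scheme: per connected component, a front is propagated from the most interior
# voxel (global maximum of the Euclidean distance map) with a speed that
# increases with distance-to-boundary, so that minimal-arrival paths run along
# the vessel centre. Branches are peeled off iteratively: the farthest
# still-uncovered voxel is back-traced along the arrival-time descent until it
# meets the existing skeleton; territory within (distance-to-boundary +
# tolerance) of the skeleton is marked covered; iteration stops when nothing
# uncovered remains.

#' Construct a vessel tree
#'
#' @param branches list of `n x 3` matrices of ordered centerline points (mm),
#'   each with at least 2 points and no consecutive duplicates.
#' @param node_types optional list of length-2 character vectors
#'   (`"terminal"` or `"bifurcation"`) classifying each branch's endpoints.
#' @param bifurcations optional `m x 3` matrix of bifurcation points (mm).
#' @param degenerate flag set when the input admitted no usable centerline.
#' @return An object of class `vessel_tree`.
#' @export
vessel_tree <- function(branches, node_types = NULL, bifurcations = NULL,
                        degenerate = FALSE) {
  stopifnot(is.list(branches))
  branches <- lapply(branches, function(b) {
    b <- matrix(as.numeric(b), ncol = 3)
    b <- dedupe_polyline(b)
    if (nrow(b) < 2) stopf("vessel_tree: branch with fewer than 2 distinct points")
    unname(b)
  })
  if (is.null(bifurcations)) bifurcations <- matrix(numeric(0), ncol = 3)
  bifurcations <- matrix(as.numeric(bifurcations), ncol = 3)
  if (is.null(node_types)) {
    node_types <- lapply(branches, function(b) {
      classify_ends(b, bifurcations)
    })
  }
  structure(list(branches = branches, node_types = node_types,
                 bifurcations = bifurcations, degenerate = isTRUE(degenerate)),
            class = "vessel_tree")
}

classify_ends <- function(b, bifurcations, tol = 1e-6) {
  ends <- rbind(b[1, ], b[nrow(b), ])
  vapply(1:2, function(i) {
    if (nrow(bifurcations) > 0 &&
        min(sqrt(rowSums(sweep(bifurcations, 2, ends[i, ])^2))) < tol + 1e-9) {
      "bifurcation"
    } else "terminal"
  }, character(1))
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d branches, %d bifurcations, total length %.2f mm%s\n",
              length(x$branches), nrow(x$bifurcations),
              sum(vapply(x$branches, polyline_arclength, numeric(1))),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Spacing-aware Euclidean distance map of a mask
#'
#' For every foreground voxel, the Euclidean distance in mm to the centre of
#' the nearest background voxel; 0 on the background.
#'
#' @param mask a [binary_mask()] with at least one foreground voxel.
#' @return An [image_volume()] whose values are distances in mm.
#' @export
distance_map <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$values)) stopf("distance_map: empty mask")
  d2 <- cpp_edt_sq(as.integer(mask$values), dim(mask$values), mask$spacing)
  vals <- array(sqrt(d2), dim = dim(mask$values))
  # a mask with no background at all leaves foreground at infinity
  vals[!is.finite(vals)] <- max(dim(mask$values) * mask$spacing)
  image_volume(vals, mask$spacing, mask$origin)
}

# drop the off-axis hook a back-trace picks up before it reaches the medial
# axis: trim leading points while the arc travelled is still shorter than the
# largest distance-to-boundary seen so far (the medial axis of a capped tube
# starts one radius away from the cap).
trim_lead <- function(path_lin, dvals, xyz) {
  n <- length(path_lin)
  if (n < 3) return(seq_len(n))
  arc <- c(0, cumsum(sqrt(rowSums(diff(xyz)^2))))
  runmax <- cummax(dvals)
  i <- 1L
  while (i < n - 1L && arc[i] < runmax[i]) i <- i + 1L
  i:n
}

#' Extract a centerline tree from a vessel mask
#'
#' @param mask a [binary_mask()] of the segmented vasculature.
#' @param centeredness_power exponent of the distance-weighted front speed;
#'   larger values pull minimal paths more strongly to the vessel centre.
#' @param endpoint_tolerance_mm stop peeling branches once every foreground
#'   voxel is within (local radius + tolerance) of the skeleton; default twice
#'   the mean voxel spacing.
#' @param resample_step_mm uniform arc-length resampling step of the output
#'   polylines; default the smallest voxel spacing.
#' @param smooth logical; apply a short moving-average to the voxel-chain
#'   polylines (sub-voxel positioning) before resampling.
#' @param max_branches safety cap on peeled branches per component.
#' @return A [vessel_tree()].
#' @export
extract_tree <- function(mask, centeredness_power = 6,
                         endpoint_tolerance_mm = NULL,
                         resample_step_mm = NULL, smooth = TRUE,
                         max_branches = 2000L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$values)) stopf("extract_tree: empty mask")
  dm <- dim(mask$values)
  spacing <- mask$spacing
  if (is.null(endpoint_tolerance_mm)) endpoint_tolerance_mm <- 2 * mean(spacing)
  if (is.null(resample_step_mm)) resample_step_mm <- min(spacing)

  D <- distance_map(mask)$values
  lab <- array(cpp_label_components(as.integer(mask$values), dm, 26L), dim = dm)
  n_comp <- max(lab)

  all_branches <- list()
  all_bif <- matrix(numeric(0), ncol = 3)
  degenerate <- FALSE

  for (comp in seq_len(n_comp)) {
    compmask <- lab == comp
    idx0 <- which(compmask) - 1L   # 0-based linear indices
    if (length(idx0) < 2) { degenerate <- TRUE; next }
    Dv <- as.numeric(D)
    speed <- (Dv / max(Dv[idx0 + 1L]) + 1e-3)^centeredness_power
    # source: most interior voxel, ties to the lowest linear index
    src <- idx0[which.max(Dv[idx0 + 1L])]
    Tarr <- cpp_arrival_time(as.integer(compmask), dm, spacing, speed, src)

    skel <- integer(prod(dm))
    skel[src + 1L] <- 1L
    covered <- integer(prod(dm))
    paths <- list()   # voxel-chain branches: list of 0-based linear index vectors

    for (iter in seq_len(max_branches)) {
      unc <- idx0[covered[idx0 + 1L] == 0L]
      if (length(unc) == 0) break
      if (any(covered == 1L)) {
        # stop rule: only peel a branch towards points farther than the
        # endpoint tolerance from territory already covered
        d2cov <- cpp_edt_sq(1L - covered, dm, spacing)
        unc <- unc[d2cov[unc + 1L] > endpoint_tolerance_mm^2]
        if (length(unc) == 0) break
      }
      tv <- Tarr[unc + 1L]
      if (!any(is.finite(tv))) break
      target <- unc[which.max(tv)]
      path <- cpp_backtrace(Tarr, dm, target, skel)
      # coverage along the full untrimmed path
      cpp_stamp_balls(covered, dm, spacing, path,
                      Dv[path + 1L] + endpoint_tolerance_mm)
      if (length(path) < 2) { covered[target + 1L] <- 1L; next }
      xyz <- ijk_to_world(lin_to_ijk(path, dm), spacing, mask$origin)
      keep <- trim_lead(path, Dv[path + 1L], xyz)
      path <- path[keep]
      if (length(path) < 2) next
      skel[path + 1L] <- 1L
      paths <- attach_path(paths, path)
    }

    paths <- prune_spurs(paths, Dv, dm, spacing, endpoint_tolerance_mm)
    built <- build_branches(paths, dm, spacing, mask$origin, mask$values,
                            resample_step_mm, smooth)
    all_branches <- c(all_branches, built$branches)
    if (nrow(built$bifurcations) > 0) all_bif <- rbind(all_bif, built$bifurcations)
    if (length(built$branches) == 0) degenerate <- TRUE
  }

  if (length(all_branches) == 0) {
    return(vessel_tree(list(), degenerate = TRUE))
  }
  vessel_tree(all_branches, bifurcations = all_bif, degenerate = degenerate)
}

# Attach a new voxel path (ordered tip -> attach point) to the running set of
# branch chains, splitting an existing branch when the attach point falls in
# its interior and merging when it extends a free end.
attach_path <- function(paths, path) {
  if (length(paths) == 0) return(list(path))
  a <- path[length(path)]
  hit <- NULL; pos <- NULL
  for (b in seq_along(paths)) {
    w <- which(paths[[b]] == a)
    if (length(w) > 0) { hit <- b; pos <- w[1]; break }
  }
  if (is.null(hit)) {
    # attach voxel adjacent to skeleton but not on a stored chain (can happen
    # for the source voxel before any chain exists through it): keep as is
    return(c(paths, list(path)))
  }
  bvox <- paths[[hit]]
  m <- length(bvox)
  if (pos > 1 && pos < m) {
    # interior attach: split into two and add the new branch (bifurcation at a)
    paths[[hit]] <- bvox[1:pos]
    paths <- c(paths, list(bvox[pos:m]), list(path))
  } else {
    # endpoint attach: degree-2 join extends the branch, otherwise bifurcation
    degree <- sum(vapply(paths, function(p) p[1] == a || p[length(p)] == a, logical(1)))
    if (degree == 1) {
      joined <- if (pos == 1) c(rev(path), bvox[-1]) else c(bvox, rev(path)[-1])
      paths[[hit]] <- joined
    } else {
      paths <- c(paths, list(path))
    }
  }
  paths
}

# Remove terminal spurs: chains with a free tip whose arc length is small
# compared to the vessel radius at their attachment point are artefacts of
# surface bumps, not true side branches. Degree-2 junctions left behind by a
# removed spur are merged back into a single chain.
prune_spurs <- function(paths, Dv, dm, spacing, tol_mm) {
  chain_arc <- function(p) {
    xyz <- ijk_to_world(lin_to_ijk(p, dm), spacing, c(0, 0, 0))
    if (nrow(xyz) < 2) 0 else polyline_arclength(xyz)
  }
  repeat {
    if (length(paths) <= 1) return(paths)
    ends <- unlist(lapply(paths, function(p) c(p[1], p[length(p)])))
    endtab <- table(ends)
    degree <- function(v) endtab[[as.character(v)]]
    drop <- NULL
    for (b in seq_along(paths)) {
      p <- paths[[b]]
      d1 <- degree(p[1]); d2 <- degree(p[length(p)])
      if (xor(d1 == 1, d2 == 1)) {
        attach <- if (d1 == 1) p[length(p)] else p[1]
        thr <- 1.5 * Dv[attach + 1L] + tol_mm
        if (chain_arc(p) < thr) { drop <- c(drop, b) }
      }
    }
    if (is.null(drop)) break
    paths <- paths[-drop]
    # merge chains that now meet end-to-end with no third chain
    repeat {
      if (length(paths) < 2) break
      ends <- unlist(lapply(paths, function(p) c(p[1], p[length(p)])))
      endtab <- table(ends)
      j <- as.integer(names(endtab)[endtab == 2])
      merged <- FALSE
      for (v in j) {
        at <- which(vapply(paths, function(p) p[1] == v || p[length(p)] == v,
                           logical(1)))
        if (length(at) != 2) next
        a <- paths[[at[1]]]; b <- paths[[at[2]]]
        if (a[1] == v) a <- rev(a)
        if (b[length(b)] == v) b <- rev(b)
        paths[[at[1]]] <- c(a, b[-1])
        paths <- paths[-at[2]]
        merged <- TRUE
        break
      }
      if (!merged) break
    }
  }
  paths
}

build_branches <- function(paths, dm, spacing, origin, maskvals,
                           resample_step_mm, smooth) {
  branches <- list()
  # bifurcations: voxels shared by >= 3 chain endpoints
  ends <- unlist(lapply(paths, function(p) c(p[1], p[length(p)])))
  endtab <- table(ends)
  bif_vox <- as.integer(names(endtab)[endtab >= 3])
  for (p in paths) {
    if (length(p) < 2) next
    xyz <- ijk_to_world(lin_to_ijk(p, dm), spacing, origin)
    if (smooth && nrow(xyz) >= 3) {
      sm <- smooth_polyline(xyz, 5L)
      # keep smoothed points only while they stay inside the mask
      idx <- world_to_ijk(sm, spacing, origin)
      ok <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
        idx[, 1] < dm[1] & idx[, 2] < dm[2] & idx[, 3] < dm[3]
      lin <- ijk_to_lin(pmax(idx, 0), dm) + 1
      ok[ok] <- maskvals[lin[ok]]
      sm[!ok, ] <- xyz[!ok, ]
      xyz <- sm
    }
    xyz <- dedupe_polyline(xyz)
    if (nrow(xyz) < 2) next
    xyz <- resample_polyline(xyz, resample_step_mm)
    if (nrow(xyz) < 2) next
    branches[[length(branches) + 1L]] <- xyz
  }
  bifs <- if (length(bif_vox) > 0) {
    ijk_to_world(lin_to_ijk(bif_vox, dm), spacing, origin)
  } else matrix(numeric(0), ncol = 3)
  list(branches = branches, bifurcations = bifs)
}

#' Branch, bifurcation and length statistics of a tree
#'
#' @param tree a [vessel_tree()].
#' @param min_branch_length minimum number of polyline points for a branch to
#'   count as eligible.
#' @return A list with `n_branches`, `n_bifurcations` and `total_length_mm`
#'   over eligible branches.
#' @export
branch_stats <- function(tree, min_branch_length = 5L) {
  stopifnot(inherits(tree, "vessel_tree"))
  elig <- Filter(function(b) nrow(b) >= min_branch_length, tree$branches)
  list(n_branches = length(elig),
       n_bifurcations = nrow(tree$bifurcations),
       total_length_mm = if (length(elig)) {
         sum(vapply(elig, polyline_arclength, numeric(1)))
       } else 0)
}

# Apply a rigid transform (3x3 rotation + translation) to a tree.
transform_tree <- function(tree, R = diag(3), t = c(0, 0, 0)) {
  branches <- lapply(tree$branches, function(b) sweep(b %*% t(R), 2, t, `+`))
  bif <- if (nrow(tree$bifurcations) > 0) {
    sweep(tree$bifurcations %*% t(R), 2, t, `+`)
  } else tree$bifurcations
  vessel_tree(branches, node_types = tree$node_types, bifurcations = bif,
              degenerate = tree$degenerate)
}
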