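# Synthetic vascular phantoms.
#
# The generator emulates the imaging situation the pipeline is built for: a
# lung-like low-attenuation cavity (-850 HU) inside a soft-tissue body
# (+40 HU) surrounded by air (-1000 HU), containing a nodule blob and a
# branching vessel tree at vessel/nodule intensity (+50 HU), rasterized into a
# noisy Hounsfield volume. Every case carries its analytic ground truth
# (centerline tree, noise-free vessel mask, nodule mask, class label), so each
# downstream stage can be validated against a known answer.

#' Phantom generation parameters
#'
#' @param tree_topology number of bifurcations (>= 0).
#' @param segment_length_mm length of the root vessel segment; child segments
#'   shrink by `child_scale` per generation.
#' @param tube_radius_mm vessel tube radius (> 0).
#' @param tortuosity_amplitude amplitude (mm) of the sinusoidal centerline
#'   displacement; 0 gives straight segments.
#' @param vessel_hu,background_hu,body_hu,air_hu intensities of
#'   vessel/nodule, lung parenchyma, chest body and exterior air.
#' @param noise_sigma_hu Gaussian noise standard deviation (>= 0).
#' @param spacing_mm length-3 voxel spacing (> 0).
#' @param volume_shape length-3 voxel counts.
#' @param nodule_radius_mm radius of the nodule sphere placed at the tree root.
#' @param rng_seed integer seed; identical specs (including the seed) give
#'   bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(tree_topology = 2L, segment_length_mm = 9,
                         tube_radius_mm = 1.2, tortuosity_amplitude = 0.5,
                         vessel_hu = 50, background_hu = -850, body_hu = 40,
                         air_hu = -1000, noise_sigma_hu = 20,
                         spacing_mm = c(0.5, 0.5, 0.5),
                         volume_shape = c(64L, 64L, 64L),
                         nodule_radius_mm = 3, rng_seed = 1L) {
  stopifnot(tree_topology >= 0, tube_radius_mm > 0, all(spacing_mm > 0),
            noise_sigma_hu >= 0, segment_length_mm > 0, nodule_radius_mm > 0,
            length(spacing_mm) == 3, length(volume_shape) == 3)
  structure(list(tree_topology = as.integer(tree_topology),
                 segment_length_mm = segment_length_mm,
                 tube_radius_mm = tube_radius_mm,
                 tortuosity_amplitude = tortuosity_amplitude,
                 vessel_hu = vessel_hu, background_hu = background_hu,
                 body_hu = body_hu, air_hu = air_hu,
                 noise_sigma_hu = noise_sigma_hu,
                 spacing_mm = as.numeric(spacing_mm),
                 volume_shape = as.integer(volume_shape),
                 nodule_radius_mm = nodule_radius_mm,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Analytic parametric centerlines
#'
#' Oracle curves with known curvature/torsion used to validate the feature
#' definitions: straight line, circular arc, helix and planar sine wave.
#'
#' @param kind one of `"line"`, `"arc"`, `"helix"`, `"sine"`.
#' @param params named list of geometry parameters (mm / radians):
#'   line: `length`, optional `start`, `direction`;
#'   arc: `radius`, `angle`, optional `center`;
#'   helix: `radius`, `pitch` (the `c` in `z = c * theta`), and `turns` or
#'   `length` (arc length);
#'   sine: `amplitude`, `wavelength`, `length`.
#' @param step_mm target arc-length spacing of consecutive points (> 0).
#' @return An `n x 3` matrix of ordered points (mm).
#' @export
make_parametric_centerline <- function(kind = c("line", "arc", "helix", "sine"),
                                       params, step_mm) {
  kind <- match.arg(kind)
  if (!is.numeric(step_mm) || step_mm <= 0) {
    stopf("make_parametric_centerline: step_mm must be > 0")
  }
  p <- params
  switch(kind,
    line = {
      if (is.null(p$length) || p$length <= 0) stopf("line: positive length required")
      start <- p$start %||% c(0, 0, 0)
      dir <- p$direction %||% c(1, 0, 0)
      dir <- dir / sqrt(sum(dir^2))
      t <- seq(0, p$length, by = step_mm)
      if (tail(t, 1) < p$length) t <- c(t, p$length)
      outer(t, dir) + matrix(start, length(t), 3, byrow = TRUE)
    },
    arc = {
      if (is.null(p$radius) || p$radius <= 0) stopf("arc: positive radius required")
      if (is.null(p$angle) || p$angle <= 0) stopf("arc: positive angle required")
      centre <- p$center %||% c(0, 0, 0)
      dth <- step_mm / p$radius
      th <- seq(0, p$angle, by = dth)
      if (tail(th, 1) < p$angle) th <- c(th, p$angle)
      cbind(centre[1] + p$radius * cos(th),
            centre[2] + p$radius * sin(th),
            centre[3])
    },
    helix = {
      if (is.null(p$radius) || p$radius <= 0) stopf("helix: positive radius required")
      cc <- p$pitch %||% stopf("helix: pitch parameter required")
      speed <- sqrt(p$radius^2 + cc^2)
      thmax <- if (!is.null(p$length)) p$length / speed
               else 2 * pi * (p$turns %||% 2)
      th <- seq(0, thmax, by = step_mm / speed)
      if (tail(th, 1) < thmax) th <- c(th, thmax)
      cbind(p$radius * cos(th), p$radius * sin(th), cc * th)
    },
    sine = {
      if (is.null(p$length) || p$length <= 0) stopf("sine: positive length required")
      A <- p$amplitude %||% 1
      lam <- p$wavelength %||% stopf("sine: wavelength required")
      # invert the arc length numerically so output points lie on the curve
      xf <- seq(0, p$length, by = min(step_mm, lam) / 50)
      yf <- A * sin(2 * pi * xf / lam)
      s <- c(0, cumsum(sqrt(diff(xf)^2 + diff(yf)^2)))
      si <- seq(0, tail(s, 1), by = step_mm)
      if (tail(si, 1) < tail(s, 1)) si <- c(si, tail(s, 1))
      x <- approx(s, xf, xout = si, ties = "ordered")$y
      cbind(x, A * sin(2 * pi * x / lam), 0)
    })
}

# Random branching centerline tree with sinusoidal tortuosity. Displacement is
# zero at segment ends (integer half-waves), so branches stay connected at
# bifurcations whatever the amplitude.
#' Generate a random phantom centerline tree
#'
#' @param n_bifurcations number of bifurcation events (>= 0).
#' @param segment_length_mm root segment length; children shrink by
#'   `child_scale` each generation.
#' @param tortuosity_amplitude sinusoidal displacement amplitude (mm).
#' @param root length-3 root position (mm).
#' @param direction initial growth direction.
#' @param seed integer seed.
#' @param step_mm point spacing along segments.
#' @param wavelength_mm wavelength of the tortuosity displacement; default
#'   half the segment length.
#' @param branch_angle_deg half-angle between child segments.
#' @param child_scale length shrink factor per generation.
#' @return A [vessel_tree()] whose branch count is `2 * n_bifurcations + 1`.
#' @export
make_phantom_tree <- function(n_bifurcations = 2L, segment_length_mm = 9,
                              tortuosity_amplitude = 0.5,
                              root = c(0, 0, 0), direction = c(1, 0, 0),
                              seed = 1L, step_mm = 0.3, wavelength_mm = NULL,
                              branch_angle_deg = 35, child_scale = 0.75) {
  stopifnot(n_bifurcations >= 0, segment_length_mm > 0, tortuosity_amplitude >= 0)
  set.seed(as.integer(seed))
  direction <- direction / sqrt(sum(direction^2))
  if (is.null(wavelength_mm)) wavelength_mm <- segment_length_mm / 2

  make_segment <- function(start, dir, len) {
    t <- seq(0, len, by = step_mm)
    if (tail(t, 1) < len) t <- c(t, len)
    pts <- outer(t, dir) + matrix(start, length(t), 3, byrow = TRUE)
    if (tortuosity_amplitude > 0 && length(t) > 2) {
      basis <- perp_basis(dir)
      k <- max(1L, round(2 * len / wavelength_mm))
      phase <- runif(1, 0, 2 * pi)
      disp <- tortuosity_amplitude * sin(k * pi * t / len)
      u <- cos(phase) * basis$u + sin(phase) * basis$v
      pts <- pts + outer(disp, u)
    }
    pts
  }

  segments <- list()
  # queue of open tips: list(start, dir, len, depth)
  tips <- list(list(start = root, dir = direction, len = segment_length_mm))
  remaining <- n_bifurcations
  while (length(tips) > 0) {
    tip <- tips[[1]]; tips <- tips[-1]
    seg <- make_segment(tip$start, tip$dir, tip$len)
    segments[[length(segments) + 1L]] <- seg
    if (remaining > 0) {
      remaining <- remaining - 1
      endp <- seg[nrow(seg), ]
      ang <- branch_angle_deg * pi / 180
      basis <- perp_basis(tip$dir)
      phi <- runif(1, 0, 2 * pi)
      u <- cos(phi) * basis$u + sin(phi) * basis$v
      d1 <- cos(ang) * tip$dir + sin(ang) * u
      d2 <- cos(ang) * tip$dir - sin(ang) * u
      newlen <- tip$len * child_scale
      tips <- c(tips, list(list(start = endp, dir = d1, len = newlen),
                           list(start = endp, dir = d2, len = newlen)))
    }
  }
  bif <- if (n_bifurcations > 0) {
    do.call(rbind, lapply(segments[seq_len(n_bifurcations)],
                          function(s) s[nrow(s), , drop = FALSE]))
  } else NULL
  vessel_tree(segments, bifurcations = bif)
}

perp_basis <- function(dir) {
  a <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * dir) * dir
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  list(u = u, v = v)
}

#' Rasterize a centerline tree into a voxel tube mask and HU volume
#'
#' A voxel is foreground iff its centre lies within `tube_radius_mm` of the
#' tree polylines (point-to-segment distance in world mm). Gaussian noise is
#' added to the returned volume only; the truth mask is noise-free.
#'
#' @param tree a [vessel_tree()] (may be empty).
#' @param tube_radius_mm tube radius (> 0).
#' @param spacing,shape,origin grid geometry.
#' @param vessel_hu,background_hu,noise_sigma_hu intensities and noise.
#' @param seed noise seed.
#' @return A list with `volume` ([image_volume()]) and `truth_vessel_mask`
#'   ([binary_mask()]).
#' @export
rasterize_tree <- function(tree, tube_radius_mm, spacing, shape,
                           vessel_hu = 50, background_hu = -850,
                           noise_sigma_hu = 0, seed = 1L,
                           origin = c(0, 0, 0)) {
  stopifnot(tube_radius_mm > 0, all(spacing > 0))
  shape <- as.integer(shape)
  extent_lo <- origin
  extent_hi <- origin + (shape - 1) * spacing
  segs <- tree_segments(tree)
  if (nrow(segs$A) > 0) {
    pts <- rbind(segs$A, segs$B)
    if (any(sweep(pts, 2, extent_lo, `<`)) || any(sweep(pts, 2, extent_hi, `>`))) {
      stopf("rasterize_tree: tree extends outside the grid extent")
    }
    m <- cpp_rasterize_segments(segs$A, segs$B, shape, spacing, origin,
                                tube_radius_mm)
    maskvals <- array(m == 1L, dim = shape)
  } else {
    maskvals <- array(FALSE, dim = shape)
  }
  vol <- array(background_hu, dim = shape)
  vol[maskvals] <- vessel_hu
  if (noise_sigma_hu > 0) {
    set.seed(as.integer(seed))
    vol <- vol + array(rnorm(prod(shape), 0, noise_sigma_hu), dim = shape)
  }
  list(volume = image_volume(vol, spacing, origin),
       truth_vessel_mask = binary_mask(maskvals, spacing, origin))
}

tree_segments <- function(tree) {
  if (!inherits(tree, "vessel_tree") || length(tree$branches) == 0) {
    return(list(A = matrix(numeric(0), ncol = 3), B = matrix(numeric(0), ncol = 3)))
  }
  A <- do.call(rbind, lapply(tree$branches, function(b) b[-nrow(b), , drop = FALSE]))
  B <- do.call(rbind, lapply(tree$branches, function(b) b[-1, , drop = FALSE]))
  list(A = A, B = B)
}

#' Generate one complete phantom case
#'
#' Assembles the full scene: exterior air shell, soft-tissue body, ellipsoidal
#' lung cavity, nodule sphere at the vessel-tree root, and the rasterized
#' vessel tree, with Gaussian noise over the whole volume.
#'
#' @param spec a [phantom_spec()].
#' @param class_label `"adeno-like"` or `"granuloma-like"` (carried through to
#'   cohort tables).
#' @return An object of class `phantom_case`: fields `volume`, `clean_volume`,
#'   `truth_vessel_mask`, `truth_tree`, `nodule_mask`, `class_label`, `spec`.
#' @export
make_phantom_case <- function(spec, class_label = "adeno-like") {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$volume_shape
  spacing <- spec$spacing_mm
  origin <- c(0, 0, 0)
  extent <- (shape - 1) * spacing
  centre <- origin + extent / 2

  # tree grows from a root placed off-centre so it fits inside the cavity
  set.seed(spec$rng_seed)
  root <- centre - c(0.28, 0, 0) * extent
  tree <- make_phantom_tree(
    n_bifurcations = spec$tree_topology,
    segment_length_mm = spec$segment_length_mm,
    tortuosity_amplitude = spec$tortuosity_amplitude,
    root = root, direction = c(1, 0, 0),
    seed = derive_seed(spec$rng_seed, "tree"))

  ras <- rasterize_tree(tree, spec$tube_radius_mm, spacing, shape,
                        vessel_hu = spec$vessel_hu,
                        background_hu = spec$background_hu,
                        noise_sigma_hu = 0, origin = origin)
  vessel <- ras$truth_vessel_mask$values

  idx <- expand_grid_coords(shape, spacing, origin)
  # exterior air shell (2 voxels), body, ellipsoidal lung cavity
  vol <- array(spec$body_hu, dim = shape)
  border <- 2L
  shell <- idx$i < border | idx$j < border | idx$k < border |
    idx$i >= shape[1] - border | idx$j >= shape[2] - border |
    idx$k >= shape[3] - border
  semi <- extent / 2 - border * spacing - 2.5  # keep a solid body wall
  lung <- ((idx$x - centre[1]) / semi[1])^2 +
    ((idx$y - centre[2]) / semi[2])^2 +
    ((idx$z - centre[3]) / semi[3])^2 <= 1
  vol[lung] <- spec$background_hu
  nod <- (idx$x - root[1])^2 + (idx$y - root[2])^2 + (idx$z - root[3])^2 <=
    spec$nodule_radius_mm^2
  nodule <- array(nod & lung, dim = shape)
  vessel <- vessel & lung
  vol[vessel] <- spec$vessel_hu
  vol[nodule] <- spec$vessel_hu
  vol[array(shell, dim = shape)] <- spec$air_hu
  clean <- vol
  if (spec$noise_sigma_hu > 0) {
    set.seed(derive_seed(spec$rng_seed, "noise"))
    vol <- vol + array(rnorm(prod(shape), 0, spec$noise_sigma_hu), dim = shape)
  }
  structure(list(volume = image_volume(vol, spacing, origin),
                 clean_volume = image_volume(clean, spacing, origin),
                 truth_vessel_mask = binary_mask(array(vessel, dim = shape),
                                                 spacing, origin),
                 truth_tree = tree,
                 nodule_mask = binary_mask(nodule, spacing, origin),
                 class_label = class_label, spec = spec),
            class = "phantom_case")
}

expand_grid_coords <- function(shape, spacing, origin) {
  i <- rep(0:(shape[1] - 1L), times = shape[2] * shape[3])
  j <- rep(rep(0:(shape[2] - 1L), each = shape[1]), times = shape[3])
  k <- rep(0:(shape[3] - 1L), each = shape[1] * shape[2])
  list(i = i, j = j, k = k,
       x = origin[1] + i * spacing[1],
       y = origin[2] + j * spacing[2],
       z = origin[3] + k * spacing[3])
}

#' Generate a balanced labelled phantom cohort
#'
#' Per-case tortuosity amplitudes are drawn from a class-specific normal
#' distribution (truncated at 0); per-case seeds are derived deterministically
#' from the master seed. The defaults plant a strong class effect: the
#' adeno-like class receives markedly more tortuous vasculature than the
#' granuloma-like class.
#'
#' @param n_per_class cases per class (>= 1).
#' @param class_params list with elements `adeno` and `granuloma`, each
#'   `c(mean, sd)` of the tortuosity amplitude in mm (`sd >= 0`).
#' @param seed master seed.
#' @param base_spec template [phantom_spec()]; its amplitude and seed fields
#'   are overridden per case.
#' @return A list with `cases` (list of [make_phantom_case()] results) and
#'   `manifest` (data.frame: case_id, label, amplitude, seed).
#' @export
make_cohort <- function(n_per_class,
                        class_params = list(adeno = c(mean = 2.2, sd = 0.4),
                                            granuloma = c(mean = 0.4, sd = 0.15)),
                        seed = 1L, base_spec = phantom_spec()) {
  stopifnot(n_per_class >= 1)
  for (cp in class_params) {
    if (cp[["sd"]] < 0) stopf("make_cohort: negative amplitude sd")
  }
  labels <- c(rep("adeno-like", n_per_class), rep("granuloma-like", n_per_class))
  dists <- c(rep("adeno", n_per_class), rep("granuloma", n_per_class))
  set.seed(as.integer(seed))
  amps <- vapply(dists, function(d) {
    max(0, rnorm(1, class_params[[d]][["mean"]], class_params[[d]][["sd"]]))
  }, numeric(1))
  cases <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sp <- base_spec
    sp$tortuosity_amplitude <- amps[i]
    sp$rng_seed <- derive_seed(seed, paste0("case-", i))
    cases[[i]] <- make_phantom_case(sp, class_label = labels[i])
  }
  manifest <- data.frame(case_id = sprintf("case%03d", seq_along(labels)),
                         label = labels, amplitude = amps,
                         seed = vapply(cases, function(cs) cs$spec$rng_seed,
                                       numeric(1)))
  list(cases = cases, manifest = manifest)
}

#' Perturbed re-test copy of a phantom case
#'
#' Emulates a same-day repeat acquisition: the noise field is re-drawn and the
#' scene can be rigidly shifted by a sub-voxel amount (trilinear resampling).
#' The ground-truth tree and masks are carried through the same shift.
#'
#' @param case a [make_phantom_case()] result.
#' @param perturbation list with `noise_sigma_hu` (>= 0; defaults to the
#'   case's own noise level) and `shift_mm` (length-3, defaults to no shift).
#' @param seed noise seed for the re-drawn noise field.
#' @return A `phantom_case` for the re-test acquisition.
#' @export
make_test_retest <- function(case, perturbation = list(), seed = 1L) {
  stopifnot(inherits(case, "phantom_case"))
  sigma <- perturbation$noise_sigma_hu %||% case$spec$noise_sigma_hu
  shift <- perturbation$shift_mm %||% c(0, 0, 0)
  if (sigma < 0 || length(shift) != 3) stopf("make_test_retest: invalid perturbation")
  clean <- case$clean_volume$values
  spacing <- case$clean_volume$spacing
  if (any(shift != 0)) {
    clean <- shift_volume(clean, shift / spacing, pad = case$spec$air_hu)
    vess <- shift_volume(case$truth_vessel_mask$values + 0, shift / spacing, pad = 0) > 0.5
    nod <- shift_volume(case$nodule_mask$values + 0, shift / spacing, pad = 0) > 0.5
    tree <- transform_tree(case$truth_tree, diag(3), shift)
  } else {
    vess <- case$truth_vessel_mask$values
    nod <- case$nodule_mask$values
    tree <- case$truth_tree
  }
  vol <- clean
  if (sigma > 0) {
    set.seed(as.integer(seed))
    vol <- vol + array(rnorm(length(clean), 0, sigma), dim = dim(clean))
  }
  out <- case
  out$volume <- image_volume(vol, spacing, case$volume$origin)
  out$clean_volume <- image_volume(clean, spacing, case$volume$origin)
  out$truth_vessel_mask <- binary_mask(vess, spacing, case$volume$origin)
  out$nodule_mask <- binary_mask(nod, spacing, case$volume$origin)
  out$truth_tree <- tree
  out
}

# Trilinear shift of a 3D array by a (possibly fractional) voxel offset:
# out(x) = in(x - shift). Outside voxels take `pad`.
shift_volume <- function(arr, shift_vox, pad = 0) {
  w <- floor(shift_vox)
  f <- shift_vox - w
  out <- array(0, dim = dim(arr))
  for (a in 0:1) for (b in 0:1) for (c in 0:1) {
    wt <- (if (a) f[1] else 1 - f[1]) * (if (b) f[2] else 1 - f[2]) *
      (if (c) f[3] else 1 - f[3])
    if (wt == 0) next
    out <- out + wt * shift_int(arr, c(w[1] + a, w[2] + b, w[3] + c), pad)
  }
  out
}

shift_int <- function(arr, s, pad) {
  d <- dim(arr)
  out <- array(pad, dim = d)
  src <- lapply(1:3, function(ax) {
    lo <- max(1, 1 - s[ax]); hi <- min(d[ax], d[ax] - s[ax])
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(vapply(src, length, integer(1)) == 0)) return(out)
  dst <- lapply(1:3, function(ax) src[[ax]] + s[ax])
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}
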