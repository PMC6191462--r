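# The 35-feature descriptor: curvature, torsion, volumes, histograms.

test_that("Menger curvature matches circle geometry and handles degeneracy", {
  expect_equal(menger_curvature(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(menger_curvature(c(5, 0, 0), c(0, 5, 0), c(-5, 0, 0)), 0.2)
  expect_equal(menger_curvature(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0)), 1.0)
  expect_error(menger_curvature(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "coincident")

  # any 3 points on a circle of radius r: curvature 1/r, and the independent
  # Heron-formula oracle agrees
  set.seed(4)
  for (i in 1:20) {
    r <- runif(1, 0.5, 20)
    th <- sort(runif(3, 0, 2 * pi))
    p <- lapply(th, function(t) c(r * cos(t), r * sin(t), 0))
    expect_equal(menger_curvature(p[[1]], p[[2]], p[[3]]), 1 / r, tolerance = 1e-9)
    expect_equal(menger_curvature(p[[1]], p[[2]], p[[3]]),
                 menger_heron_oracle(p[[1]], p[[2]], p[[3]]), tolerance = 1e-9)
  }
})

test_that("curvature is scale-covariant: scaling points by s divides kappa by s", {
  set.seed(7)
  p <- matrix(rnorm(9), 3)
  k1 <- menger_curvature(p[1, ], p[2, ], p[3, ])
  for (s in c(0.1, 2, 117)) {
    expect_equal(menger_curvature(s * p[1, ], s * p[2, ], s * p[3, ]), k1 / s,
                 tolerance = 1e-12)
  }
})

test_that("branch torsion: straight = 1, semicircle = 2/pi, loop = 0", {
  line <- make_parametric_centerline("line", list(length = 20), 1)
  expect_equal(branch_torsion(line), 1.0)

  semi <- make_parametric_centerline("arc", list(radius = 5, angle = pi), 0.01 * 5)
  expect_equal(branch_torsion(semi), 2 / pi, tolerance = 1e-3)
  # refinement converges towards the analytic value
  coarse <- make_parametric_centerline("arc", list(radius = 5, angle = pi), 0.2 * 5)
  expect_lt(abs(branch_torsion(semi) - 2 / pi), abs(branch_torsion(coarse) - 2 / pi))

  loop <- make_parametric_centerline("arc", list(radius = 3, angle = 2 * pi), 0.05)
  loop[nrow(loop), ] <- loop[1, ]   # close exactly
  expect_equal(branch_torsion(qvtools:::dedupe_polyline(loop)), 0)

  expect_error(branch_torsion(matrix(0, 2, 3)), "zero arc")
})

test_that("point torsion follows the windowed chord/arc definition", {
  line <- make_parametric_centerline("line", list(length = 10), 0.5)
  expect_equal(point_torsion(line, 10, 5), 1.0)
  expect_true(is.na(point_torsion(line, 1, 5)))   # no left window
  expect_true(is.na(point_torsion(matrix(rnorm(12), 4), 2, 5)))  # branch shorter than window

  # fine circle: window chord/arc of arc angle 4*step/r, -> 1 as step -> 0
  for (step in c(0.2, 0.02)) {
    circ <- make_parametric_centerline("arc", list(radius = 2, angle = pi), step)
    i <- nrow(circ) %/% 2
    phi <- 4 * (step / 2)  # window spans 4 steps of arc angle step/r
    analytic <- (2 * 2 * sin(phi / 2)) / (2 * phi)
    expect_equal(point_torsion(circ, i, 5), analytic, tolerance = 1e-3)
  }
})

test_that("the 35-vector is canonical on forced geometries", {
  cfg <- qvt_config()
  expect_length(qvt_feature_names(cfg), 35)

  fx <- tube_fixture(radius = 2, length = 20, spacing = 0.5)
  tree <- extract_tree(fx$mask)
  voi <- roi(c(12, 12, 12), c(52, 52, 52))   # 20 mm cube at 0.5 mm spacing
  f <- compute_qvt(tree, fx$mask, voi, cfg)
  expect_length(f, 35)
  expect_equal(unname(f[paste0("qvt_torsion_", c("mean", "min", "max", "median"))]),
               rep(1, 4), tolerance = 0.02)
  expect_lt(unname(f["qvt_torsion_std"]), 0.02)
  expect_lt(unname(f["qvt_curvMean_mean"]), 0.05)
  expect_equal(unname(f["qvt_nBranches"]), 1)
  expect_equal(unname(f["qvt_nBifurcations"]), 0)
  # torsion histogram concentrated in the top bin
  expect_gt(unname(f["qvt_torsHist_7"]), 0.99)

  yfx <- y_fixture()
  ytree <- extract_tree(yfx$mask)
  fy <- compute_qvt(ytree, yfx$mask, roi(c(0, 0, 0), c(64, 64, 64)), cfg)
  expect_equal(unname(fy["qvt_nBranches"]), 3)
  expect_equal(unname(fy["qvt_nBifurcations"]), 1)
})

test_that("volume features match the analytic cylinder inside the VOI", {
  # 40 mm VOI cube centred on a 20 mm x r=2 mm tube
  fx <- tube_fixture(radius = 2, length = 20, spacing = 0.5, shape = c(96, 96, 96))
  tree <- extract_tree(fx$mask)
  voi <- roi(c(8, 8, 8), c(88, 88, 88))   # 40 mm cube
  f <- compute_qvt(tree, fx$mask, voi)
  vol_true <- pi * 4 * 20
  expect_lt(abs(f[["qvt_vesselVolume"]] - vol_true) / vol_true, 0.05)
  expect_lt(abs(f[["qvt_volVoiRatio"]] - vol_true / 40^3) / (vol_true / 40^3), 0.05)
  # independent bounding-box computation straight from the mask voxels
  idx <- which(fx$mask$values, arr.ind = TRUE)
  ext <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * 0.5
  expect_equal(f[["qvt_volBBoxRatio"]], f[["qvt_vesselVolume"]] / prod(ext),
               tolerance = 1e-9)
})

test_that("histograms are normalized and empty trees give flagged zeros", {
  fx <- y_fixture()
  tree <- extract_tree(fx$mask)
  f <- compute_qvt(tree, fx$mask, roi(c(0, 0, 0), c(64, 64, 64)))
  expect_equal(sum(f[paste0("qvt_curvHist_", 1:8)]), 1, tolerance = 1e-9)
  expect_equal(sum(f[paste0("qvt_torsHist_", 1:7)]), 1, tolerance = 1e-9)
  expect_true(all(f[paste0("qvt_torsion_", c("mean", "min", "max", "median"))] <= 1))
  expect_true(all(f >= 0))

  empty <- vessel_tree(list(), degenerate = TRUE)
  f0 <- compute_qvt(empty, fx$mask, roi(c(0, 0, 0), c(64, 64, 64)))
  expect_true(all(f0 == 0))
  expect_true(isTRUE(attr(f0, "degenerate")))
})

test_that("polyline features are rigid-motion invariant and scale-covariant", {
  tr <- make_phantom_tree(2, segment_length_mm = 10, tortuosity_amplitude = 1,
                          root = c(6, 16, 16), seed = 5)
  mask <- rasterize_tree(tr, 1.2, c(0.5, 0.5, 0.5), c(64, 64, 64))$truth_vessel_mask
  voi <- roi(c(0, 0, 0), c(64, 64, 64))
  f <- compute_qvt(tr, mask, voi)

  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr_rt <- qvtools:::transform_tree(tr, R, c(5, -3, 11))
  f_rt <- compute_qvt(tr_rt, mask, voi)
  expect_equal(unname(f[1:17]), unname(f_rt[1:17]), tolerance = 1e-9)

  s <- 2
  tr_s <- vessel_tree(lapply(tr$branches, function(b) s * b),
                      bifurcations = s * tr$bifurcations)
  f_s <- compute_qvt(tr_s, mask, voi)
  expect_equal(unname(f_s[1:5]), unname(f[1:5]), tolerance = 1e-9)   # torsion unchanged
  expect_equal(unname(f_s[6:15]), unname(f[6:15]) / s, tolerance = 1e-9)  # curvature / s
})

test_that("branch curvature statistics match a direct triple-wise oracle", {
  tr <- make_phantom_tree(1, segment_length_mm = 12, tortuosity_amplitude = 1.5,
                          root = c(8, 16, 16), seed = 9)
  mask <- rasterize_tree(tr, 1.2, c(0.5, 0.5, 0.5), c(64, 64, 64))$truth_vessel_mask
  f <- compute_qvt(tr, mask, roi(c(0, 0, 0), c(64, 64, 64)))
  curv_or <- lapply(tr$branches, function(b) {
    vapply(2:(nrow(b) - 1), function(i) {
      menger_heron_oracle(b[i - 1, ], b[i, ], b[i + 1, ])
    }, numeric(1))
  })
  means <- vapply(curv_or, mean, numeric(1))
  maxs <- vapply(curv_or, max, numeric(1))
  expect_equal(unname(f["qvt_curvMean_mean"]), mean(means), tolerance = 1e-6)
  expect_equal(unname(f["qvt_curvMean_max"]), max(means), tolerance = 1e-6)
  expect_equal(unname(f["qvt_curvMax_mean"]), mean(maxs), tolerance = 1e-6)
  expect_equal(unname(f["qvt_curvMax_median"]), median(maxs), tolerance = 1e-6)
})

test_that("raising tortuosity amplitude lowers torsion and raises curvature", {
  amps <- c(0, 0.5, 1, 1.5, 2.5)
  vals <- t(vapply(amps, function(a) {
    tr <- make_phantom_tree(1, segment_length_mm = 12, tortuosity_amplitude = a,
                            root = c(8, 16, 16), seed = 17)
    mask <- rasterize_tree(tr, 1.2, c(0.5, 0.5, 0.5), c(64, 64, 64))$truth_vessel_mask
    f <- compute_qvt(tr, mask, roi(c(0, 0, 0), c(64, 64, 64)))
    c(f[["qvt_torsion_mean"]], f[["qvt_curvMean_mean"]])
  }, numeric(2)))
  expect_true(all(diff(vals[, 1]) < 0))
  expect_true(all(diff(vals[, 2]) > 0))
})
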