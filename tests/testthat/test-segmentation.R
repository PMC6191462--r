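# Lung isolation, seeded region growing with the S parameter, VOI.

make_two_cavity_volume <- function() {
  # +40 body with 2-voxel exterior air shell and two -850 cavities
  shape <- c(60, 40, 40)
  vol <- array(40, dim = shape)
  vol[1:2, , ] <- -1000; vol[59:60, , ] <- -1000
  vol[, 1:2, ] <- -1000; vol[, 39:40, ] <- -1000
  vol[, , 1:2] <- -1000; vol[, , 39:40] <- -1000
  cav1 <- cav2 <- array(FALSE, shape)
  cav1[10:26, 10:30, 10:30] <- TRUE
  cav2[34:50, 10:30, 10:30] <- TRUE
  vol[cav1] <- -850; vol[cav2] <- -850
  list(volume = image_volume(vol, c(1, 1, 1)), cav = cav1 | cav2,
       exterior = vol == -1000)
}

test_that("lung isolation covers cavities and excludes exterior air", {
  fx <- make_two_cavity_volume()
  lung <- segment_lungs(fx$volume)
  expect_gt(sum(lung$values & fx$cav) / sum(fx$cav), 0.99)
  expect_equal(sum(lung$values & fx$exterior), 0)

  expect_error(segment_lungs(image_volume(array(40, c(10, 10, 10)), c(1, 1, 1))),
               "no lung field")
})

test_that("closing pulls interior vessels into the lung mask", {
  fx <- make_two_cavity_volume()
  vol <- fx$volume$values
  # a +50 HU tube crossing the first cavity
  tube <- array(FALSE, dim(vol))
  tube[12:24, 19:21, 19:21] <- TRUE
  vol[tube] <- 50
  lung <- segment_lungs(image_volume(vol, c(1, 1, 1)))
  expect_gt(mean(lung$values[tube]), 0.99)
})

test_that("nodule centroid is the unweighted centre of gravity in mm", {
  m <- array(FALSE, c(21, 21, 21))
  m[11, 11, 11] <- TRUE
  expect_equal(nodule_centroid(binary_mask(m, c(1, 1, 1))), c(10, 10, 10))

  m2 <- array(FALSE, c(21, 21, 21))
  m2[1, 1, 1] <- TRUE; m2[3, 1, 1] <- TRUE
  expect_equal(nodule_centroid(binary_mask(m2, c(1, 1, 1))), c(1, 0, 0))

  # symmetric sphere: centroid within half a voxel of the centre
  sp <- array(FALSE, c(31, 31, 31))
  ctr <- c(15, 15, 15)
  for (i in 1:31) for (j in 1:31) for (k in 1:31) {
    if (sum((c(i, j, k) - 1 - ctr)^2) <= 36) sp[i, j, k] <- TRUE
  }
  expect_lt(max(abs(nodule_centroid(binary_mask(sp, c(1, 1, 1))) - ctr)), 0.5)

  expect_error(nodule_centroid(binary_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1))),
               "empty")
})

test_that("region growing recovers a high-contrast tube at S = -50", {
  fx <- tube_fixture(radius = 2, length = 20, spacing = 0.5)
  vol <- fx$volume$values
  set.seed(99)
  vol <- vol + array(rnorm(length(vol), 0, 20), dim = dim(vol))
  nod <- array(FALSE, dim(vol))
  nod[28:36, 28:36, 28:36] <- fx$mask$values[28:36, 28:36, 28:36]
  grown <- region_grow_vasculature(image_volume(vol, c(0.5, 0.5, 0.5)),
                                   binary_mask(nod, c(0.5, 0.5, 0.5)),
                                   region_grow_config(S_hu = -50, rng_seed = 4))
  expect_gt(dice(grown$values, fx$mask$values), 0.95)
  expect_false(attr(grown, "truncated"))
})

test_that("the acceptance rule blocks growth at S = +50 on homogeneous input", {
  fx <- tube_fixture(radius = 2, length = 20, spacing = 0.5)
  nod <- array(FALSE, dim(fx$mask$values))
  nod[30:34, 30:34, 30:34] <- fx$mask$values[30:34, 30:34, 30:34]
  cfg <- region_grow_config(S_hu = 50, n_random_seeds = 5, rng_seed = 1)
  grown <- region_grow_vasculature(fx$volume, binary_mask(nod, fx$mask$spacing), cfg)
  # nothing beyond the seeds is accepted: every voxel equals the mean
  expect_lte(attr(grown, "n_voxels"), 6)
  expect_true(all(nod[grown$values]))
})

test_that("a permissive S in a homogeneous volume hits the cap and flags it", {
  vol <- image_volume(array(50, c(30, 30, 30)), c(1, 1, 1))
  nod <- array(FALSE, c(30, 30, 30)); nod[15, 15, 15] <- TRUE
  grown <- region_grow_vasculature(vol, binary_mask(nod, c(1, 1, 1)),
                                   region_grow_config(S_hu = -150,
                                                      max_voxels = 500))
  expect_true(attr(grown, "truncated"))
  expect_gte(attr(grown, "n_voxels"), 500)
})

test_that("grown volume is non-increasing in S and deterministic", {
  cs <- make_phantom_case(phantom_spec(rng_seed = 21))
  lung <- segment_lungs(cs$volume)
  sizes <- vapply(c(-150, -100, -50, 0, 50), function(S) {
    g <- region_grow_vasculature(cs$volume, cs$nodule_mask,
                                 region_grow_config(S_hu = S, rng_seed = 8), lung)
    attr(g, "n_voxels")
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))

  g1 <- region_grow_vasculature(cs$volume, cs$nodule_mask,
                                region_grow_config(S_hu = -50, rng_seed = 8), lung)
  g2 <- region_grow_vasculature(cs$volume, cs$nodule_mask,
                                region_grow_config(S_hu = -50, rng_seed = 8), lung)
  expect_identical(g1$values, g2$values)
  # the grown region stays inside lung + nodule
  expect_true(all((lung$values | cs$nodule_mask$values)[g1$values]))
})

test_that("VOI construction follows the margin arithmetic and clips", {
  m <- array(FALSE, c(40, 40, 40)); m[20, 20, 20] <- TRUE
  v0 <- define_voi(binary_mask(m, c(1, 1, 1)), 0)
  expect_equal(v0$upper - v0$lower, c(1L, 1L, 1L))

  m8 <- array(FALSE, c(80, 80, 80)); m8[40, 40, 40] <- TRUE
  v1 <- define_voi(binary_mask(m8, c(0.5, 0.5, 0.5)), margin_mm = 10)
  expect_equal(v1$lower, c(39L, 39L, 39L) - 20L)   # 10 mm = 20 voxels per side
  expect_equal(v1$upper, c(40L, 40L, 40L) + 20L)

  corner <- array(FALSE, c(20, 20, 20)); corner[1, 1, 1] <- TRUE
  vc <- define_voi(binary_mask(corner, c(1, 1, 1)), margin_mm = 5)
  expect_equal(vc$lower, c(0L, 0L, 0L))
  expect_error(define_voi(binary_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), 1),
               "empty")
})

test_that("single-S sensitivity yields a trivial unit correlation", {
  cs <- make_phantom_case(phantom_spec(rng_seed = 31))
  lung <- segment_lungs(cs$volume)
  res <- sensitivity_to_S(cs$volume, cs$nodule_mask, S_list = -50,
                          lung_mask = lung)
  expect_equal(dim(res$corr), c(1, 1))
  expect_equal(res$corr[1, 1], 1)
  expect_equal(nrow(res$features), 1)
  expect_error(sensitivity_to_S(cs$volume, cs$nodule_mask, S_list = numeric(0)),
               "empty")
})
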