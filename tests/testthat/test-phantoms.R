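test_that("phantom_spec validates its invariants", {
  expect_s3_class(phantom_spec(), "phantom_spec")
  expect_error(phantom_spec(n_vessels = -1), "counts")
  expect_error(phantom_spec(radius_range = c(5, 2)), "min <= max")
  expect_error(phantom_spec(spacing = c(3, 0, 1)), "positive")
  # field of view too small to hold the largest tube
  expect_error(phantom_spec(shape = c(10, 12, 12), spacing = c(3, 1, 1),
                            radius_range = c(3, 20)),
               "too small")
})

test_that("vessel phantom renders analytic cylinder geometry", {
  spec <- phantom_spec(shape = c(24, 60, 120), spacing = c(1, 1, 1),
                       n_vessels = 1, noise_sd = 4, poisson = FALSE, seed = 7)
  r <- 4
  cl <- list(list(points = cbind(12, 30, c(0, 120)), radius = r))
  vp <- make_vessel_phantom(spec, centerlines = cl)
  ratio <- sum(vp$truth$vessel_mask$data) / (pi * r^2 * 120)
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
  # anisotropic sampling with the tube resolved in every axis
  spec2 <- phantom_spec(shape = c(24, 120, 180), spacing = c(3, 0.69, 0.69),
                        n_vessels = 1, seed = 1)
  cl2 <- list(list(points = cbind(36, 40, c(0, 180 * 0.69)), radius = 8))
  vp2 <- make_vessel_phantom(spec2, centerlines = cl2)
  ratio2 <- sum(vp2$truth$vessel_mask$data) * prod(spec2$spacing) /
    (pi * 64 * 180 * 0.69)
  expect_gt(ratio2, 0.85)
  expect_lt(ratio2, 1.15)
})

test_that("tubes above hollow_above are rendered wall-only", {
  spec <- phantom_spec(shape = c(60, 80, 120), spacing = c(1.5, 1, 1),
                       n_vessels = 1, hollow_above = 10, wall_thickness = 4,
                       noise_sd = 0, poisson = FALSE, attenuation_per_um = 0,
                       seed = 2)
  cl <- list(list(points = cbind(45, 40, c(0, 120)), radius = 15))
  vp <- make_vessel_phantom(spec, centerlines = cl)
  wall <- vp$truth$wall_mask$data
  vessel <- vp$truth$vessel_mask$data
  expect_gt(sum(wall), 0)
  # wall is a subset of the filled vessel mask
  expect_true(all(vessel[wall == 1L] == 1L))
  # per-slice annulus: the mid-tube cross-section has interior background
  x_mid <- 60
  sl_w <- wall[, , x_mid]
  sl_v <- vessel[, , x_mid]
  interior <- sl_v == 1L & sl_w == 0L
  expect_gt(sum(interior), 0)
  # interior carries only background intensity (no wall signal rendered)
  intens <- vp$channel$data[, , x_mid]
  expect_lt(max(intens[interior]), 50)
  # radial check: wall voxels lie within (r - wall, r] of the axis
  zc <- 45 / 1.5; yc <- 40
  zi <- (slice.index(sl_w, 1) - 1) * 1.5
  yi <- slice.index(sl_w, 2) - 1
  rad <- sqrt((zi - 45)^2 + (yi - 40)^2)
  expect_true(all(rad[sl_w == 1L] <= 15 + 1.5 + 1e-9))
  expect_true(all(rad[sl_w == 1L] >= 15 - 4 - 1.5))
  # solid when below hollow_above
  cl2 <- list(list(points = cbind(45, 40, c(0, 120)), radius = 6))
  vp2 <- make_vessel_phantom(spec, centerlines = cl2)
  expect_equal(sum(vp2$truth$wall_mask$data), 0)
})

test_that("empty vessel phantom is pure noise with empty truth", {
  spec <- phantom_spec(shape = c(8, 32, 32), spacing = c(3, 1, 1),
                       n_vessels = 0, n_spots = 0, n_artifacts = 0, seed = 5)
  vp <- make_vessel_phantom(spec)
  expect_equal(sum(vp$truth$vessel_mask$data), 0)
  expect_equal(sum(vp$truth$wall_mask$data), 0)
  expect_equal(length(vp$truth$centerlines), 0)
  expect_gt(stats::sd(vp$channel$data), 0)  # noise present
  sp <- make_spot_phantom(spec, vp$truth)
  expect_equal(nrow(sp$truth$spot_records), 0)
  expect_equal(nrow(sp$truth$artifact_records), 0)
})

test_that("phantoms are bit-identical across runs with the same seed", {
  spec <- phantom_spec(shape = c(12, 48, 48), spacing = c(3, 1.5, 1.5),
                       n_vessels = 2, n_spots = 2, n_artifacts = 2, seed = 42)
  a <- make_vessel_phantom(spec)
  b <- make_vessel_phantom(spec)
  expect_identical(a$channel$data, b$channel$data)
  expect_identical(a$truth$vessel_mask$data, b$truth$vessel_mask$data)
  sa <- suppressWarnings(make_spot_phantom(spec, a$truth))
  sb <- suppressWarnings(make_spot_phantom(spec, b$truth))
  expect_identical(sa$channel$data, sb$channel$data)
  expect_identical(sa$truth$spot_records, sb$truth$spot_records)
  # and the generator leaves the caller's RNG stream untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(make_vessel_phantom(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("spot phantom records analytic volumes and artifact bounds", {
  spec <- phantom_spec(seed = 11)
  vp <- make_vessel_phantom(spec)
  sp <- suppressWarnings(make_spot_phantom(spec, vp$truth))
  tr <- sp$truth$spot_records
  expect_gt(nrow(tr), 0)
  # a sphere of radius 20 um has volume 33,510 um^3; our ellipsoids with
  # semi-axes r * U(0.9, 1.1) stay within the radius-derived analytic range
  rng <- spec$spot_radius_range
  expect_true(all(tr$volume_um3 > 4 / 3 * pi * rng[1]^3 * 0.9^2))
  expect_true(all(tr$volume_um3 < 4 / 3 * pi * rng[2]^3 * 1.1^2))
  # voxelized volume of a planted sphere agrees with the analytic record
  spec1 <- phantom_spec(shape = c(40, 120, 120), spacing = c(3, 1, 1),
                        n_vessels = 0, n_spots = 1, n_artifacts = 0,
                        spot_radius_range = c(20, 20), noise_sd = 0,
                        poisson = FALSE, attenuation_per_um = 0, seed = 3)
  vp1 <- make_vessel_phantom(spec1)
  sp1 <- make_spot_phantom(spec1, vp1$truth)
  expect_equal(nrow(sp1$truth$spot_records), 1)
  vox <- sum(sp1$channel$data > 100) * prod(spec1$spacing)
  expect_lt(abs(vox - sp1$truth$spot_records$volume_um3[1]) /
              sp1$truth$spot_records$volume_um3[1], 0.1)
  # artifacts: records kept separately, every true volume < 10,000 um^3
  ar <- sp$truth$artifact_records
  expect_gt(nrow(ar), 0)
  expect_true(all(ar$volume_um3 < 10000))
  # every spot centroid lies near some centerline (2 spot radii bound)
  allpts <- do.call(rbind, lapply(vp$truth$centerlines, `[[`, "points"))
  for (i in seq_len(nrow(tr))) {
    d <- sqrt(rowSums(sweep(allpts, 2, as.numeric(tr[i, 1:3]))^2))
    rad <- (tr$volume_um3[i] * 3 / (4 * pi))^(1 / 3)
    expect_lt(min(d), 2.5 * rad)
  }
})

test_that("perfusion slide phantom hits class proportions and contrasts", {
  spec <- phantom_spec(shape = c(192, 192), spacing = c(0.69, 0.69), seed = 5)
  sl <- make_perfusion_slide(spec)
  truth <- sl$truth$class_map$data
  expect_true(all(truth %in% 0:3))
  frac <- as.numeric(table(factor(truth[truth > 0], 1:3)) / sum(truth > 0))
  expect_true(all(abs(frac - spec$class_proportions) < 0.05))
  # class-2 (underperfused) dextran dimmer than class-1 (non-perfused)
  expect_lt(mean(sl$dextran$data[truth == 2]),
            mean(sl$dextran$data[truth == 1]))
  # class identity by channel: 1 bright only in dextran, 3 only in lectin
  expect_gt(mean(sl$dextran$data[truth == 1]), 150)
  expect_lt(mean(sl$lectin$data[truth == 1]), 50)
  expect_gt(mean(sl$lectin$data[truth == 3]), 150)
  expect_lt(mean(sl$dextran$data[truth == 3]), 50)
  # degenerate proportions: only class 3 present
  spec2 <- phantom_spec(shape = c(96, 96), spacing = c(1, 1),
                        class_proportions = c(0, 0, 1), seed = 6)
  sl2 <- make_perfusion_slide(spec2)
  expect_true(all(sl2$truth$class_map$data %in% c(0L, 3L)))
})

test_that("shrinkage sample generator matches its stated world", {
  s0 <- make_shrinkage_samples(n = 6, sd = 0, seed = 1)
  expect_equal(median(s0$ocs), -71)
  expect_equal(median(s0$cps), -12)
  s1 <- make_shrinkage_samples(n = 6, sd = 2, seed = 1)
  expect_lt(abs(median(s1$ocs) - (-71)), 3)
  expect_lt(abs(median(s1$cps) - (-12)), 3)
  expect_identical(make_shrinkage_samples(n = 6, sd = 2, seed = 9),
                   make_shrinkage_samples(n = 6, sd = 2, seed = 9))
  expect_error(make_shrinkage_samples(n = 0), ">= 1")
})
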