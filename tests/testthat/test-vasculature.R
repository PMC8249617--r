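test_that("fill_lumens fills closed lumens and respects the area range", {
  spec <- phantom_spec(shape = c(60, 80, 120), spacing = c(1.5, 1, 1),
                       n_vessels = 1, hollow_above = 10, wall_thickness = 4,
                       noise_sd = 0, poisson = FALSE, attenuation_per_um = 0,
                       seed = 2)
  cl <- list(list(points = cbind(45, 40, c(0, 120)), radius = 15))
  vp <- make_vessel_phantom(spec, centerlines = cl)
  wall <- array(as.integer(vp$truth$wall_mask$data),
                dim(vp$truth$wall_mask$data))
  truth <- array(as.integer(vp$truth$vessel_mask$data), dim(wall))
  filled <- fill_lumens(wall, spacing = spec$spacing)
  expect_identical(filled$data, truth)
  # lumen area above the admissible range: unchanged
  small_range <- fill_lumens(wall, area_range = c(1, 50),
                             spacing = spec$spacing)
  expect_identical(small_range$data, wall)
  # output is always a superset of the input
  expect_true(all(filled$data[wall == 1L] == 1L))
  expect_error(fill_lumens(wall, orientations = character(0),
                           spacing = spec$spacing), "empty")
})

test_that("a lumen open in one orientation fills via the closing one", {
  # hollow box with a full-length slit in one side wall: every XY slice is
  # a C (open), but XZ slices through the lumen are closed rectangles
  m <- array(0L, c(24, 24, 24))
  m[6:18, 6:18, 6:18] <- 1L
  m[8:16, 8:16, 8:16] <- 0L          # lumen
  m[8:16, 6:7, 10:14] <- 0L          # slit through the y-min wall, all z
  # prove openness: XY-only filling leaves the lumen empty
  fx <- fill_lumens(m, area_range = c(1, 400), orientations = "XY",
                    iterations = 2, spacing = c(1, 1, 1))
  expect_identical(fx$data, m)
  # the XZ slicing sees closed contours and fills the lumen
  fz <- fill_lumens(m, area_range = c(1, 400), orientations = "XZ",
                    iterations = 2, spacing = c(1, 1, 1))
  expect_gt(sum(fz$data), sum(m))
  lumen_filled <- all(fz$data[9:15, 9:15, 9:15] == 1L)
  expect_true(lumen_filled)
})

test_that("fill_lumens agrees exactly with the brute-force oracle", {
  set.seed(42)
  for (i in 1:12) {
    a <- array(as.integer(runif(20^3) < 0.45), c(20, 20, 20))
    f1 <- fill_lumens(a, area_range = c(1, 150), iterations = 2,
                      spacing = c(1, 1, 1))
    f2 <- fill_lumens_oracle(a, area_range = c(1, 150), iterations = 2,
                             spacing = c(1, 1, 1))
    expect_identical(f1$data, f2$data)
  }
  # degenerate masks are fixed points
  full <- array(1L, c(8, 8, 8))
  expect_identical(fill_lumens(full, spacing = c(1, 1, 1))$data, full)
  none <- array(0L, c(8, 8, 8))
  expect_identical(fill_lumens(none, spacing = c(1, 1, 1))$data, none)
})

test_that("fill_lumens is idempotent once converged", {
  spec <- phantom_spec(shape = c(40, 60, 80), spacing = c(1.5, 1, 1),
                       n_vessels = 1, wall_thickness = 4, noise_sd = 0,
                       poisson = FALSE, attenuation_per_um = 0, seed = 4)
  cl <- list(list(points = cbind(30, 30, c(0, 80)), radius = 12))
  vp <- make_vessel_phantom(spec, centerlines = cl)
  wall <- array(as.integer(vp$truth$wall_mask$data), dim(vp$truth$wall_mask$data))
  two <- fill_lumens(wall, iterations = 2, spacing = spec$spacing)
  three <- fill_lumens(wall, iterations = 3, spacing = spec$spacing)
  expect_identical(two$data, three$data)
})

test_that("postprocess_vessel_mask cleans speckle and passes solid tubes", {
  cfg <- vessel_pipeline_config(median_radius = 1)
  e <- postprocess_vessel_mask(array(0L, c(6, 20, 20)), cfg,
                               spacing = c(1.5, 1, 1))
  expect_equal(sum(e$data), 0)
  # isolated speckle voxels are almost completely removed
  set.seed(8)
  sp <- array(0L, c(20, 40, 40))
  planted <- sample(length(sp), 120)
  sp[planted] <- 1L
  out <- postprocess_vessel_mask(sp, cfg, spacing = c(1.5, 1, 1))
  expect_lte(sum(out$data), ceiling(0.01 * 120))
  # a solid resolved tube survives with volume change < 15%
  spec <- phantom_spec(shape = c(60, 80, 120), spacing = c(1.5, 1, 1),
                       n_vessels = 1, noise_sd = 0, poisson = FALSE,
                       attenuation_per_um = 0, seed = 3)
  cl <- list(list(points = cbind(45, 40, c(0, 120)), radius = 8))
  vp <- make_vessel_phantom(spec, centerlines = cl)
  solid <- array(as.integer(vp$truth$vessel_mask$data),
                 dim(vp$truth$vessel_mask$data))
  post <- postprocess_vessel_mask(solid, cfg, spacing = spec$spacing)
  expect_lt(abs(sum(post$data) / sum(solid) - 1), 0.15)
  expect_error(postprocess_vessel_mask(array(3L, c(2, 4, 4)), cfg,
                                       spacing = c(1, 1, 1)), "binary")
})

test_that("skeletonization recovers cylinder and Y-junction geometry", {
  # straight cylinder, L = 100 um, r = 5 um
  m <- cylinder_mask(c(16, 24, 110), r = 5, x_range = c(5, 104))
  g <- skeletonize_to_graph(m, spacing = c(1, 1, 1), min_segment_length = 10)
  expect_equal(nrow(g$segments), 1)
  expect_gte(g$segments$length_um, 95)
  expect_lte(g$segments$length_um, 105)
  expect_equal(sum(g$nodes$degree >= 3), 0)
  expect_gte(g$segments$tortuosity, 1)
  expect_lte(g$segments$tortuosity, 1.05)
  expect_equal(g$segments$mean_diameter_um, 10, tolerance = 0.15)
  # Y junction: exactly one degree-3 node, three endpoints
  y <- array(0L, c(20, 60, 60))
  ctr <- c(10, 30, 30)
  y <- stamp_tube(y, rbind(c(10, 30, 2), ctr), 3)
  y <- stamp_tube(y, rbind(ctr, c(10, 8, 55)), 3)
  y <- stamp_tube(y, rbind(ctr, c(10, 52, 55)), 3)
  gy <- skeletonize_to_graph(y, spacing = c(1, 1, 1), min_segment_length = 10)
  expect_equal(sum(gy$nodes$degree == 3), 1)
  expect_equal(sum(gy$nodes$degree == 1), 3)
  expect_equal(nrow(gy$segments), 3)
  # empty mask: empty graph, not an error
  ge <- skeletonize_to_graph(array(0L, c(6, 6, 6)), spacing = c(1, 1, 1))
  expect_equal(nrow(ge$segments), 0)
  expect_equal(nrow(ge$nodes), 0)
})

test_that("anisotropic masks are resampled before thinning", {
  # same cylinder sampled anisotropically; geometry still recovered in um
  m <- array(0L, c(34, 24, 110))
  m <- stamp_tube(m, rbind(c(25, 12, 5), c(25, 12, 104)), 5,
                  spacing = c(3, 1, 1))
  g <- skeletonize_to_graph(m, spacing = c(3, 1, 1), min_segment_length = 10)
  expect_equal(nrow(g$segments), 1)
  expect_gte(g$segments$length_um, 94)
  expect_lte(g$segments$length_um, 106)
  expect_equal(g$segments$mean_diameter_um, 10, tolerance = 0.2)
})

test_that("short terminal twigs are pruned and topology preserved", {
  m <- cylinder_mask(c(16, 30, 110), r = 4, x_range = c(5, 104), yc = 15)
  # a 6 um stub poking out sideways: below the 10 um bound, must vanish
  m <- stamp_tube(m, rbind(c(8, 19, 50), c(8, 25, 50)), 2)
  g <- skeletonize_to_graph(m, spacing = c(1, 1, 1), min_segment_length = 10)
  expect_equal(nrow(g$segments), 1)
  expect_true(all(g$segments$length_um >= 10))
  # one connected component in -> one connected graph out
  expect_equal(length(unique(c(g$segments$from, g$segments$to))) -
                 nrow(g$segments), 1)
})

test_that("diameter recovery on solid cylinders across radii", {
  for (r in c(3, 5, 10, 15)) {
    dims <- c(2 * r + 16, 2 * r + 16, 90)
    m <- cylinder_mask(dims, r = r, x_range = c(3, 86))
    g <- skeletonize_to_graph(m, spacing = c(1, 1, 1),
                              min_segment_length = 10)
    expect_equal(nrow(g$segments), 1)
    md <- g$segments$mean_diameter_um
    tol <- max(1, 0.15 * 2 * r)
    expect_lt(abs(md - 2 * r), tol)
  }
})

test_that("graph_summary conserves mass and reports panel quantities", {
  m <- cylinder_mask(c(16, 24, 110), r = 5, x_range = c(5, 104))
  g <- skeletonize_to_graph(m, spacing = c(1, 1, 1))
  tv <- prod(dim(m)) / 1e9  # mm^3
  s <- graph_summary(g, tv)
  expect_equal(s$mean_tortuosity, g$segments$tortuosity)
  expect_equal(s$vascular_volume_fraction, sum(m) / prod(dim(m)))
  # phantom with known tube volume: fraction within 10% of analytic
  expect_lt(abs(s$vascular_volume_fraction -
                  pi * 25 * 100 / prod(dim(m))) /
              (pi * 25 * 100 / prod(dim(m))), 0.1)
  # histogram masses sum to the total volume fraction
  expect_equal(sum(s$diameter_volume_fraction), s$vascular_volume_fraction,
               tolerance = 1e-9)
  expect_equal(s$n_branch_points, 0)
  expect_error(graph_summary(g, 0), "positive")
})

test_that("correction factor evaluates the closed form exactly", {
  p <- diameter_correction(3.7, 1.3, 0.5861)
  expect_equal(correction_factor(0, p), 3.7)
  expect_lt(abs(correction_factor(1e6, p) - 1.3), 1e-9)
  # degenerate Y0 = Plateau: constant CF
  flat <- diameter_correction(2, 2, 0.5)
  expect_equal(correction_factor(c(0, 1, 10, 100), flat), rep(2, 4))
  # strictly decreasing on a grid when Y0 > Plateau, K > 0
  md <- seq(0, 40, by = 0.25)
  cf <- correction_factor(md, p)
  expect_true(all(diff(cf) < 0))
  expect_gte(min(cf), 1.3)
  expect_error(correction_factor(-1, p), ">= 0")
  # corrected diameter = MD x CF on a graph
  m <- cylinder_mask(c(16, 24, 110), r = 5, x_range = c(5, 104))
  g <- correct_diameters(skeletonize_to_graph(m, spacing = c(1, 1, 1)), p)
  expect_equal(g$segments$corrected_diameter_um,
               g$segments$mean_diameter_um *
                 correction_factor(g$segments$mean_diameter_um, p))
})

test_that("fit_diameter_correction recovers parameters", {
  truep <- diameter_correction(3.7, 1.3, 0.5861)
  md <- seq(1, 30, length.out = 100)
  cf <- correction_factor(md, truep)
  fit <- fit_diameter_correction(md, md * cf)
  expect_lt(abs(fit$y0 - 3.7), 1e-6)
  expect_lt(abs(fit$plateau - 1.3), 1e-6)
  expect_lt(abs(fit$k - 0.5861), 1e-6)
  # constant CF: flat fit with Y0 ~ Plateau ~ c
  flat <- fit_diameter_correction(md, md * 1.7)
  expect_equal(flat$y0, 1.7, tolerance = 1e-4)
  expect_equal(flat$plateau, 1.7, tolerance = 1e-4)
  # 5% multiplicative noise, n = 100: median relative error over a small
  # fixed-seed Monte-Carlo within 10% per parameter
  err <- withr::with_seed(9, {
    t(replicate(6, {
      fitn <- fit_diameter_correction(md, md * cf * (1 + rnorm(100, 0, 0.05)))
      c(abs(fitn$y0 - 3.7) / 3.7, abs(fitn$plateau - 1.3) / 1.3,
        abs(fitn$k - 0.5861) / 0.5861)
    }))
  })
  expect_true(all(apply(err, 2, median) < 0.1))
  expect_error(fit_diameter_correction(1:3, 1:3), "at least 4")
  expect_error(fit_diameter_correction(rep(2, 5), rep(2, 5)), "equal")
})
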