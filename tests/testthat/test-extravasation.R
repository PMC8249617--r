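test_that("Richardson-Lucy deconvolution behaves like RL should", {
  a <- array(0, c(21, 41, 41)); a[11, 21, 21] <- 1000
  blurred <- voxel_grid(vasclear:::gaussian_filter(a, c(2, 2, 2)), c(1, 1, 1))
  # near-delta PSF: output ~ input
  d0 <- deconvolve(blurred, psf_sigma = rep(1e-3, 3), iterations = 3)
  expect_lt(max(abs(d0$data - blurred$data)), 1e-6)
  # matched PSF: point source sharpens monotonically in peak height
  peaks <- vapply(c(1, 5, 10), function(it)
    max(deconvolve(blurred, rep(2, 3), it)$data), numeric(1))
  expect_true(all(diff(peaks) > 0))
  expect_gt(peaks[3], max(blurred$data))
  # flux conservation within 1%
  d10 <- deconvolve(blurred, rep(2, 3), 10)
  expect_lt(abs(sum(d10$data) / sum(blurred$data) - 1), 0.01)
  expect_error(deconvolve(blurred, c(-1, 1, 1)), "positive")
  expect_error(deconvolve(blurred, rep(1, 3), 0), ">= 1")
})

test_that("postprocessing glues fragments and approximately restores size", {
  cfg <- spot_pipeline_config()
  # empty in, empty out
  e <- postprocess_spot_mask(array(0L, c(4, 20, 20)), cfg,
                             spacing = c(3, 1, 1))
  expect_equal(sum(e$data), 0)
  # two in-plane fragments 4 px apart merge into one component
  m <- array(0L, c(7, 40, 40))
  m[3:5, 16:24, 10:14] <- 1L
  m[3:5, 16:24, 19:23] <- 1L   # gap of 4 columns (15:18)
  pre <- vasclear:::label_components(m, 26)
  expect_equal(max(pre), 2)
  post <- postprocess_spot_mask(m, cfg, spacing = c(3, 0.69, 0.69))
  expect_equal(max(vasclear:::label_components(post$data, 26)), 1)
  # a fragmented solid sphere (half its voxels dropped, as a patchy
  # segmentation would deliver) comes back as one component whose volume
  # matches the analytic dilation + blur + threshold envelope: the margins
  # are n_dil pixels plus qnorm(1 - 50/255) * sigma per axis
  sp <- array(0L, c(30, 120, 120))
  z <- (slice.index(sp, 1) - 1) * 3; y <- (slice.index(sp, 2) - 1) * 0.69
  x <- (slice.index(sp, 3) - 1) * 0.69
  sph <- (z - 45)^2 + (y - 41)^2 + (x - 41)^2 <= 20^2
  sp[sph] <- 1L
  frag <- sp
  set.seed(77)
  frag[sample(which(frag == 1L), sum(frag) %/% 2)] <- 0L
  out <- postprocess_spot_mask(frag, cfg, spacing = c(3, 0.69, 0.69))
  expect_equal(max(vasclear:::label_components(out$data, 26)), 1)
  q <- qnorm(1 - 50 / 255)
  m_xy <- 4 * 0.69 + q * 3 * 0.69
  m_z <- q * 3 * 3
  predicted <- 4 / 3 * pi * (20 + m_z) * (20 + m_xy)^2
  measured <- sum(out$data) * 3 * 0.69^2
  expect_lt(abs(measured / predicted - 1), 0.25)
  expect_error(postprocess_spot_mask(array(2L, c(2, 4, 4)), cfg,
                                     spacing = c(1, 1, 1)), "binary")
})

test_that("extract_spots measures physical morphometry exactly", {
  # empty mask: zero rows
  expect_equal(nrow(extract_spots(array(0L, c(4, 8, 8)),
                                  spacing = c(1, 1, 1))), 0)
  # a 10x10x10 voxel cube at 0.69 x 0.69 x 3 um spacing
  m <- array(0L, c(20, 30, 30))
  m[6:15, 11:20, 11:20] <- 1L
  tab <- extract_spots(m, spacing = c(3, 0.69, 0.69), min_volume = 10000)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$volume_um3, 1000 * 3 * 0.69 * 0.69)  # 1428.3 um^3
  expect_equal(tab$volume_um3, 1428.3, tolerance = 1e-6)
  expect_true(tab$flag_small)
  # analytic cube surface: 6 faces with anisotropic areas
  expect_equal(tab$surface_um2,
               2 * (10 * 0.69 * 10 * 0.69) + 4 * (10 * 3 * 10 * 0.69))
  # centroid at voxel-index mean times spacing
  expect_equal(tab$centroid_z_um, mean(5:14) * 3)
  expect_equal(tab$centroid_y_um, mean(10:19) * 0.69)
  expect_equal(tab$bbox_z0, 5); expect_equal(tab$bbox_z1, 14)
  # two objects: separated -> 2 rows; touching diagonally -> 1 with 26-conn
  two <- array(0L, c(6, 12, 12))
  two[2:3, 2:3, 2:3] <- 1L
  two[2:3, 2:3, 6:7] <- 1L
  expect_equal(nrow(extract_spots(two, spacing = c(1, 1, 1))), 2)
  diag <- array(0L, c(6, 12, 12))
  diag[2, 2, 2] <- 1L
  diag[3, 3, 3] <- 1L
  expect_equal(nrow(extract_spots(diag, spacing = c(1, 1, 1),
                                  connectivity = 26)), 1)
  expect_equal(nrow(extract_spots(diag, spacing = c(1, 1, 1),
                                  connectivity = 6)), 2)
  # mean intensity from the source channel
  intens <- array(10, dim(two)); intens[two == 1L] <- 50
  ti <- extract_spots(two, intensity = intens, spacing = c(1, 1, 1))
  expect_equal(ti$mean_intensity, c(50, 50))
})

test_that("extract_spots total volume equals a brute-force voxel count", {
  set.seed(31)
  for (i in 1:5) {
    m <- array(as.integer(runif(32^3) < 0.2), c(32, 32, 32))
    tab <- extract_spots(m, spacing = c(2, 1, 1))
    expect_equal(sum(tab$volume_um3), sum(m) * 2)  # exact equality
  }
})

test_that("filter_spots applies the exclusion boundary and is monotone", {
  tab <- vasclear:::empty_spot_table()
  tab <- rbind(tab, data.frame(id = 1:4,
                               volume_um3 = c(5000, 9999, 10001, 20000),
                               surface_um2 = 1, centroid_z_um = 0,
                               centroid_y_um = 0, centroid_x_um = 0,
                               bbox_z0 = 0L, bbox_z1 = 0L, bbox_y0 = 0L,
                               bbox_y1 = 0L, bbox_x0 = 0L, bbox_x1 = 0L,
                               mean_intensity = 0,
                               flag_small = c(TRUE, TRUE, FALSE, FALSE)))
  kept <- filter_spots(tab, 10000)
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "n_removed"), 2)
  # keep iff volume >= bound: exactly-at-bound spots stay
  at <- tab; at$volume_um3[2] <- 10000
  expect_equal(nrow(filter_spots(at, 10000)), 3)
  # min_volume = 0 is the identity
  expect_equal(nrow(filter_spots(tab, 0)), 4)
  # monotone: larger bound never increases the row count
  counts <- vapply(c(0, 5000, 10000, 15000, 25000),
                   function(b) nrow(filter_spots(tab, b)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("albumin extravascular volume is thresholded set difference", {
  vm <- array(0L, c(6, 20, 20))
  vm[, 5:10, 5:10] <- 1L
  # albumin identical to the vessel signal: complete subtraction
  alb <- array(0, dim(vm)); alb[vm == 1L] <- 200
  g <- voxel_grid(alb, c(3, 1, 1))
  expect_equal(albumin_extravasation_volume(g, vm)$volume_um3, 0)
  # a halo of known voxel count outside the vessels
  alb2 <- alb
  alb2[, 5:10, 11:13] <- 100   # 6 * 6 * 3 = 108 voxels outside the mask
  res <- albumin_extravasation_volume(voxel_grid(alb2, c(3, 1, 1)), vm,
                                      threshold = c(60, 255))
  expect_equal(res$volume_um3, 108 * 3)
  expect_equal(sum(res$mask$data), 108)
  # threshold above the image maximum finds nothing
  expect_equal(albumin_extravasation_volume(
    voxel_grid(array(254, dim(vm)), c(3, 1, 1)), vm,
    threshold = c(255, 255))$volume_um3, 0)
  expect_error(albumin_extravasation_volume(
    voxel_grid(array(0, c(2, 2, 2)), c(1, 1, 1)), vm), "differ")
})
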