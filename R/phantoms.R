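#' Specification of a synthetic vascular phantom
#'
#' The phantom generator stands in for the imaging data: it renders tubes
#' (vessels), near-vessel ellipsoidal blobs (tracer extravasation spots) and
#' axially elongated bright spindles (point-spread-function artifacts) into
#' calibrated 8-bit channels, together with exact ground truth. Tubes above
#' the `hollow_above` radius are rendered wall-only, emulating large vessels
#' whose label binds the endothelial surface so that the segmented mask is a
#' hollow shell; small tubes are solid.
#'
#' Defaults describe the stated world the package is tested in: anisotropic
#' voxels with a 3 um z pitch as in light-sheet/confocal practice, 8-bit
#' intensities, mixed Gaussian + Poisson noise, and mild depth attenuation.
#'
#' @param shape voxel counts `(nz, ny, nx)`, or `(ny, nx)` for a 2D slide.
#' @param spacing voxel spacing in um per axis, same length as `shape`.
#' @param n_vessels number of tubes.
#' @param radius_range tube radius range, um.
#' @param hollow_above tubes with radius above this (um) are wall-only.
#' @param wall_thickness wall shell thickness for hollow tubes, um.
#' @param n_spots number of extravasation blobs for [make_spot_phantom()].
#' @param spot_radius_range blob radius range, um.
#' @param n_artifacts number of PSF-artifact spindles.
#' @param artifact_z_extent spindle extent along z, um.
#' @param noise_sd additive Gaussian noise sd, 8-bit intensity units.
#' @param poisson add Poisson (shot) noise before the Gaussian component.
#' @param attenuation_per_um fractional signal loss per um of depth.
#' @param class_proportions target area proportions of the three vessel
#'   classes (non-perfused, underperfused, perfused) on 2D slides.
#' @param seed integer RNG seed; every generator call is seeded locally.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(40, 320, 320), spacing = c(3, 0.69, 0.69),
                         n_vessels = 6, radius_range = c(3, 12),
                         hollow_above = 8, wall_thickness = 3,
                         n_spots = 6, spot_radius_range = c(17, 21),
                         n_artifacts = 5, artifact_z_extent = 30,
                         noise_sd = 8, poisson = TRUE,
                         attenuation_per_um = 0.001,
                         class_proportions = c(0.25, 0.25, 0.5),
                         seed = 1L) {
  if (!length(shape) %in% c(2, 3)) stop_user("shape must be 2D or 3D")
  if (length(spacing) != length(shape))
    stop_user("spacing must match shape dimensionality")
  counts <- c(n_vessels, n_spots, n_artifacts)
  if (any(counts < 0)) stop_user("counts must be >= 0")
  if (any(spacing <= 0)) stop_user("spacing must be positive")
  for (rng in list(radius_range, spot_radius_range))
    if (length(rng) != 2 || rng[1] > rng[2])
      stop_user("ranges must be (min, max) with min <= max")
  if (wall_thickness <= 0) stop_user("wall_thickness must be positive")
  if (noise_sd < 0) stop_user("noise_sd must be >= 0")
  if (abs(sum(class_proportions) - 1) > 1e-9 || any(class_proportions < 0))
    stop_user("class_proportions must be nonnegative and sum to 1")
  ext <- shape * spacing
  if (length(shape) == 3 && n_vessels > 0 &&
      2 * radius_range[2] > min(ext[2:3]))
    stop_user("volume too small for radius_range: field of view ",
              paste(round(ext), collapse = "x"),
              " um cannot contain tubes of radius ", radius_range[2], " um")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_vessels = as.integer(n_vessels),
                 radius_range = radius_range, hollow_above = hollow_above,
                 wall_thickness = wall_thickness,
                 n_spots = as.integer(n_spots),
                 spot_radius_range = spot_radius_range,
                 n_artifacts = as.integer(n_artifacts),
                 artifact_z_extent = artifact_z_extent,
                 noise_sd = noise_sd, poisson = isTRUE(poisson),
                 attenuation_per_um = attenuation_per_um,
                 class_proportions = class_proportions,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# depth attenuation + shot/read noise + 8-bit quantization
finalize_channel <- function(intens, spec) {
  d <- dim(intens)
  if (length(d) == 3 && spec$attenuation_per_um > 0) {
    z_um <- (seq_len(d[1]) - 1) * spec$spacing[1]
    att <- exp(-spec$attenuation_per_um * z_um)
    intens <- intens * att  # recycles along z (first axis)
  }
  if (spec$poisson) intens <- array(rpois(length(intens), pmax(intens, 0)), d)
  if (spec$noise_sd > 0)
    intens <- intens + rnorm(length(intens), 0, spec$noise_sd)
  intens <- round(intens)
  intens[intens < 0] <- 0
  intens[intens > 255] <- 255
  array(intens, d)
}

# smoothed random-walk centerline inside the physical volume, respecting a
# margin of `r` um from the y/x faces
random_centerline <- function(ext, r, step = 4, momentum = 0.85) {
  lo <- c(0, r, r)
  hi <- ext - c(0, r, r)
  p <- runif(3, lo + 0.1 * ext, hi - 0.1 * ext)
  dir <- rnorm(3)
  dir[1] <- dir[1] * 0.3  # favour in-plane courses as vessels in a slab
  dir <- dir / sqrt(sum(dir^2))
  n_steps <- ceiling(1.4 * max(ext) / step)
  pts <- matrix(NA_real_, n_steps + 1, 3)
  pts[1, ] <- p
  for (i in seq_len(n_steps)) {
    turn <- rnorm(3, 0, 1 - momentum)
    dir <- dir + turn
    dir <- dir / sqrt(sum(dir^2))
    q <- p + step * dir
    for (ax in 1:3) {
      if (q[ax] < lo[ax] || q[ax] > hi[ax]) {
        dir[ax] <- -dir[ax]
        q[ax] <- p[ax] + step * dir[ax]
        q[ax] <- min(max(q[ax], lo[ax]), hi[ax])
      }
    }
    pts[i + 1, ] <- q
    p <- q
  }
  # two passes of 3-point smoothing for a gentle curvature bound
  for (k in 1:2) {
    m <- nrow(pts)
    if (m > 2)
      pts[2:(m - 1), ] <- (pts[1:(m - 2), ] + pts[2:(m - 1), ] +
                           pts[3:m, ]) / 3
  }
  pts
}

#' Render a vascular tube phantom
#'
#' Renders `spec$n_vessels` tubes along smooth random polylines into a
#' lectin-like channel. Tubes with radius above `spec$hollow_above` carry
#' intensity only in a wall shell of `spec$wall_thickness`; smaller tubes are
#' solid. The returned truth holds the *filled* vessel mask, the wall mask
#' and the exact centerlines with per-point radius.
#'
#' @param spec a [phantom_spec()] with 3D shape.
#' @param centerlines optional list of `list(points = <n x 3 um matrix>,
#'   radius = <um>)` to render instead of random centerlines (used to build
#'   analytic fixtures, e.g. straight cylinders).
#' @return `list(channel = voxel_grid, truth = phantom_truth)`.
#' @export
make_vessel_phantom <- function(spec, centerlines = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$shape) != 3) stop_user("vessel phantoms need a 3D shape")
  with_seed(spec$seed, function() {
    d <- spec$shape
    ext <- d * spec$spacing
    if (is.null(centerlines)) {
      centerlines <- lapply(seq_len(spec$n_vessels), function(i) {
        r <- runif(1, spec$radius_range[1], spec$radius_range[2])
        list(points = random_centerline(ext, r), radius = r)
      })
    }
    vessel <- array(0L, d)
    wall <- array(0L, d)
    intens <- array(0, d)
    for (cl in centerlines) {
      r <- cl$radius
      dist <- cpp_polyline_distance(as.numeric(cl$points), d, spec$spacing,
                                    r + 2 * max(spec$spacing))
      dim(dist) <- d
      inside <- dist <= r
      vessel[inside] <- 1L
      if (r > spec$hollow_above) {
        w <- inside & dist > (r - spec$wall_thickness)
        wall[w] <- 1L
        intens[w] <- 200
      } else {
        intens[inside] <- 200
      }
    }
    intens <- intens + 5  # camera offset / autofluorescence floor
    channel <- voxel_grid(finalize_channel(intens, spec), spec$spacing,
                          channel = "lectin", bits = 8L)
    truth <- structure(list(
      vessel_mask = label_mask(vessel, spec$spacing,
                               c("0" = "background", "1" = "vessel")),
      wall_mask = label_mask(wall, spec$spacing,
                             c("0" = "background", "1" = "wall")),
      centerlines = centerlines,
      spot_records = NULL, artifact_records = NULL, class_map = NULL,
      spacing = spec$spacing), class = "phantom_truth")
    list(channel = channel, truth = truth)
  })
}

# stamp an axis-aligned ellipsoid (semi-axes um, center um) into `arr`,
# returning the modified array; value is max-combined
stamp_ellipsoid <- function(arr, spacing, center, semi, value) {
  d <- dim(arr)
  idx <- lapply(1:3, function(ax) {
    lo <- max(0L, floor((center[ax] - semi[ax]) / spacing[ax]))
    hi <- min(d[ax] - 1L, ceiling((center[ax] + semi[ax]) / spacing[ax]))
    if (lo > hi) integer(0) else seq.int(lo, hi)
  })
  if (any(lengths(idx) == 0)) return(arr)
  zz <- (idx[[1]] * spacing[1] - center[1]) / semi[1]
  yy <- (idx[[2]] * spacing[2] - center[2]) / semi[2]
  xx <- (idx[[3]] * spacing[3] - center[3]) / semi[3]
  q <- outer(outer(zz^2, yy^2, `+`), xx^2, `+`)
  sub <- arr[idx[[1]] + 1L, idx[[2]] + 1L, idx[[3]] + 1L, drop = FALSE]
  dim(sub) <- dim(q)
  sub[q <= 1] <- pmax(sub[q <= 1], value)
  arr[idx[[1]] + 1L, idx[[2]] + 1L, idx[[3]] + 1L] <- sub
  arr
}

#' Render the tracer (dextran) channel with extravasation spots and
#' PSF artifacts
#'
#' Places `spec$n_spots` ellipsoidal blobs adjacent to the vessel
#' centerlines (each centroid within two spot radii of a centerline point)
#' and `spec$n_artifacts` bright z-elongated spindles seeded on bright
#' vessel voxels, each with analytic volume below 10,000 um^3, mimicking
#' out-of-focus light elongated along the PSF z-axis. True centroids and
#' analytic volumes are recorded separately for spots and artifacts.
#'
#' @param spec a [phantom_spec()].
#' @param truth the `phantom_truth` from [make_vessel_phantom()].
#' @return `list(channel = voxel_grid, truth = phantom_truth)` where the
#'   truth gains `spot_records` and `artifact_records` data frames.
#' @export
make_spot_phantom <- function(spec, truth) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(truth, "phantom_truth"))
  with_seed(spec$seed + 1L, function() {
    d <- spec$shape
    ext <- d * spec$spacing
    intens <- array(0, d)
    # intravascular tracer baseline: residual dextran inside vessels
    intens[truth$vessel_mask$data == 1L] <- 110
    cls <- truth$centerlines
    rec <- list()
    placed <- 0
    centers <- matrix(numeric(0), 0, 3)
    radii <- numeric(0)
    # spots are distinct leakage events: enforce a separation margin wide
    # enough that the dilation + blur of the postprocessing stage cannot
    # glue neighbouring spots together
    sep_margin <- 30
    for (i in seq_len(spec$n_spots)) {
      ok <- FALSE
      for (try in 1:80) {
        r <- runif(1, spec$spot_radius_range[1], spec$spot_radius_range[2])
        semi <- r * c(1, runif(2, 0.9, 1.1))
        if (length(cls)) {
          cl <- cls[[sample.int(length(cls), 1)]]
          p <- cl$points[sample.int(nrow(cl$points), 1), ]
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          center <- p + u * runif(1, 0.8, 2) * r
        } else {
          center <- runif(3, semi, ext - semi)
        }
        if (any(center < semi) || any(center > ext - semi)) next
        if (nrow(centers)) {
          dd <- sqrt(rowSums(sweep(centers, 2, center)^2))
          if (any(dd < radii + r + sep_margin)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) next
      placed <- placed + 1
      centers <- rbind(centers, center)
      radii <- c(radii, max(semi))
      intens <- stamp_ellipsoid(intens, spec$spacing, center, semi, 215)
      rec[[placed]] <- c(center, 4 / 3 * pi * prod(semi))
    }
    if (placed < spec$n_spots)
      warning(sprintf("placed %d of %d requested spots", placed, spec$n_spots))
    spot_records <- if (placed) {
      m <- do.call(rbind, rec)
      data.frame(z_um = m[, 1], y_um = m[, 2], x_um = m[, 3],
                 volume_um3 = m[, 4])
    } else data.frame(z_um = numeric(), y_um = numeric(), x_um = numeric(),
                      volume_um3 = numeric())

    bright <- which(truth$vessel_mask$data == 1L)
    arec <- list()
    for (i in seq_len(spec$n_artifacts)) {
      if (!length(bright)) break
      a <- spec$artifact_z_extent / 2
      for (try in 1:80) {
        lin <- bright[sample.int(length(bright), 1)] - 1L
        z <- lin %% d[1]; rest <- lin %/% d[1]
        y <- rest %% d[2]; x <- rest %/% d[2]
        center <- c(z, y, x) * spec$spacing
        # thin axial streaks; true volume far below the 10,000 um^3 bound so
        # that even the pipeline-inflated measurement stays below it
        vol <- runif(1, 400, 1500)
        rxy <- sqrt(vol / (4 / 3 * pi * a))
        semi <- c(a, rxy, rxy)
        center <- pmin(pmax(center, semi), ext - semi)
        if (nrow(centers)) {
          dd <- sqrt(rowSums(sweep(centers, 2, center)^2))
          if (any(dd < radii + max(semi) + sep_margin)) next
        }
        centers <- rbind(centers, center)
        radii <- c(radii, max(semi))
        intens <- stamp_ellipsoid(intens, spec$spacing, center, semi, 245)
        arec[[length(arec) + 1]] <- c(center, 4 / 3 * pi * prod(semi))
        break
      }
    }
    artifact_records <- if (length(arec)) {
      m <- do.call(rbind, arec)
      data.frame(z_um = m[, 1], y_um = m[, 2], x_um = m[, 3],
                 volume_um3 = m[, 4])
    } else data.frame(z_um = numeric(), y_um = numeric(), x_um = numeric(),
                      volume_um3 = numeric())

    intens <- intens + 5
    channel <- voxel_grid(finalize_channel(intens, spec), spec$spacing,
                          channel = "dextran", bits = 8L)
    truth$spot_records <- spot_records
    truth$artifact_records <- artifact_records
    list(channel = channel, truth = truth)
  })
}

# draw a thick 2D stroke into class_map; returns updated map
stamp_stroke2d <- function(class_map, spacing, pts, r, value) {
  d <- dim(class_map)
  dist <- cpp_polyline_distance(as.numeric(cbind(0, pts)),
                                c(1L, d), c(1, spacing), r + 2 * max(spacing))
  dim(dist) <- d
  class_map[dist <= r] <- value
  class_map
}

#' Render a 2D perfusion slide phantom
#'
#' Draws planar vessel strokes and assigns each of them one of three
#' perfusion classes, targeting `spec$class_proportions` of the vascular
#' pixel area: class 1 (non-perfused) is bright only in the dextran channel,
#' class 3 (perfused) only in the lectin channel, and class 2 (underperfused)
#' is bright in both with dextran intensity drawn lower than the class-1
#' mean. The truth `class_map` is exact; value 0 is background.
#'
#' @param spec a [phantom_spec()] with a 2D `shape`.
#' @return `list(dextran = voxel_grid, lectin = voxel_grid,
#'   truth = phantom_truth)`.
#' @export
make_perfusion_slide <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$shape) != 2) stop_user("perfusion slides need a 2D shape")
  with_seed(spec$seed + 2L, function() {
    d <- spec$shape
    ext <- d * spec$spacing
    class_map <- array(0L, d)
    target <- spec$class_proportions
    n_strokes <- max(30, 10 * spec$n_vessels)
    for (i in seq_len(n_strokes)) {
      counts <- vapply(1:3, function(k) sum(class_map == k), numeric(1))
      tot <- sum(counts)
      share <- if (tot > 0) counts / tot else rep(0, 3)
      deficit <- target - share
      cls_pick <- which.max(deficit)
      if (target[cls_pick] == 0) cls_pick <- which.max(target)
      pts <- random_centerline(c(1, ext), 0, step = 6)[, 2:3, drop = FALSE]
      r <- runif(1, 2, 5)
      class_map <- stamp_stroke2d(class_map, spec$spacing, pts, r, cls_pick)
    }
    dex <- array(5, d)
    lec <- array(5, d)
    i1 <- class_map == 1L; i2 <- class_map == 2L; i3 <- class_map == 3L
    dex[i1] <- rnorm(sum(i1), 200, 12)
    dex[i2] <- rnorm(sum(i2), 120, 12)
    lec[i2] <- rnorm(sum(i2), 180, 12)
    lec[i3] <- rnorm(sum(i3), 190, 12)
    dextran <- voxel_grid(finalize_channel(dex, spec), spec$spacing,
                          channel = "dextran", bits = 8L)
    lectin <- voxel_grid(finalize_channel(lec, spec), spec$spacing,
                         channel = "lectin", bits = 8L)
    truth <- structure(list(
      vessel_mask = NULL, wall_mask = NULL, centerlines = NULL,
      spot_records = NULL, artifact_records = NULL,
      class_map = label_mask(class_map, spec$spacing,
                             c("0" = "background", "1" = "non-perfused",
                               "2" = "underperfused", "3" = "perfused")),
      spacing = spec$spacing), class = "phantom_truth")
    list(dextran = dextran, lectin = lectin, truth = truth)
  })
}

#' Simulate per-sample tissue volume-change percentages
#'
#' Draws `n` volume-change percentages for each preparation group around the
#' stated group means: optically cleared samples (OCS) and conventionally
#' (cryo)prepared samples (CPS). Defaults reproduce the reported ~-71% and
#' ~-12% group changes.
#'
#' @param n samples per group (>= 1).
#' @param ocs_change,cps_change group mean volume change, percent.
#' @param sd between-sample standard deviation, percentage points.
#' @param seed RNG seed.
#' @return `list(ocs = numeric(n), cps = numeric(n))`.
#' @export
make_shrinkage_samples <- function(n = 6, ocs_change = -71, cps_change = -12,
                                   sd = 2, seed = 1L) {
  if (n < 1) stop_user("n must be >= 1")
  with_seed(seed, function() {
    list(ocs = rnorm(n, ocs_change, sd), cps = rnorm(n, cps_change, sd))
  })
}
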