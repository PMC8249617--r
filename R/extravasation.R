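#' Spot pipeline configuration
#'
#' Defaults follow the published workflow for tracer extravasation in
#' cleared tissue: pre-segmentation 2D Gaussian blur (sigma 1.3 px), four
#' consecutive 2D dilation steps, 3D Gaussian filtering with sigma 3 px on
#' the {0,255}-scaled mask, re-thresholding at 50-255, 26-connected 3D spot
#' recognition, and exclusion of spots smaller than 10,000 um^3. Filter
#' sizes are in pixels of the uncalibrated image, thresholds on the 8-bit
#' scale.
#'
#' @param pre_sigma pre-segmentation in-plane Gaussian sigma, px.
#' @param n_dilations number of slice-wise 3x3 dilation passes.
#' @param post_sigma 3D Gaussian sigma (x, y and z), px.
#' @param post_threshold inclusive 8-bit threshold range.
#' @param min_volume spot exclusion bound, um^3 (spots *smaller* than this
#'   are excluded; a spot exactly at the bound is kept).
#' @param connectivity 3D component connectivity: 6, 18 or 26.
#' @return a `spot_pipeline_config`.
#' @export
spot_pipeline_config <- function(pre_sigma = 1.3, n_dilations = 4,
                                 post_sigma = 3, post_threshold = c(50, 255),
                                 min_volume = 10000, connectivity = 26) {
  if (any(post_threshold < 0) || any(post_threshold > 255) ||
      post_threshold[1] > post_threshold[2])
    stop_user("post_threshold must be an increasing range within [0,255]")
  if (min_volume < 0) stop_user("min_volume must be >= 0")
  if (!connectivity %in% c(6, 18, 26))
    stop_user("connectivity must be 6, 18 or 26")
  structure(list(pre_sigma = pre_sigma, n_dilations = as.integer(n_dilations),
                 post_sigma = post_sigma, post_threshold = post_threshold,
                 min_volume = min_volume,
                 connectivity = as.integer(connectivity)),
            class = "spot_pipeline_config")
}

#' Richardson-Lucy deconvolution with a parametric Gaussian PSF
#'
#' Stands in for blind deconvolution in the preprocessing stage: iterative
#' Richardson-Lucy updates with an anisotropic Gaussian point-spread
#' function given by its sigma per axis in micrometres (converted to voxels
#' through the grid spacing). Output is non-negative and conserves total
#' intensity up to boundary effects. The stage is optional and skippable.
#'
#' @param grid a [voxel_grid()].
#' @param psf_sigma PSF sigma per axis in um, `(dz, dy, dx)` (or
#'   `(dy, dx)` in 2D).
#' @param iterations number of RL updates (>= 1).
#' @return deconvolved [voxel_grid()] (same calibration, floating point).
#' @export
deconvolve <- function(grid, psf_sigma, iterations = 10) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (iterations < 1) stop_user("iterations must be >= 1")
  if (any(psf_sigma <= 0)) stop_user("psf_sigma must be positive")
  if (length(psf_sigma) != length(grid$spacing))
    stop_user("psf_sigma must match image dimensionality")
  sig_vox <- psf_sigma / grid$spacing
  img <- grid$data
  est <- pmax(img, 1e-8)
  eps <- 1e-8
  for (i in seq_len(iterations)) {
    blurred <- gaussian_filter(est, sig_vox)
    ratio <- img / (blurred + eps)
    est <- est * gaussian_filter(ratio, sig_vox)  # Gaussian PSF is symmetric
  }
  voxel_grid(est, grid$spacing, grid$channel, grid$bits)
}

#' Postprocess a segmented spot mask
#'
#' Glues the fragmented pieces of a segmented spot back together: `n` 2D
#' dilation passes with a 3x3 8-connected element on every slice, scaling of
#' the binary mask to {0, 255}, a 3D Gaussian filter, and re-thresholding,
#' which brings the dilated spots back to approximately their original size
#' with evened-up margins.
#'
#' @param mask binary [label_mask()] (or array with `spacing`).
#' @param cfg a [spot_pipeline_config()].
#' @param spacing spacing when `mask` is a bare array.
#' @return binary [label_mask()].
#' @export
postprocess_spot_mask <- function(mask, cfg = spot_pipeline_config(),
                                  spacing = NULL) {
  gd <- grid_data(mask, spacing)
  check_binary(gd$data)
  a <- dilate_slices(gd$data, cfg$n_dilations)
  a <- a * 255
  a <- gaussian_filter(a, rep(cfg$post_sigma, length(dim(a))))
  out <- array(0L, dim(a))
  out[a >= cfg$post_threshold[1] & a <= cfg$post_threshold[2]] <- 1L
  label_mask(out, gd$spacing, c("0" = "background", "1" = "spot"))
}

#' Recognize and measure 3D spots
#'
#' Labels 3D connected components of a binary mask and measures each spot
#' in physical units: volume (voxel count x voxel volume), surface area
#' (summed exposed voxel faces, anisotropy-aware), intensity-unweighted
#' centroid, voxel bounding box and mean source-channel intensity.
#' `flag_small` marks spots below `min_volume` (see [filter_spots()]).
#'
#' @param mask binary [label_mask()] or array.
#' @param intensity optional intensity [voxel_grid()] (or array) for
#'   per-spot mean intensity.
#' @param spacing spacing when `mask` is a bare array.
#' @param min_volume exclusion bound used to set `flag_small`, um^3.
#' @param connectivity 3D connectivity (default 26).
#' @return a `spot_table` data frame.
#' @export
extract_spots <- function(mask, intensity = NULL, spacing = NULL,
                          min_volume = 10000, connectivity = 26) {
  gd <- grid_data(mask, spacing)
  if (is.null(gd$spacing)) stop_user("spacing is required")
  check_binary(gd$data)
  a <- gd$data
  if (length(dim(a)) == 2) {
    a <- array(a, c(1, dim(a)))
    sp <- c(1, gd$spacing)
  } else sp <- gd$spacing
  lab <- label_components(a, connectivity)
  K <- max(lab)
  if (K == 0) return(empty_spot_table())
  intens <- if (is.null(intensity)) array(0, dim(a)) else {
    it <- if (inherits(intensity, "voxel_grid")) intensity$data else intensity
    if (!all(dim(it) == dim(gd$data)))
      stop_user("intensity grid shape does not match the mask")
    array(it, dim(a))
  }
  st <- cpp_region_stats(as.integer(lab), dim(a), as.numeric(intens))
  surf <- cpp_region_surface(as.integer(lab), dim(a), sp)
  voxvol <- prod(sp)
  vol <- st$count * voxvol
  df <- data.frame(
    id = seq_len(K),
    volume_um3 = vol,
    surface_um2 = surf,
    centroid_z_um = st$sz / st$count * sp[1],
    centroid_y_um = st$sy / st$count * sp[2],
    centroid_x_um = st$sx / st$count * sp[3],
    bbox_z0 = st$z0, bbox_z1 = st$z1,
    bbox_y0 = st$y0, bbox_y1 = st$y1,
    bbox_x0 = st$x0, bbox_x1 = st$x1,
    mean_intensity = st$sum_intensity / st$count,
    flag_small = vol < min_volume)
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Exclude small spots
#'
#' Removes spots strictly smaller than `min_volume` (a spot exactly at the
#' bound is kept); PSF artifacts falsely segmented as spots rarely exceed
#' the default 10,000 um^3 bound, so this filter rejects them. The number
#' of removed rows is attached as attribute `n_removed`.
#'
#' @param table a `spot_table`.
#' @param min_volume exclusion bound, um^3; 0 keeps everything.
#' @return filtered `spot_table`.
#' @export
filter_spots <- function(table, min_volume = 10000) {
  keep <- table$volume_um3 >= min_volume
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- c("spot_table", "data.frame")
  out
}

#' Threshold-based extravascular (albumin) volume
#'
#' Thresholds the albumin channel, subtracts the vessel mask, and reports
#' the remaining (extravascular) volume in um^3 together with the binary
#' extravasation mask.
#'
#' @param albumin a [voxel_grid()].
#' @param vessel_mask binary [label_mask()] on the same lattice.
#' @param threshold inclusive 8-bit intensity range (default 60-255).
#' @return `list(volume_um3, mask)`.
#' @export
albumin_extravasation_volume <- function(albumin, vessel_mask,
                                         threshold = c(60, 255)) {
  stopifnot(inherits(albumin, "voxel_grid"))
  vm <- if (inherits(vessel_mask, "label_mask")) vessel_mask$data else vessel_mask
  if (!all(dim(albumin$data) == dim(vm)))
    stop_user("albumin channel and vessel mask shapes differ")
  sel <- albumin$data >= threshold[1] & albumin$data <= threshold[2] & vm == 0
  out <- array(0L, dim(vm))
  out[sel] <- 1L
  list(volume_um3 = sum(sel) * prod(albumin$spacing),
       mask = label_mask(out, albumin$spacing,
                         c("0" = "background", "1" = "extravascular")))
}

#' Run the full extravasation-spot pipeline
#'
#' Preprocessing (optional 2D Gaussian blur), segmentation (trained
#' classifier or intensity threshold), postprocessing
#' ([postprocess_spot_mask()]), spot recognition ([extract_spots()]) and
#' size filtering ([filter_spots()]).
#'
#' @param grid tracer channel [voxel_grid()].
#' @param model optional `pixel_classifier` whose highest class codes spot;
#'   when absent, `segment_threshold` is applied instead.
#' @param cfg a [spot_pipeline_config()].
#' @param segment_threshold 8-bit range for threshold segmentation.
#' @param pre_blur apply the `cfg$pre_sigma` in-plane blur first.
#' @return `list(spots, all_spots, mask)`: the filtered table, the
#'   unfiltered table and the postprocessed mask.
#' @export
run_spot_pipeline <- function(grid, model = NULL,
                              cfg = spot_pipeline_config(),
                              segment_threshold = c(160, 255),
                              pre_blur = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"))
  a <- grid$data
  if (pre_blur && cfg$pre_sigma > 0) {
    nd <- length(dim(a))
    sig <- if (nd == 2) rep(cfg$pre_sigma, 2) else c(0, cfg$pre_sigma, cfg$pre_sigma)
    a <- gaussian_filter(a, sig)
  }
  if (!is.null(model)) {
    pred <- pc_predict(model, voxel_grid(a, grid$spacing, grid$channel,
                                         grid$bits))
    spot_class <- max(model$classes)
    seg <- array(0L, dim(a))
    seg[pred$labels$data == spot_class] <- 1L
  } else {
    seg <- array(0L, dim(a))
    seg[a >= segment_threshold[1] & a <= segment_threshold[2]] <- 1L
  }
  mask <- postprocess_spot_mask(seg, cfg, spacing = grid$spacing)
  tab <- extract_spots(mask, intensity = grid, min_volume = cfg$min_volume,
                       connectivity = cfg$connectivity)
  list(spots = filter_spots(tab, cfg$min_volume), all_spots = tab,
       mask = mask)
}
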