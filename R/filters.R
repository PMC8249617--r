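# Thin R wrappers around the compiled image kernels. All of them accept and
# return plain arrays in (z, y, x) / (y, x) layout; the voxel_grid /
# label_mask classes are peeled off at the operation level.

gaussian_filter <- function(a, sigma) {
  vol <- as_vol(a)
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  if (vol$d2 && length(sigma) == 2) sigma <- c(0, sigma)
  if (length(sigma) != 3) stop_user("sigma must have 1-3 entries")
  out <- cpp_gaussian_filter(vol$vec, vol$dims, as.numeric(sigma))
  from_vol(out, vol)
}

median_filter <- function(a, radius) {
  if (radius < 1) return(a)
  vol <- as_vol(a)
  from_vol(cpp_median3d(vol$vec, vol$dims, as.integer(radius)), vol)
}

dilate_slices <- function(a, iterations) {
  vol <- as_vol(a)
  out <- cpp_dilate2d(as.integer(vol$vec != 0), vol$dims,
                      as.integer(iterations))
  from_vol(as.numeric(out), vol)
}

label_components <- function(a, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop_user("connectivity must be 6, 18 or 26")
  vol <- as_vol(a)
  out <- cpp_label3d(as.integer(vol$vec != 0), vol$dims,
                     as.integer(connectivity))
  r <- from_vol(out, vol)
  storage.mode(r) <- "integer"
  r
}

distance_transform <- function(a, spacing) {
  vol <- as_vol(a)
  sp <- spacing3(spacing, vol$d2)
  from_vol(cpp_edt(as.integer(vol$vec != 0), vol$dims, as.numeric(sp)), vol)
}

# resample a volume to isotropic spacing s = min(spacing) (trilinear)
resample_isotropic <- function(a, spacing, target = min(spacing)) {
  d <- dim(a)
  if (length(d) != 3) stop_user("resample_isotropic expects a 3D array")
  if (all(abs(spacing - target) < 1e-12))
    return(list(data = a, spacing = rep(target, 3)))
  dims_out <- pmax(1L, as.integer(floor((d - 1) * spacing / target) + 1))
  out <- cpp_resample(as.numeric(a), as.integer(d), as.numeric(spacing),
                      dims_out, rep(target, 3))
  dim(out) <- dims_out
  list(data = out, spacing = rep(target, 3))
}
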