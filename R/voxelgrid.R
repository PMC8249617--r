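#' Calibrated intensity image
#'
#' A `voxel_grid` couples a 2D or 3D intensity lattice with its physical
#' voxel spacing in micrometres. Axis order is fixed as (z, y, x) for
#' volumes and (y, x) for planar images; indices are 0-based in all physical
#' coordinate computations, with the physical position of a voxel equal to
#' `index * spacing` (voxel-corner origin).
#'
#' @param data numeric 2D or 3D array, `(y, x)` or `(z, y, x)`.
#' @param spacing voxel spacing in micrometres per axis, `(dy, dx)` or
#'   `(dz, dy, dx)`. All entries must be positive.
#' @param channel optional channel name.
#' @param bits nominal bit depth, 8 or 16.
#' @return an object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(matrix(0, 8, 8), spacing = c(0.69, 0.69))
#' dim(g$data)
#' @export
voxel_grid <- function(data, spacing, channel = "", bits = 8L) {
  d <- dim(data)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop_user("voxel_grid data must be a 2D or 3D array")
  if (length(spacing) != length(d))
    stop_user("spacing must have one entry per axis (got ", length(spacing),
              " for a ", length(d), "D image)")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop_user("spacing must be positive and finite")
  if (!bits %in% c(8L, 16L)) stop_user("bits must be 8 or 16")
  structure(list(data = data, spacing = as.numeric(spacing),
                 channel = as.character(channel), bits = as.integer(bits)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid%s> %s voxels, spacing (%s) um, %d-bit\n",
              if (nzchar(x$channel)) paste0(" ", x$channel) else "",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = ", "), x$bits))
  invisible(x)
}

#' Integer class map aligned to a voxel grid
#'
#' @param data integer 2D/3D array of class labels.
#' @param spacing physical spacing, as in [voxel_grid()].
#' @param legend named character vector mapping values to class names, e.g.
#'   `c("0" = "background", "1" = "vessel")`.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(data, spacing, legend = NULL) {
  d <- dim(data)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop_user("label_mask data must be a 2D or 3D array")
  if (length(spacing) != length(d))
    stop_user("spacing must have one entry per axis")
  if (any(spacing <= 0)) stop_user("spacing must be positive")
  storage.mode(data) <- "integer"
  if (!is.null(legend)) {
    vals <- sort(unique(as.integer(data)))
    miss <- setdiff(vals, as.integer(names(legend)))
    if (length(miss))
      stop_user("mask contains values absent from legend: ",
                paste(miss, collapse = ", "))
  }
  structure(list(data = data, spacing = as.numeric(spacing), legend = legend),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %s voxels, values {%s}\n",
              paste(dim(x$data), collapse = " x "),
              paste(sort(unique(as.integer(x$data))), collapse = ",")))
  invisible(x)
}

# accept voxel_grid / label_mask / bare array, return list(data, spacing)
grid_data <- function(x, spacing = NULL) {
  if (inherits(x, "voxel_grid") || inherits(x, "label_mask"))
    list(data = x$data, spacing = x$spacing)
  else {
    if (is.null(spacing))
      stop_user("spacing must be given when passing a bare array")
    list(data = x, spacing = spacing)
  }
}

check_binary <- function(a, what = "mask") {
  v <- unique(as.vector(a))
  if (!all(v %in% c(0, 1)))
    stop_user(what, " must be binary (0/1); found values ",
              paste(utils::head(setdiff(v, c(0, 1)), 3), collapse = ", "))
  invisible(TRUE)
}

#' Rescale an image to 8-bit display range
#'
#' Linearly maps the `[low_pct, high_pct]` intensity percentiles to
#' `[0, 255]`, clipping outside. An image that is already 8-bit and mapped
#' with the full `(0, 100)` range passes through unchanged. All pixel-value
#' thresholds used downstream (e.g. spot threshold 50-255) assume this
#' 8-bit convention.
#'
#' @param grid a [voxel_grid()].
#' @param low_pct,high_pct percentile bounds, `high_pct > low_pct`.
#' @return an 8-bit [voxel_grid()].
#' @export
to_8bit <- function(grid, low_pct = 0, high_pct = 100) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (high_pct <= low_pct) stop_user("high_pct must exceed low_pct")
  a <- grid$data
  lo <- quantile(a, low_pct / 100, names = FALSE)
  hi <- quantile(a, high_pct / 100, names = FALSE)
  if (hi <= lo) {
    warning("constant image; returning all zeros")
    out <- array(0, dim(a))
  } else if (grid$bits == 8L && low_pct == 0 && high_pct == 100 &&
             lo >= 0 && hi <= 255) {
    out <- a
  } else {
    out <- (a - lo) / (hi - lo) * 255
    out[out < 0] <- 0
    out[out > 255] <- 255
    out <- round(out)
  }
  voxel_grid(out, grid$spacing, grid$channel, bits = 8L)
}
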