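# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures on disk.

# solid cylinder along x, radius r (voxel units), centred at (zc, yc)
cylinder_mask <- function(dims, r, x_range, zc = dims[1] / 2,
                          yc = dims[2] / 2) {
  m <- array(0L, dims)
  z <- slice.index(m, 1) - 1
  y <- slice.index(m, 2) - 1
  x <- slice.index(m, 3) - 1
  m[(z - zc)^2 + (y - yc)^2 <= r^2 & x >= x_range[1] & x <= x_range[2]] <- 1L
  m
}

# stamp a tube of radius r (um) along a physical polyline into a mask
stamp_tube <- function(m, pts, r, spacing = c(1, 1, 1)) {
  d <- dim(m)
  dist <- vasclear:::cpp_polyline_distance(as.numeric(pts), d, spacing,
                                           r + 2 * max(spacing))
  dim(dist) <- d
  m[dist <= r] <- 1L
  m
}

# fraction of truth records recovered by table centroids within their radius
match_records <- function(records, table, radius = NULL) {
  if (!nrow(records)) return(1)
  cent <- as.matrix(table[, c("centroid_z_um", "centroid_y_um",
                              "centroid_x_um")])
  hits <- vapply(seq_len(nrow(records)), function(i) {
    rad <- radius %||% (records$volume_um3[i] * 3 / (4 * pi))^(1 / 3)
    if (!nrow(cent)) return(FALSE)
    d <- sqrt(rowSums(sweep(cent, 2, as.numeric(records[i, 1:3]))^2))
    min(d) < rad
  }, logical(1))
  mean(hits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
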