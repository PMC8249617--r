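`%||%` <- function(a, b) if (is.null(a)) b else a

#' @useDynLib vasclear, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median optim quantile rnorm rpois runif setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

# Run `fun()` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps every generator call-local.
with_seed <- function(seed, fun) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

stop_user <- function(...) {
  stop(structure(class = c("vasclear_user_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# coerce a 2D/3D numeric array to the flat (nz, ny, nx) layout used by the
# C++ kernels; 2D inputs become a single z-slice
as_vol <- function(a) {
  d <- dim(a)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop_user("expected a 2D or 3D array")
  if (length(d) == 2L) {
    dims <- c(1L, d)
    list(vec = as.numeric(a), dims = as.integer(dims), d2 = TRUE, dim_in = d)
  } else {
    list(vec = as.numeric(a), dims = as.integer(d), d2 = FALSE, dim_in = d)
  }
}

from_vol <- function(vec, vol) {
  a <- vec
  dim(a) <- vol$dim_in
  a
}

spacing3 <- function(spacing, d2) {
  if (d2) c(1, spacing) else spacing
}
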