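#' Multiscale filter-bank configuration
#'
#' The trainable segmentation follows the fixed-features-plus-forest
#' architecture: a documented multiscale bank of classical image features
#' feeds a random forest, and only the forest is trained. Per scale the full
#' bank contributes 7 channels: Gaussian (1), gradient magnitude (1),
#' Laplacian (1), Hessian eigenvalues (2) and structure-tensor eigenvalues
#' (2); `difference-of-gaussians` adds 1 more.
#'
#' @param scales smoothing scales in pixels (>= 1 scale).
#' @param features subset of `c("gaussian", "gradient", "laplacian",
#'   "hessian", "structure", "dog")`.
#' @return a `feature_bank_config`.
#' @export
feature_bank_config <- function(scales = c(1, 2, 4, 8),
                                features = c("gaussian", "gradient",
                                             "laplacian", "hessian",
                                             "structure")) {
  all_feats <- c("gaussian", "gradient", "laplacian", "hessian",
                 "structure", "dog")
  if (length(scales) < 1 || any(scales <= 0))
    stop_user("need at least one positive scale")
  bad <- setdiff(features, all_feats)
  if (length(bad)) stop_user("unknown features: ", paste(bad, collapse = ", "))
  if (!length(features)) stop_user("need at least one feature")
  structure(list(scales = as.numeric(scales), features = features),
            class = "feature_bank_config")
}

feature_channels <- function(cfg) {
  per <- c(gaussian = 1, gradient = 1, laplacian = 1, hessian = 2,
           structure = 2, dog = 1)
  sum(per[cfg$features]) * length(cfg$scales)
}

# central differences on a 2D matrix (unit pixel steps, replicated border)
diff_x <- function(m) (cbind(m[, -1], m[, ncol(m)]) - cbind(m[, 1], m[, -ncol(m)])) / 2
diff_y <- function(m) (rbind(m[-1, ], m[nrow(m), ]) - rbind(m[1, ], m[-nrow(m), ])) / 2

features_slice <- function(m, cfg) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(NA_real_, ny * nx, 0)
  nm <- character(0)
  for (s in cfg$scales) {
    if (s >= min(ny, nx))
      stop_user("scale ", s, " is larger than the image")
    g <- gaussian_filter(m, c(s, s))
    gx <- diff_x(g); gy <- diff_y(g)
    gxx <- diff_x(gx); gyy <- diff_y(gy); gxy <- diff_y(gx)
    for (f in cfg$features) {
      cols <- switch(f,
        gaussian = {
          nm <- c(nm, sprintf("gauss_s%g", s)); cbind(as.vector(g))
        },
        gradient = {
          nm <- c(nm, sprintf("gradmag_s%g", s))
          cbind(as.vector(sqrt(gx^2 + gy^2)))
        },
        laplacian = {
          nm <- c(nm, sprintf("laplace_s%g", s)); cbind(as.vector(gxx + gyy))
        },
        hessian = {
          tr2 <- (gxx + gyy) / 2
          dt <- sqrt(pmax(((gxx - gyy) / 2)^2 + gxy^2, 0))
          nm <- c(nm, sprintf("hess1_s%g", s), sprintf("hess2_s%g", s))
          cbind(as.vector(tr2 + dt), as.vector(tr2 - dt))
        },
        structure = {
          sxx <- gaussian_filter(gx * gx, c(s, s))
          syy <- gaussian_filter(gy * gy, c(s, s))
          sxy <- gaussian_filter(gx * gy, c(s, s))
          tr2 <- (sxx + syy) / 2
          dt <- sqrt(pmax(((sxx - syy) / 2)^2 + sxy^2, 0))
          nm <- c(nm, sprintf("st1_s%g", s), sprintf("st2_s%g", s))
          cbind(as.vector(tr2 + dt), as.vector(tr2 - dt))
        },
        dog = {
          nm <- c(nm, sprintf("dog_s%g", s))
          cbind(as.vector(gaussian_filter(m, c(1.6 * s, 1.6 * s)) - g))
        })
      out <- cbind(out, cols)
    }
  }
  colnames(out) <- nm
  out
}

#' Compute the per-pixel feature stack
#'
#' 3D stacks are processed slice-wise with 2D features (vessel stacks were
#' annotated and classified on 2D planes); the result is a matrix with one
#' row per pixel in (z, then column-major y/x) order. A multi-channel image
#' is passed as an unnamed list of aligned channels; per-channel feature
#' banks are concatenated.
#'
#' @param grid a [voxel_grid()], 2D matrix, 3D array, or list of aligned
#'   channels thereof.
#' @param cfg a [feature_bank_config()].
#' @param spacing spacing when `grid` is a bare array (unused by the 2D
#'   features but kept for interface symmetry).
#' @return numeric matrix `n_pixels x n_features`.
#' @export
build_features <- function(grid, cfg = feature_bank_config(), spacing = NULL) {
  if (is.list(grid) && !inherits(grid, "voxel_grid")) {
    blocks <- lapply(grid, build_features, cfg = cfg, spacing = spacing)
    if (length(unique(vapply(blocks, nrow, integer(1)))) != 1)
      stop_user("channels have inconsistent shapes")
    for (i in seq_along(blocks))
      colnames(blocks[[i]]) <- paste0("ch", i, "_", colnames(blocks[[i]]))
    return(do.call(cbind, blocks))
  }
  gd <- if (inherits(grid, "voxel_grid")) grid$data else grid
  d <- dim(gd)
  if (length(d) == 2) return(features_slice(gd, cfg))
  blocks <- lapply(seq_len(d[1]), function(z) features_slice(gd[z, , ], cfg))
  # interleave rows so that row order matches as.vector() of the (z,y,x) array
  nfeat <- ncol(blocks[[1]])
  res <- matrix(NA_real_, prod(d), nfeat)
  for (z in seq_len(d[1])) {
    res[seq.int(z, prod(d), by = d[1]), ] <- blocks[[z]]
  }
  colnames(res) <- colnames(blocks[[1]])
  res
}

#' Train the pixel classifier
#'
#' Fits a bagged CART forest on the feature vectors of labelled pixels only
#' (sparse scribble annotations; label 0 = unlabelled). Pixels are gathered
#' in canonical scan order, so the result is invariant to how the caller
#' ordered images or produced the label masks. Out-of-bag accuracy over the
#' labelled pixels is reported in the model.
#'
#' @param images a [voxel_grid()]/array or list of them; a multi-channel
#'   image is itself a list of aligned channels (so a single two-channel
#'   image is `list(list(ch1, ch2))`).
#' @param labels matching integer label arrays (0 = unlabelled).
#' @param cfg a [feature_bank_config()].
#' @param n_trees,max_depth forest size and depth cap (0 = unlimited).
#' @param min_labels minimum labelled pixels required per class.
#' @param classes optional integer vector of expected class values; an
#'   expected class with no labels is an error naming the class.
#' @param seed forest RNG seed (deterministic training and prediction).
#' @return a `pixel_classifier` with elements `cfg`, `trees`, `classes`,
#'   `oob_accuracy`.
#' @export
pc_train <- function(images, labels, cfg = feature_bank_config(),
                     n_trees = 100, max_depth = 0, min_labels = 1,
                     classes = NULL, seed = 1L) {
  if (!is.list(images) || inherits(images, "voxel_grid")) images <- list(images)
  if (!is.list(labels) || inherits(labels, "label_mask")) labels <- list(labels)
  if (length(images) > 1 && length(labels) == 1 &&
      !is.list(images[[1]]))
    stop_user("images and labels must have the same length; wrap the ",
              "channels of a multi-channel image in their own list")
  if (length(images) != length(labels))
    stop_user("images and labels must have the same length")
  Xs <- list(); ys <- list()
  for (i in seq_along(images)) {
    lab <- labels[[i]]
    lab <- if (inherits(lab, "label_mask")) lab$data else lab
    f <- build_features(images[[i]], cfg)
    sel <- which(as.vector(lab) > 0)
    Xs[[i]] <- f[sel, , drop = FALSE]
    ys[[i]] <- as.vector(lab)[sel]
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  if (!length(y)) stop_user("no labelled pixels")
  found <- sort(unique(y))
  classes <- if (is.null(classes)) found else sort(as.integer(classes))
  cnt <- table(factor(y, levels = classes))
  lacking <- classes[cnt < min_labels]
  if (length(lacking))
    stop_user("class(es) with fewer than ", min_labels,
              " labelled pixels: ", paste(lacking, collapse = ", "))
  if (length(classes) < 2)
    stop_user("need at least 2 labelled classes, got ",
              paste(classes, collapse = ", "))
  if (any(!y %in% classes))
    stop_user("labels contain values outside the declared classes: ",
              paste(setdiff(unique(y), classes), collapse = ", "))
  y0 <- match(y, classes) - 1L
  mtry <- max(1L, floor(sqrt(ncol(X))))
  fit <- cpp_rf_train(X, y0, length(classes), as.integer(n_trees),
                      mtry, as.integer(max_depth), 1L, as.integer(seed))
  votes <- fit$oob_votes
  hasv <- rowSums(votes) > 0
  pred <- max.col(votes[hasv, , drop = FALSE], ties.method = "first")
  oob <- mean(pred == (y0[hasv] + 1L))
  structure(list(cfg = cfg, trees = fit$trees, classes = classes,
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 oob_accuracy = oob, n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(paste0("<pixel_classifier> %d classes {%s}, %d trees, ",
                     "%d features, OOB accuracy %.3f\n"),
              length(x$classes), paste(x$classes, collapse = ","),
              x$n_trees, x$n_features, x$oob_accuracy))
  invisible(x)
}

#' Predict class probabilities and labels for an image
#'
#' Per-pixel class probabilities are the forest vote fractions (they sum to
#' one); the label map is the argmax. `smooth_sigma > 0` applies a Gaussian
#' to each probability channel before the argmax — a light-weight stand-in
#' for structured (conditional-random-field) postprocessing, off by default.
#'
#' @param model a trained `pixel_classifier`.
#' @param grid image to classify ([voxel_grid()], matrix, 3D array, or a
#'   list of aligned channels for a multi-channel model).
#' @param smooth_sigma in-plane probability smoothing sigma in pixels.
#' @param spacing spacing for bare arrays (used to build the label mask).
#' @return `list(prob = array(dims x n_classes), labels = label_mask)`.
#' @export
pc_predict <- function(model, grid, smooth_sigma = 0, spacing = NULL) {
  stopifnot(inherits(model, "pixel_classifier"))
  first <- if (is.list(grid) && !inherits(grid, "voxel_grid")) grid[[1]] else grid
  gd <- if (inherits(first, "voxel_grid")) first$data else first
  sp <- if (inherits(first, "voxel_grid")) first$spacing else spacing
  X <- build_features(grid, model$cfg)
  if (ncol(X) != model$n_features)
    stop_user("feature bank mismatch: model expects ", model$n_features,
              " features, image yields ", ncol(X))
  votes <- cpp_rf_votes(model$trees, X, length(model$classes))
  prob <- votes / model$n_trees
  d <- dim(gd)
  K <- length(model$classes)
  parr <- array(prob, c(d, K))
  if (smooth_sigma > 0) {
    if (length(d) == 2) {
      for (k in seq_len(K))
        parr[, , k] <- gaussian_filter(parr[, , k], rep(smooth_sigma, 2))
    } else {
      for (k in seq_len(K))
        parr[, , , k] <- gaussian_filter(parr[, , , k],
                                         c(0, smooth_sigma, smooth_sigma))
    }
    tot <- apply(parr, seq_along(d), sum)
    parr <- parr / as.vector(tot)
  }
  flat <- matrix(parr, ncol = K)
  lab <- model$classes[max.col(flat, ties.method = "first")]
  lab <- array(as.integer(lab), d)
  sp <- sp %||% rep(1, length(d))
  list(prob = parr, labels = label_mask(lab, sp))
}

#' Save / load a trained classifier
#'
#' The model is stored as a single JSON archive holding the feature-bank
#' configuration and the serialized forest.
#'
#' @param model a `pixel_classifier`.
#' @param path JSON file path.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "pixel_classifier"))
  obj <- list(cfg = list(scales = model$cfg$scales,
                         features = model$cfg$features),
              classes = model$classes, n_trees = model$n_trees,
              seed = model$seed, oob_accuracy = model$oob_accuracy,
              n_features = model$n_features,
              feature_names = model$feature_names,
              trees = model$trees)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  trees <- lapply(obj$trees, function(t)
    list(feature = as.integer(unlist(t$feature)),
         threshold = as.numeric(unlist(t$threshold)),
         left = as.integer(unlist(t$left)),
         right = as.integer(unlist(t$right)),
         pred = as.integer(unlist(t$pred))))
  structure(list(cfg = feature_bank_config(as.numeric(unlist(obj$cfg$scales)),
                                           unlist(obj$cfg$features)),
                 trees = trees, classes = as.integer(unlist(obj$classes)),
                 n_trees = as.integer(obj$n_trees[[1]]),
                 seed = as.integer(obj$seed[[1]]),
                 oob_accuracy = as.numeric(obj$oob_accuracy[[1]]),
                 n_features = as.integer(obj$n_features[[1]]),
                 feature_names = unlist(obj$feature_names)),
            class = "pixel_classifier")
}
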