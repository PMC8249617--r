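#' Quantify perfusion classes on one section
#'
#' Computes the area covered by each vascular class — 1 non-perfused,
#' 2 underperfused, 3 perfused (0 is background) — within an optional ROI,
#' and each class's percentage of the total vascular area of the section.
#'
#' @param class_mask a [label_mask()] with values in 0..3 (or array with
#'   `spacing`).
#' @param roi_mask optional binary ROI ([label_mask()] or array); pixels
#'   outside are ignored.
#' @param spacing spacing when `class_mask` is a bare array.
#' @param section section identifier stored in the output.
#' @return one-row data frame with per-class areas (um^2), percentages,
#'   `total_vascular_area_um2` and a `valid` flag (FALSE when the ROI holds
#'   no vascular pixels; percentages are then reported as 0).
#' @export
quantify_section <- function(class_mask, roi_mask = NULL, spacing = NULL,
                             section = 1L) {
  gd <- grid_data(class_mask, spacing)
  vals <- unique(as.vector(gd$data))
  if (!all(vals %in% 0:3))
    stop_user("class mask must contain only values 0..3")
  a <- gd$data
  if (!is.null(roi_mask)) {
    roi <- if (inherits(roi_mask, "label_mask")) roi_mask$data else roi_mask
    if (!all(dim(roi) == dim(a))) stop_user("ROI shape mismatch")
    a <- a * (roi != 0)
    if (!any(roi != 0)) warning("ROI is empty")
  }
  px_area <- prod(gd$spacing[(length(gd$spacing) - 1):length(gd$spacing)])
  counts <- vapply(1:3, function(k) sum(a == k), numeric(1))
  areas <- counts * px_area
  total <- sum(areas)
  pct <- if (total > 0) 100 * areas / total else c(0, 0, 0)
  if (total == 0) warning("section has no vascular pixels")
  data.frame(section = section,
             area_nonperfused_um2 = areas[1],
             area_underperfused_um2 = areas[2],
             area_perfused_um2 = areas[3],
             pct_nonperfused = pct[1], pct_underperfused = pct[2],
             pct_perfused = pct[3],
             total_vascular_area_um2 = total,
             valid = total > 0)
}

#' Tumor-level weighted class percentages
#'
#' Aggregates per-section class percentages into a whole-tumor summary,
#' weighting each section by its total vascular area (default) or, as an
#' alternative reading, by equal section weights. Sections without vascular
#' area are skipped.
#'
#' @param sections data frame of rows from [quantify_section()].
#' @param weighting `"vascular"` (area-weighted) or `"equal"`.
#' @return named numeric vector of weighted percentages per class.
#' @export
tumor_weighted_summary <- function(sections, weighting = c("vascular",
                                                           "equal")) {
  weighting <- match.arg(weighting)
  if (!nrow(sections)) stop_user("no sections given")
  ok <- sections$total_vascular_area_um2 > 0
  if (!any(ok)) stop_user("all sections have zero vascular area")
  s <- sections[ok, , drop = FALSE]
  w <- if (weighting == "vascular") s$total_vascular_area_um2
       else rep(1, nrow(s))
  w <- w / sum(w)
  c(pct_nonperfused = sum(w * s$pct_nonperfused),
    pct_underperfused = sum(w * s$pct_underperfused),
    pct_perfused = sum(w * s$pct_perfused))
}

#' Mean pixel intensity per class
#'
#' @param intensity a [voxel_grid()] (or array).
#' @param class_mask aligned [label_mask()].
#' @return named numeric vector of mean intensities for the classes present
#'   in the mask; empty classes are absent from the output.
#' @export
class_intensity_stats <- function(intensity, class_mask) {
  it <- if (inherits(intensity, "voxel_grid")) intensity$data else intensity
  cm <- if (inherits(class_mask, "label_mask")) class_mask$data else class_mask
  if (!all(dim(it) == dim(cm))) stop_user("shape mismatch")
  present <- sort(unique(as.vector(cm)))
  means <- vapply(present, function(k) mean(it[cm == k]), numeric(1))
  setNames(means, as.character(present))
}

#' Arcsine square-root transform of a proportion
#'
#' Variance-stabilizing transform applied to class percentages before
#' group-level regression (the regression itself is left to standard
#' statistics packages).
#'
#' @param p proportion(s) in `[0, 1]`.
#' @return `asin(sqrt(p))`, radians.
#' @export
arcsine_transform <- function(p) {
  if (any(p < 0 | p > 1)) stop_user("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Tissue volume-change correction between preparations
#'
#' From per-sample volume-change percentages of optically cleared samples
#' (OCS) and conventionally prepared samples (CPS), computes
#' `CF = med(OCS) - med(CPS)` (percentage points; even-n medians are the
#' mean of the central pair).
#'
#' @param ocs_changes,cps_changes per-sample volume changes, percent (each
#'   at least one value).
#' @return a `shrinkage_correction` with `med_ocs`, `med_cps`, `cf`.
#' @export
shrinkage_correction <- function(ocs_changes, cps_changes) {
  if (!length(ocs_changes) || !length(cps_changes))
    stop_user("each group needs at least one sample")
  mo <- median(ocs_changes)
  mc <- median(cps_changes)
  structure(list(med_ocs = mo, med_cps = mc, cf = mo - mc),
            class = "shrinkage_correction")
}

#' @export
print.shrinkage_correction <- function(x, ...) {
  cat(sprintf("<shrinkage_correction> med(OCS) = %g%%, med(CPS) = %g%%, CF = %g points\n",
              x$med_ocs, x$med_cps, x$cf))
  invisible(x)
}

#' Rescale a cleared-sample volume to sectioned-sample equivalent
#'
#' Multiplies a volume measured in an optically cleared sample by
#' `(100 + med(CPS)) / (100 + med(OCS))` so that densities are comparable
#' across the two preparations.
#'
#' @param volume volume(s) measured in the cleared preparation.
#' @param correction a [shrinkage_correction()].
#' @return corrected volume(s).
#' @export
apply_shrinkage_correction <- function(volume, correction) {
  stopifnot(inherits(correction, "shrinkage_correction"))
  if (correction$med_ocs <= -100)
    stop_user("med(OCS) = -100% leaves no residual volume to rescale")
  volume * (100 + correction$med_cps) / (100 + correction$med_ocs)
}
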