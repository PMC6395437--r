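#' @include AllClasses.R
NULL

#' Per-ROI means of a voxel map
#'
#' Arithmetic mean of the valid (non-`NA`) voxels of each ROI; ROIs with
#' more than 20% invalid voxels are flagged.
#'
#' @param map a [VoxelMap].
#' @param rois an [ROISet] or a list of logical masks.
#' @return data.frame with columns `roi`, `mean`, `n`, `n_invalid`,
#'   `flagged`.
#' @export
roiMeans <- function(map, rois) {
  stopifnot(is(map, "VoxelMap"))
  masks <- if (is(rois, "ROISet")) lesionROIs(rois) else rois
  if (is.matrix(masks)) masks <- list(masks)
  res <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    if (!identical(dim(m), dim(map@values)))
      stop("ROI dimensions differ from the map")
    if (!any(m)) stop("ROI ", i, " is empty")
    v <- map@values[m]
    n_inv <- sum(is.na(v))
    if (n_inv == length(v)) stop("ROI ", i, " has no valid voxels")
    data.frame(roi = i, mean = mean(v, na.rm = TRUE),
               n = length(v) - n_inv, n_invalid = n_inv,
               flagged = n_inv > 0.2 * length(v))
  })
  do.call(rbind, res)
}

#' Lowest per-ROI mean (the reported lesion value)
#'
#' Out of several small lesion ROIs, the one with the lowest APTW mean is
#' reported, on the rationale that the lowest APTW corresponds to the
#' most acidic part of the lesion.  Ties break to the lowest index.
#'
#' @param means data.frame from [roiMeans()], or a numeric vector.
#' @return list with `value` and `index`.
#' @export
lowestROI <- function(means) {
  v <- if (is.data.frame(means)) means$mean else as.numeric(means)
  if (!length(v)) stop("no ROI means given")
  i <- which.min(v)  # which.min is deterministic: first minimum wins
  list(value = v[i], index = i)
}

#' Mirror an ROI across the brain midline
#'
#' Maps each pixel `(r, c)` to `(r, round(2 * midline - c))`; pixels
#' falling outside the image are dropped with a warning.  The default
#' midline is the vertical image center `(ncol + 1) / 2` (columns are
#' 1-based), so for a 64-column image column `c` maps to `65 - c`.
#'
#' @param roi logical matrix.
#' @param midline midline column (may be fractional).
#' @return logical matrix, the mirrored ROI.
#' @export
mirrorROI <- function(roi, midline = NULL) {
  storage.mode(roi) <- "logical"
  nc <- ncol(roi)
  if (is.null(midline)) midline <- (nc + 1) / 2
  idx <- which(roi, arr.ind = TRUE)
  mc <- round(2 * midline - idx[, 2L])
  keep <- mc >= 1L & mc <= nc
  if (!all(keep))
    warning(sum(!keep), " mirrored pixel(s) fall outside the image")
  if (!any(keep)) stop("mirrored ROI is empty")
  out <- matrix(FALSE, nrow(roi), nc)
  out[cbind(idx[keep, 1L], mc[keep])] <- TRUE
  out
}

#' Measure a lesion on an APTW map
#'
#' Applies the full ROI rule set: per-ROI means over the small lesion
#' ROIs, selection of the lowest mean as the lesion APTW, a CNAWM value
#' from the explicit CNAWM ROI or (by default) from mirroring the
#' selected lesion ROI across the midline, the lesion-minus-CNAWM APTW
#' contrast, and the whole-lesion mean when a whole-lesion mask is
#' present.
#'
#' @param map a [VoxelMap] in percent (APTW).
#' @param rois an [ROISet].
#' @param midline midline column for mirroring (default: image center).
#' @return list of class `LesionMeasurement` with fields
#'   `lesion_aptw_pct`, `lesion_aptw_mean_pct`, `cnawm_aptw_pct`,
#'   `contrast_pct`, `n_rois`, `selected_roi_index`, `roi_means`.
#' @export
measureLesion <- function(map, rois, midline = NULL) {
  stopifnot(is(map, "VoxelMap"), is(rois, "ROISet"))
  means <- roiMeans(map, rois)
  low <- lowestROI(means)
  cn_mask <- cnawmROI(rois)
  if (is.null(cn_mask))
    cn_mask <- mirrorROI(lesionROIs(rois)[[low$index]], midline)
  cn <- roiMeans(map, list(cn_mask))$mean
  whole <- wholeLesionMask(rois)
  whole_mean <- if (is.null(whole)) NA_real_
                else roiMeans(map, list(whole))$mean
  structure(list(
    lesion_aptw_pct = low$value,
    lesion_aptw_mean_pct = whole_mean,
    cnawm_aptw_pct = cn,
    contrast_pct = low$value - cn,
    n_rois = nrow(means),
    selected_roi_index = low$index,
    roi_means = means), class = "LesionMeasurement")
}

#' @export
print.LesionMeasurement <- function(x, ...) {
  cat("Lesion measurement (APTW, % of bulk water signal)\n")
  cat(sprintf("  lesion (lowest of %d ROIs, #%d): %.3f\n", x$n_rois,
              x$selected_roi_index, x$lesion_aptw_pct))
  if (is.finite(x$lesion_aptw_mean_pct))
    cat(sprintf("  whole-lesion mean:             %.3f\n",
                x$lesion_aptw_mean_pct))
  cat(sprintf("  CNAWM:                         %.3f\n", x$cnawm_aptw_pct))
  cat(sprintf("  contrast (lesion - CNAWM):     %.3f\n", x$contrast_pct))
  invisible(x)
}
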