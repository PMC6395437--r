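#' @include AllClasses.R
NULL

#' Construct a z-spectrum series
#'
#' @param frames numeric array `nrow x ncol x nframes` in offset-table
#'   expansion order.
#' @param s0 unsaturated reference image.
#' @param offset_table an [OffsetTable] whose expansion matches `nframes`.
#' @param pixel_size_mm in-plane pixel spacing.
#' @return a validated [ZSpectrumSeries].
#' @export
zSpectrumSeries <- function(frames, s0, offset_table,
                            pixel_size_mm = c(1, 1)) {
  new("ZSpectrumSeries", frames = frames, s0 = as.matrix(s0),
      offset_table = offset_table, pixel_size_mm = as.numeric(pixel_size_mm))
}

#' Construct an ROI set
#'
#' ROI pixel-count bounds are advisory (manual ROIs are conventionally
#' 100-125 pixels): out-of-bound ROIs raise a warning, not an error.
#'
#' @param lesion_rois list of logical masks (or a single mask).
#' @param cnawm optional CNAWM mask.
#' @param whole_lesion optional whole-lesion mask.
#' @param size_bounds advisory pixel-count bounds for lesion ROIs.
#' @return a validated [ROISet].
#' @export
roiSet <- function(lesion_rois, cnawm = NULL, whole_lesion = NULL,
                   size_bounds = c(100, 125)) {
  if (is.matrix(lesion_rois)) lesion_rois <- list(lesion_rois)
  lesion_rois <- lapply(lesion_rois, function(m) {
    storage.mode(m) <- "logical"; m
  })
  sizes <- vapply(lesion_rois, sum, numeric(1))
  bad <- sizes < size_bounds[1L] | sizes > size_bounds[2L]
  if (any(bad))
    warning(sprintf(
      "%d lesion ROI(s) outside the advisory size bounds [%g, %g] px",
      sum(bad), size_bounds[1L], size_bounds[2L]))
  asLogical <- function(m) {
    if (is.null(m)) return(NULL)
    storage.mode(m) <- "logical"; m
  }
  new("ROISet", lesion_rois = lesion_rois, cnawm = asLogical(cnawm),
      whole_lesion = asLogical(whole_lesion))
}

#' Construct a voxel map
#'
#' @param values numeric matrix; entries outside `mask` are set to `NA`.
#' @param mask logical matrix.
#' @param units unit string (`"%"` for APTW maps, `"ppm"` for B0 maps).
#' @return a validated [VoxelMap].
#' @export
voxelMap <- function(values, mask, units) {
  values <- as.matrix(values)
  storage.mode(mask) <- "logical"
  values[!mask] <- NA_real_
  new("VoxelMap", values = values, mask = mask, units = units)
}

## ---------------------------------------------------------------------------
## NIfTI image series
## ---------------------------------------------------------------------------

#' Read a saturated image series with its S0 image and offset table
#'
#' The series is a single NIfTI volume with one 2D frame per acquisition
#' stacked along the third axis, in offset-table expansion order
#' (repeats contiguous); S0 is a separate 2D NIfTI image; the offset
#' table is a CSV (see [readOffsetTable()]).
#'
#' @param series_path NIfTI path of the frame stack.
#' @param s0_path NIfTI path of the unsaturated image.
#' @param offset_table_path CSV path of the offset table.
#' @param mask optional logical matrix; S0 must be strictly positive on it.
#' @return a validated [ZSpectrumSeries].
#' @export
readZSpectrumSeries <- function(series_path, s0_path, offset_table_path,
                                mask = NULL) {
  for (p in c(series_path, s0_path, offset_table_path))
    if (!file.exists(p)) stop("file not found: ", p)
  tab <- readOffsetTable(offset_table_path)
  vol <- RNifti::readNifti(series_path)
  frames <- array(as.numeric(vol), dim = dim(vol))
  if (length(dim(frames)) == 2L)
    frames <- array(frames, c(dim(frames), 1L))
  s0img <- RNifti::readNifti(s0_path)
  s0 <- matrix(as.numeric(s0img), nrow = dim(s0img)[1L])
  pix <- tryCatch(RNifti::pixdim(vol)[1:2], error = function(e) c(1, 1))
  if (length(pix) < 2L || any(!is.finite(pix)) || any(pix <= 0))
    pix <- c(1, 1)
  if (dim(frames)[3L] != nFrames(tab))
    stop(sprintf(
      "series has %d frames but the offset table expands to %d",
      dim(frames)[3L], nFrames(tab)))
  if (!is.null(mask) && any(s0[mask] <= 0))
    stop("S0 is not strictly positive inside the analysis mask")
  zSpectrumSeries(frames, s0, tab, pixel_size_mm = pix)
}

#' Write a z-spectrum series to NIfTI + CSV
#'
#' @param series a [ZSpectrumSeries].
#' @param series_path,s0_path,offset_table_path output paths.
#' @return invisibly, the three paths.
#' @export
writeZSpectrumSeries <- function(series, series_path, s0_path,
                                 offset_table_path) {
  stopifnot(is(series, "ZSpectrumSeries"))
  img <- RNifti::asNifti(series@frames)
  RNifti::pixdim(img) <- c(series@pixel_size_mm, 1)
  RNifti::writeNifti(img, series_path, datatype = "double")
  RNifti::writeNifti(RNifti::asNifti(series@s0), s0_path,
                     datatype = "double")
  writeOffsetTable(series@offset_table, offset_table_path)
  invisible(c(series_path, s0_path, offset_table_path))
}

## ---------------------------------------------------------------------------
## ROI masks
## ---------------------------------------------------------------------------

#' Read / write an ROI set as NIfTI masks
#'
#' @param lesion_paths character vector of lesion ROI mask paths.
#' @param cnawm_path,whole_lesion_path optional mask paths.
#' @return [readROISet()] returns a validated [ROISet].
#' @export
readROISet <- function(lesion_paths, cnawm_path = NULL,
                       whole_lesion_path = NULL) {
  readMask <- function(p) {
    img <- RNifti::readNifti(p)
    m <- matrix(as.numeric(img), nrow = dim(img)[1L])
    if (!all(m %in% c(0, 1))) stop("mask is not binary: ", p)
    m > 0
  }
  roiSet(lapply(lesion_paths, readMask),
         cnawm = if (!is.null(cnawm_path)) readMask(cnawm_path),
         whole_lesion = if (!is.null(whole_lesion_path))
           readMask(whole_lesion_path))
}

#' @rdname readROISet
#' @param rois an [ROISet] to write.
#' @param dir output directory (created if needed).
#' @return [writeROISet()] returns, invisibly, the written paths.
#' @export
writeROISet <- function(rois, dir) {
  stopifnot(is(rois, "ROISet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, name) {
    p <- file.path(dir, paste0(name, ".nii"))
    RNifti::writeNifti(RNifti::asNifti(m * 1), p)
    p
  }
  paths <- mapply(wr, rois@lesion_rois,
                  sprintf("lesion_roi_%02d", seq_along(rois@lesion_rois)))
  if (!is.null(rois@cnawm)) paths <- c(paths, wr(rois@cnawm, "cnawm"))
  if (!is.null(rois@whole_lesion))
    paths <- c(paths, wr(rois@whole_lesion, "whole_lesion"))
  invisible(paths)
}

## ---------------------------------------------------------------------------
## Derived maps
## ---------------------------------------------------------------------------

#' Write / read a derived voxel map (NIfTI + JSON metadata sidecar)
#'
#' The sidecar records the unit string and mask so a round trip is
#' lossless up to float storage precision.
#'
#' @param map a [VoxelMap].
#' @param path NIfTI output path; the sidecar gets extension `.json`.
#' @return [writeVoxelMap()] returns `path` invisibly; [readVoxelMap()]
#'   returns a [VoxelMap].
#' @export
writeVoxelMap <- function(map, path) {
  stopifnot(is(map, "VoxelMap"))
  vals <- map@values
  vals[!map@mask] <- 0
  RNifti::writeNifti(RNifti::asNifti(vals), path, datatype = "double")
  meta <- list(units = map@units, mask = which(map@mask),
               dim = dim(map@mask))
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path),
                                    ".json"))
  invisible(path)
}

#' @rdname writeVoxelMap
#' @export
readVoxelMap <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- matrix(as.numeric(img), nrow = dim(img)[1L])
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path),
                                     ".json"), simplifyVector = TRUE)
  mask <- matrix(FALSE, meta$dim[1L], meta$dim[2L])
  mask[meta$mask] <- TRUE
  voxelMap(vals, mask, meta$units)
}

## ---------------------------------------------------------------------------
## Cohort tables
## ---------------------------------------------------------------------------

.COHORT_COLS <- c("patient_id", "scan_id", "phase", "nihss", "onset_time_h",
                  "post_treatment_time_h", "treated", "effective",
                  "lesion_aptw_pct", "cnawm_aptw_pct", "contrast_pct")

#' Validate a cohort table
#'
#' A cohort table is a plain data.frame with one row per scan:
#' `patient_id`, `scan_id`, `phase` ("pre"/"post"), `nihss` (0-42),
#' `onset_time_h` (time from symptom onset to this scan, hours),
#' `post_treatment_time_h` (time from treatment start to this scan; `NA`
#' for pre-treatment scans), logical `treated` and `effective` flags, and
#' APTW measurements in percent (`lesion_aptw_pct`, `cnawm_aptw_pct`,
#' `contrast_pct`).  Exactly one pre-treatment scan per patient is
#' required.
#'
#' @param cohort data.frame.
#' @return the cohort, invisibly, or an error.
#' @export
validateCohortTable <- function(cohort) {
  miss <- setdiff(.COHORT_COLS, names(cohort))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(cohort$phase %in% c("pre", "post")))
    stop("phase must be 'pre' or 'post'")
  pre <- cohort[cohort$phase == "pre", ]
  if (anyDuplicated(pre$patient_id))
    stop("each patient must have exactly one pre-treatment scan")
  ni <- cohort$nihss[!is.na(cohort$nihss)]
  if (any(ni < 0 | ni > 42)) stop("NIHSS must lie in [0, 42]")
  if (any(cohort$onset_time_h <= 0, na.rm = TRUE))
    stop("onset times must be positive")
  invisible(cohort)
}

#' Read / write a cohort table as CSV
#'
#' @param path CSV path.
#' @return [readCohortTable()] returns a validated cohort data.frame.
#' @export
readCohortTable <- function(path) {
  d <- utils::read.csv(path)
  validateCohortTable(d)
  d
}

#' @rdname readCohortTable
#' @param cohort cohort data.frame to write.
#' @export
writeCohortTable <- function(cohort, path) {
  validateCohortTable(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
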