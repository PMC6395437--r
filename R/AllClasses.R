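#' @include AllGenerics.R
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

## ---------------------------------------------------------------------------
## OffsetTable
## ---------------------------------------------------------------------------

#' Saturation-offset table
#'
#' Describes the saturation-frequency protocol of a z-spectrum series:
#' one row per nominal offset (ppm, positive = downfield of water) with the
#' number of repeated acquisitions at that offset.  The default clinical
#' protocol has 31 unique offsets expanding to 61 frames, with 8 repeats at
#' each of +3.5 and -3.5 ppm (see [defaultOffsetTable()]).
#'
#' @slot offset_ppm numeric, unique signed offsets in ppm, in on-disk frame
#'   order (repeats at one offset are stored contiguously).
#' @slot n_acq integer, number of acquisitions per offset (>= 1).
#' @slot reference_ppm numeric(1), the offset of the registration reference
#'   frame (default 3.5 ppm).
#' @seealso [offsetTable()], [expandOffsets()]
#' @export
setClass("OffsetTable",
  representation(offset_ppm = "numeric", n_acq = "integer",
                 reference_ppm = "numeric"),
  prototype(reference_ppm = 3.5))

setValidity("OffsetTable", function(object) {
  msg <- character()
  if (length(object@offset_ppm) != length(object@n_acq))
    msg <- c(msg, "offset_ppm and n_acq must have equal length")
  if (anyDuplicated(object@offset_ppm))
    msg <- c(msg, "offsets must be unique")
  if (any(!is.finite(object@offset_ppm)))
    msg <- c(msg, "offsets must be finite")
  if (any(object@n_acq < 1L))
    msg <- c(msg, "n_acq must be positive")
  if (length(object@reference_ppm) != 1L || !is.finite(object@reference_ppm))
    msg <- c(msg, "reference_ppm must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' @describeIn OffsetTable unique nominal offsets in table order.
#' @export
setMethod("offsets", "OffsetTable", function(x) x@offset_ppm)

#' @describeIn OffsetTable total number of frames after expansion.
#' @export
setMethod("nFrames", "OffsetTable", function(x) sum(x@n_acq))

## ---------------------------------------------------------------------------
## SaturationSpec / PoolParameterSet
## ---------------------------------------------------------------------------

#' Continuous-wave saturation block
#'
#' @slot b1_uT numeric(1), RF amplitude in microtesla (>= 0).
#' @slot duration_ms numeric(1), saturation duration in milliseconds (> 0).
#' @slot waveform character(1), only `"cw"` (continuous wave) is supported.
#' @seealso [saturationSpec()]
#' @export
setClass("SaturationSpec",
  representation(b1_uT = "numeric", duration_ms = "numeric",
                 waveform = "character"),
  prototype(b1_uT = 2, duration_ms = 800, waveform = "cw"))

setValidity("SaturationSpec", function(object) {
  msg <- character()
  if (length(object@b1_uT) != 1L || !is.finite(object@b1_uT) ||
      object@b1_uT < 0)
    msg <- c(msg, "b1_uT must be a single finite number >= 0")
  if (length(object@duration_ms) != 1L || !is.finite(object@duration_ms) ||
      object@duration_ms <= 0)
    msg <- c(msg, "duration_ms must be a single positive number")
  if (!identical(object@waveform, "cw"))
    msg <- c(msg, "only continuous-wave ('cw') saturation is supported")
  if (length(msg)) msg else TRUE
})

#' Multi-pool exchange model parameters
#'
#' One row per proton pool: free water plus any number of exchanging or
#' cross-relaxing pools (semisolid MT, amide, NOE, ...).  Proton fractions
#' are relative to water; exchange rates are pool-to-water first-order
#' rates in 1/s, with the reverse rate fixed by detailed balance.
#'
#' @slot pools data.frame with columns `name`, `shift_ppm`, `fraction`,
#'   `T1_s`, `T2_s`, `k_per_s`; the water pool (shift 0, fraction 1) must
#'   be the first row.
#' @slot field_T numeric(1), static field strength in tesla (default 3).
#' @seealso [poolParameterSet()], [defaultPoolSet()]
#' @export
setClass("PoolParameterSet",
  representation(pools = "data.frame", field_T = "numeric"),
  prototype(field_T = 3))

setValidity("PoolParameterSet", function(object) {
  p <- object@pools
  need <- c("name", "shift_ppm", "fraction", "T1_s", "T2_s", "k_per_s")
  if (!all(need %in% names(p)))
    return(paste("pools must have columns", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(p) < 1L || p$shift_ppm[1L] != 0 || p$fraction[1L] != 1)
    msg <- c(msg, "first pool must be water with shift 0 and fraction 1")
  if (any(p$T1_s <= 0) || any(p$T2_s <= 0))
    msg <- c(msg, "all relaxation times must be positive")
  if (any(p$k_per_s < 0))
    msg <- c(msg, "exchange rates must be nonnegative")
  if (any(p$fraction < 0))
    msg <- c(msg, "proton fractions must be nonnegative")
  if (any(!is.finite(as.matrix(p[-1L]))))
    msg <- c(msg, "pool parameters must be finite")
  if (length(object@field_T) != 1L || !is.finite(object@field_T) ||
      object@field_T <= 0)
    msg <- c(msg, "field_T must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @describeIn PoolParameterSet the pool parameter data.frame.
#' @export
setMethod("poolTable", "PoolParameterSet", function(x) x@pools)

## ---------------------------------------------------------------------------
## ZSpectrumSeries
## ---------------------------------------------------------------------------

#' Saturated image series with its unsaturated reference
#'
#' The raw (or registered / repeat-averaged) acquisition: one 2D image per
#' saturated frame, stacked along the third array axis in offset-table
#' expansion order, plus the unsaturated S0 image used for normalization.
#'
#' @slot frames numeric array `nrow x ncol x nframes`.
#' @slot s0 numeric matrix, same in-plane dimensions as the frames.
#' @slot offset_table an [OffsetTable] whose expansion length equals the
#'   number of frames.
#' @slot pixel_size_mm numeric(2), in-plane pixel spacing.
#' @seealso [zSpectrumSeries()], [readZSpectrumSeries()], [averageRepeats()]
#' @export
setClass("ZSpectrumSeries",
  representation(frames = "array", s0 = "matrix",
                 offset_table = "OffsetTable", pixel_size_mm = "numeric"),
  prototype(pixel_size_mm = c(1, 1)))

setValidity("ZSpectrumSeries", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    return("frames must be a 3D array (rows x cols x frames)")
  if (!identical(d[1:2], dim(object@s0)))
    msg <- c(msg, "frames and s0 image must share in-plane dimensions")
  if (d[3L] != nFrames(object@offset_table))
    msg <- c(msg, sprintf(
      "frame count (%d) does not match offset-table expansion length (%d)",
      d[3L], nFrames(object@offset_table)))
  if (length(object@pixel_size_mm) != 2L || any(object@pixel_size_mm <= 0))
    msg <- c(msg, "pixel_size_mm must be two positive numbers")
  if (length(msg)) msg else TRUE
})

#' @describeIn ZSpectrumSeries the series' offset table's unique offsets.
#' @export
setMethod("offsets", "ZSpectrumSeries", function(x) offsets(x@offset_table))

#' @describeIn ZSpectrumSeries number of stored frames.
#' @export
setMethod("nFrames", "ZSpectrumSeries", function(x) dim(x@frames)[3L])

#' @describeIn ZSpectrumSeries the S0 image.
#' @export
setMethod("s0Image", "ZSpectrumSeries", function(x) x@s0)

#' @describeIn ZSpectrumSeries the frame array.
#' @export
setMethod("seriesFrames", "ZSpectrumSeries", function(x) x@frames)

## ---------------------------------------------------------------------------
## ZSpectrumStack / VoxelMap
## ---------------------------------------------------------------------------

#' Per-voxel z-spectra on the unique nominal offsets
#'
#' Produced by [normalizeSeries()]: one normalized spectrum S_sat/S_0 per
#' masked voxel, on strictly increasing unique offsets.  Voxels whose S0 is
#' nonpositive (or whose B0 fit fails downstream) carry `valid = FALSE`.
#'
#' @slot values numeric matrix, `n_masked_voxels x n_offsets`.
#' @slot offsets_ppm numeric, strictly increasing.
#' @slot mask logical matrix; `values` rows correspond to `which(mask)`.
#' @slot valid logical, one flag per masked voxel.
#' @export
setClass("ZSpectrumStack",
  representation(values = "matrix", offsets_ppm = "numeric",
                 mask = "matrix", valid = "logical"))

setValidity("ZSpectrumStack", function(object) {
  msg <- character()
  if (is.unsorted(object@offsets_ppm, strictly = TRUE))
    msg <- c(msg, "offsets must be strictly increasing")
  if (ncol(object@values) != length(object@offsets_ppm))
    msg <- c(msg, "one value column per offset required")
  if (nrow(object@values) != sum(object@mask))
    msg <- c(msg, "one value row per masked voxel required")
  if (length(object@valid) != nrow(object@values))
    msg <- c(msg, "one validity flag per masked voxel required")
  v <- object@values[object@valid, , drop = FALSE]
  if (length(v) && any(is.finite(v) & (v < -0.5 | v > 1.5)))
    msg <- c(msg, "normalized values outside [-0.5, 1.5]; check S0")
  if (length(msg)) msg else TRUE
})

#' @describeIn ZSpectrumStack sorted unique offsets.
#' @export
setMethod("offsets", "ZSpectrumStack", function(x) x@offsets_ppm)

#' @describeIn ZSpectrumStack the per-voxel value matrix.
#' @export
setMethod("stackValues", "ZSpectrumStack", function(x) x@values)

#' @describeIn ZSpectrumStack the analysis mask.
#' @export
setMethod("mapMask", "ZSpectrumStack", function(x) x@mask)

#' Derived voxel map (APTW, B0, ...)
#'
#' A single-valued voxel map over an analysis mask.  APTW maps are stored
#' in percent of the bulk water signal; B0 maps in ppm.  Voxels excluded
#' by the mask, or flagged invalid upstream, are `NA`.
#'
#' @slot values numeric matrix with `NA` outside the mask.
#' @slot mask logical matrix.
#' @slot units character(1), e.g. `"%"` or `"ppm"`.
#' @export
setClass("VoxelMap",
  representation(values = "matrix", mask = "matrix", units = "character"))

setValidity("VoxelMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask dimensions differ")
  if (any(!is.na(object@values[!object@mask])))
    msg <- c(msg, "values outside the mask must be NA")
  if (length(object@units) != 1L)
    msg <- c(msg, "units must be a single string")
  if (length(msg)) msg else TRUE
})

#' @describeIn VoxelMap the value matrix.
#' @export
setMethod("mapValues", "VoxelMap", function(x) x@values)

#' @describeIn VoxelMap the analysis mask.
#' @export
setMethod("mapMask", "VoxelMap", function(x) x@mask)

## ---------------------------------------------------------------------------
## ROISet
## ---------------------------------------------------------------------------

#' Lesion, CNAWM, and whole-lesion regions of interest
#'
#' Lesion ROIs are small regions (conventionally 100-125 pixels each)
#' placed inside the infarct; the CNAWM ROI is the contralateral
#' normal-appearing white matter reference, either given explicitly or
#' derived by mirroring a lesion ROI across the brain midline.
#'
#' @slot lesion_rois list of logical matrices, all the same dimensions.
#' @slot cnawm logical matrix or `NULL`.
#' @slot whole_lesion logical matrix or `NULL`.
#' @seealso [roiSet()], [mirrorROI()], [measureLesion()]
#' @export
setClass("ROISet",
  representation(lesion_rois = "list", cnawm = "matrixOrNULL",
                 whole_lesion = "matrixOrNULL"))

setValidity("ROISet", function(object) {
  if (!length(object@lesion_rois))
    return("at least one lesion ROI is required")
  dims <- lapply(object@lesion_rois, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    return("all lesion ROIs must share dimensions")
  msg <- character()
  d <- dims[[1L]]
  if (!all(vapply(object@lesion_rois, is.logical, logical(1))))
    msg <- c(msg, "ROIs must be logical masks")
  if (any(vapply(object@lesion_rois, sum, numeric(1)) == 0))
    msg <- c(msg, "lesion ROIs must be nonempty")
  if (!is.null(object@cnawm)) {
    if (!identical(dim(object@cnawm), d))
      msg <- c(msg, "CNAWM ROI dimensions differ from lesion ROIs")
    else if (any(Reduce(`|`, object@lesion_rois) & object@cnawm))
      msg <- c(msg, "lesion ROIs must not overlap the CNAWM ROI")
  }
  if (!is.null(object@whole_lesion) &&
      !identical(dim(object@whole_lesion), d))
    msg <- c(msg, "whole-lesion mask dimensions differ from lesion ROIs")
  if (length(msg)) msg else TRUE
})

#' @describeIn ROISet list of lesion ROI masks.
#' @export
setMethod("lesionROIs", "ROISet", function(x) x@lesion_rois)

#' @describeIn ROISet the CNAWM ROI mask (or `NULL`).
#' @export
setMethod("cnawmROI", "ROISet", function(x) x@cnawm)

#' @describeIn ROISet the whole-lesion mask (or `NULL`).
#' @export
setMethod("wholeLesionMask", "ROISet", function(x) x@whole_lesion)

## ---------------------------------------------------------------------------
## RigidTransform2D
## ---------------------------------------------------------------------------

#' Rigid-body 2D transform (3 degrees of freedom)
#'
#' Translation in pixels (x = column, y = row), rotation in degrees
#' (counterclockwise) about a fixed center, conventionally the image
#' center.  Applying the transform to an image moves its content by
#' `(tx, ty)` and rotates it by `theta` about the center.
#'
#' @slot tx_px,ty_px numeric(1) translations in pixels.
#' @slot theta_deg numeric(1) rotation in degrees.
#' @slot center numeric(2), `(x, y)` center of rotation in pixel units.
#' @seealso [rigidTransform2D()], [applyRigidTransform()],
#'   [invertTransform()], [composeTransforms()]
#' @export
setClass("RigidTransform2D",
  representation(tx_px = "numeric", ty_px = "numeric", theta_deg = "numeric",
                 center = "numeric"))

setValidity("RigidTransform2D", function(object) {
  ok <- all(vapply(list(object@tx_px, object@ty_px, object@theta_deg),
                   function(v) length(v) == 1L && is.finite(v), logical(1)))
  if (!ok) return("tx, ty, theta must be single finite numbers")
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    return("center must be two finite numbers")
  TRUE
})

## ---------------------------------------------------------------------------
## PhantomSpec
## ---------------------------------------------------------------------------

#' Specification of a synthetic z-spectrum phantom
#'
#' Encodes the simulated acquisition: image geometry, a circular ischemic
#' lesion embedded in background tissue, per-class pH (driving the amide
#' exchange rate), a smooth B0 inhomogeneity field, a noise model, and
#' optional per-frame rigid motion jitter.
#'
#' @slot shape integer(2), image dimensions (rows, cols).
#' @slot lesion_center numeric(2), lesion center (row, col).
#' @slot lesion_radius_px numeric(1), lesion radius in pixels.
#' @slot lesion_ph,background_ph numeric(1), tissue pH in \[5.5, 8\].
#' @slot lesion_amide_k,background_amide_k numeric(1); when finite these
#'   override the pH-derived amide exchange rate (used when embedding a
#'   calibrated ground-truth APTW value, see [calibrateAmideExchange()]).
#' @slot pools a [PoolParameterSet] template shared by both tissue classes.
#' @slot sat a [SaturationSpec].
#' @slot offset_table an [OffsetTable].
#' @slot b0_amplitude_ppm numeric(1), peak |B0| of the smooth 2nd-order
#'   polynomial field (0 disables the field).
#' @slot texture_amplitude numeric(1), relative amplitude of the smooth
#'   multiplicative anatomy texture shared by S0 and all frames (it
#'   cancels exactly in S_sat/S_0 but gives registration anatomical
#'   contrast; 0 disables).
#' @slot noise character(1), `"none"`, `"gaussian"` or `"rician"`.
#' @slot noise_sigma numeric(1), noise SD relative to S0.
#' @slot motion_px numeric(1), max per-frame translation jitter (0 = none).
#' @slot motion_deg numeric(1), max per-frame rotation jitter.
#' @slot seed integer(1), seed for all stochastic elements.
#' @seealso [phantomSpec()], [buildPhantom()]
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", lesion_center = "numeric",
                 lesion_radius_px = "numeric",
                 lesion_ph = "numeric", background_ph = "numeric",
                 lesion_amide_k = "numeric", background_amide_k = "numeric",
                 pools = "PoolParameterSet", sat = "SaturationSpec",
                 offset_table = "OffsetTable",
                 b0_amplitude_ppm = "numeric",
                 texture_amplitude = "numeric",
                 noise = "character", noise_sigma = "numeric",
                 motion_px = "numeric", motion_deg = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 2L || any(object@shape < 8L))
    msg <- c(msg, "shape must be two dimensions of at least 8 pixels")
  for (ph in c(object@lesion_ph, object@background_ph))
    if (ph < 5.5 || ph > 8.0)
      msg <- c(msg, "pH must lie within [5.5, 8.0]")
  r <- object@lesion_radius_px
  ctr <- object@lesion_center
  if (any(ctr - r < 0.5) || ctr[1L] + r > object@shape[1L] + 0.5 ||
      ctr[2L] + r > object@shape[2L] + 0.5)
    msg <- c(msg, "lesion extends outside the image")
  if (!object@noise %in% c("none", "gaussian", "rician"))
    msg <- c(msg, "noise must be one of none, gaussian, rician")
  if (object@noise_sigma < 0)
    msg <- c(msg, "noise sigma must be nonnegative")
  if (object@b0_amplitude_ppm < 0)
    msg <- c(msg, "b0 amplitude must be nonnegative")
  if (object@texture_amplitude < 0 || object@texture_amplitude >= 1)
    msg <- c(msg, "texture amplitude must lie in [0, 1)")
  if (object@motion_px < 0 || object@motion_deg < 0)
    msg <- c(msg, "motion jitter bounds must be nonnegative")
  if (length(msg)) msg else TRUE
})
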