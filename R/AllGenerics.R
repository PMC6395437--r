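#' @include aptwcest-package.R
NULL

#' Offsets of an object carrying a saturation-offset axis
#'
#' @param x an [OffsetTable], [ZSpectrumSeries] or [ZSpectrumStack].
#' @return numeric vector of offsets in ppm (positive = downfield of water).
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))

#' Number of saturated frames described or stored
#'
#' @param x an [OffsetTable] or [ZSpectrumSeries].
#' @return integer frame count (repeated acquisitions counted separately).
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Unsaturated reference image of a series
#'
#' @param x a [ZSpectrumSeries].
#' @return numeric matrix, the S0 image.
#' @export
setGeneric("s0Image", function(x) standardGeneric("s0Image"))

#' Saturated frames of a series
#'
#' @param x a [ZSpectrumSeries].
#' @return numeric array `nrow x ncol x nframes`.
#' @export
setGeneric("seriesFrames", function(x) standardGeneric("seriesFrames"))

#' Voxel values of a derived map
#'
#' @param x a [VoxelMap].
#' @return numeric matrix with `NA` outside the analysis mask.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Analysis mask of a map or stack
#'
#' @param x a [VoxelMap] or [ZSpectrumStack].
#' @return logical matrix.
#' @export
setGeneric("mapMask", function(x) standardGeneric("mapMask"))

#' Per-voxel z-spectrum values of a stack
#'
#' @param x a [ZSpectrumStack].
#' @return numeric matrix, one row per masked voxel, one column per offset.
#' @export
setGeneric("stackValues", function(x) standardGeneric("stackValues"))

#' Lesion regions of interest
#'
#' @param x an [ROISet].
#' @return list of logical matrices.
#' @export
setGeneric("lesionROIs", function(x) standardGeneric("lesionROIs"))

#' Contralateral normal-appearing white matter ROI
#'
#' @param x an [ROISet].
#' @return logical matrix, or `NULL` when absent.
#' @export
setGeneric("cnawmROI", function(x) standardGeneric("cnawmROI"))

#' Whole-lesion mask
#'
#' @param x an [ROISet].
#' @return logical matrix, or `NULL` when absent.
#' @export
setGeneric("wholeLesionMask", function(x) standardGeneric("wholeLesionMask"))

#' Pool parameter table
#'
#' @param x a [PoolParameterSet].
#' @return data.frame with one row per proton pool.
#' @export
setGeneric("poolTable", function(x) standardGeneric("poolTable"))
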