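#' @include AllClasses.R
NULL

setMethod("show", "OffsetTable", function(object) {
  cat(sprintf("OffsetTable: %d unique offsets, %d frames, reference %+g ppm\n",
              length(object@offset_ppm), nFrames(object),
              object@reference_ppm))
  cat("  offsets (ppm):",
      paste(sprintf("%g", sort(object@offset_ppm)), collapse = " "), "\n")
})

setMethod("show", "SaturationSpec", function(object) {
  cat(sprintf("SaturationSpec: CW, B1 = %g uT, duration = %g ms\n",
              object@b1_uT, object@duration_ms))
})

setMethod("show", "PoolParameterSet", function(object) {
  cat(sprintf("PoolParameterSet at %g T, %d pools:\n", object@field_T,
              nrow(object@pools)))
  print(object@pools, row.names = FALSE, digits = 4)
})

setMethod("show", "ZSpectrumSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "ZSpectrumSeries: %d x %d pixels, %d frames (%d unique offsets)\n",
    d[1L], d[2L], d[3L], length(offsets(object))))
})

setMethod("show", "ZSpectrumStack", function(object) {
  cat(sprintf(
    "ZSpectrumStack: %d masked voxels (%d valid), %d offsets [%g, %g] ppm\n",
    nrow(object@values), sum(object@valid), length(object@offsets_ppm),
    min(object@offsets_ppm), max(object@offsets_ppm)))
})

setMethod("show", "VoxelMap", function(object) {
  v <- object@values[object@mask]
  cat(sprintf(
    "VoxelMap (%s): %d x %d, %d masked voxels, range [%.3g, %.3g]\n",
    object@units, nrow(object@values), ncol(object@values),
    sum(object@mask), min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "ROISet", function(object) {
  sizes <- vapply(object@lesion_rois, sum, numeric(1))
  cat(sprintf("ROISet: %d lesion ROI(s) of %s px, CNAWM %s, whole lesion %s\n",
              length(sizes), paste(sizes, collapse = "/"),
              if (is.null(object@cnawm)) "absent" else "present",
              if (is.null(object@whole_lesion)) "absent"
              else sprintf("%d px", sum(object@whole_lesion))))
})

setMethod("show", "RigidTransform2D", function(object) {
  cat(sprintf(
    "RigidTransform2D: tx = %.3f px, ty = %.3f px, theta = %.3f deg\n",
    object@tx_px, object@ty_px, object@theta_deg))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d, lesion r = %g px (pH %.2f) in background pH %.2f\n",
    object@shape[1L], object@shape[2L], object@lesion_radius_px,
    object@lesion_ph, object@background_ph))
  cat(sprintf("  B0 amplitude %g ppm, noise %s (sigma %g), seed %d\n",
              object@b0_amplitude_ppm, object@noise, object@noise_sigma,
              object@seed))
})
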