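#' @include bloch.R
NULL

#' Construct a phantom specification
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' a 64x64 single-slice acquisition with the 31-offset / 61-frame
#' protocol, CW saturation of 800 ms at 2 uT, an acute ischemic lesion
#' (pH 6.4) embedded in normal tissue (pH 7.0) so the lesion-minus-
#' background APTW is negative at baseline, a smooth second-order
#' polynomial B0 field, and Rician noise appropriate for magnitude MRI.
#'
#' @param shape image dimensions (rows, cols).
#' @param lesion_center lesion center (row, col); default places the
#'   lesion in the left hemisphere so its mirror lies in the right.
#' @param lesion_radius_px lesion radius in pixels.
#' @param lesion_ph,background_ph tissue pH per class.
#' @param lesion_amide_k,background_amide_k optional explicit amide
#'   exchange rates (1/s) overriding the pH-derived rates.
#' @param pools pool template shared by both tissue classes.
#' @param sat saturation block.
#' @param offset_table acquisition protocol.
#' @param b0_amplitude_ppm peak |B0| of the polynomial field (ppm).
#' @param texture_amplitude relative amplitude of the smooth
#'   multiplicative anatomy texture applied to S0 and every frame.
#' @param noise `"none"`, `"gaussian"` or `"rician"`.
#' @param noise_sigma noise SD relative to S0.
#' @param motion_px,motion_deg per-frame rigid jitter bounds (0 = none).
#' @param seed integer seed controlling field coefficients, noise and
#'   motion; identical specs and seeds yield identical phantoms.
#' @return a [PhantomSpec].
#' @export
phantomSpec <- function(shape = c(64L, 64L),
                        lesion_center = c(shape[1L] / 2, shape[2L] * 0.3),
                        lesion_radius_px = 12,
                        lesion_ph = 6.4, background_ph = 7.0,
                        lesion_amide_k = NA_real_,
                        background_amide_k = NA_real_,
                        pools = defaultPoolSet(),
                        sat = saturationSpec(),
                        offset_table = defaultOffsetTable(),
                        b0_amplitude_ppm = 0.3,
                        texture_amplitude = 0.3,
                        noise = c("none", "gaussian", "rician"),
                        noise_sigma = 0,
                        motion_px = 0, motion_deg = 0,
                        seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape),
      lesion_center = as.numeric(lesion_center),
      lesion_radius_px = lesion_radius_px,
      lesion_ph = lesion_ph, background_ph = background_ph,
      lesion_amide_k = lesion_amide_k,
      background_amide_k = background_amide_k,
      pools = pools, sat = sat, offset_table = offset_table,
      b0_amplitude_ppm = b0_amplitude_ppm,
      texture_amplitude = texture_amplitude,
      noise = match.arg(noise), noise_sigma = noise_sigma,
      motion_px = motion_px, motion_deg = motion_deg,
      seed = as.integer(seed))
}

## circular lesion mask
.diskMask <- function(shape, center, radius) {
  r <- outer(seq_len(shape[1L]) - center[1L],
             seq_len(shape[2L]) - center[2L],
             function(dr, dc) sqrt(dr^2 + dc^2))
  r <= radius
}

## smooth second-order 2D polynomial B0 field scaled to a peak amplitude;
## coefficients are drawn deterministically from the phantom seed
.b0Field <- function(shape, amplitude_ppm, seed) {
  if (amplitude_ppm == 0) return(matrix(0, shape[1L], shape[2L]))
  coef <- withr_seed(seed + 7L, function() stats::runif(5L, -1, 1))
  u <- matrix(seq(-1, 1, length.out = shape[1L]), shape[1L], shape[2L])
  v <- matrix(seq(-1, 1, length.out = shape[2L]), shape[1L], shape[2L],
              byrow = TRUE)
  f <- coef[1L] * u + coef[2L] * v + coef[3L] * u * v +
       coef[4L] * u^2 + coef[5L] * v^2
  f * (amplitude_ppm / max(abs(f)))
}

## smooth multiplicative anatomy texture (sum of Gaussian lumps) shared
## by S0 and every saturated frame; mean ~1, range within 1 +/- amplitude
.anatomyTexture <- function(shape, amplitude, seed) {
  if (amplitude == 0) return(matrix(1, shape[1L], shape[2L]))
  par <- withr_seed(seed + 13L, function()
    matrix(stats::runif(16L * 4L), ncol = 4L))
  f <- matrix(0, shape[1L], shape[2L])
  rows <- seq_len(shape[1L]); cols <- seq_len(shape[2L])
  for (i in seq_len(nrow(par))) {
    cy <- 1 + par[i, 1L] * (shape[1L] - 1); cx <- 1 + par[i, 2L] *
      (shape[2L] - 1)
    sg <- 2.5 + 4 * par[i, 3L]
    f <- f + (par[i, 4L] - 0.5) *
      outer(exp(-(rows - cy)^2 / (2 * sg^2)),
            exp(-(cols - cx)^2 / (2 * sg^2)))
  }
  1 + f * (amplitude / max(abs(f)))
}

## run fn under a temporary RNG state
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

## pool set of one tissue class: template with the amide rate set from pH
## (or an explicit override)
.classPools <- function(spec, class = c("background", "lesion")) {
  class <- match.arg(class)
  k <- if (class == "lesion") spec@lesion_amide_k else spec@background_amide_k
  ph <- if (class == "lesion") spec@lesion_ph else spec@background_ph
  if (!"amide" %in% spec@pools@pools$name) return(spec@pools)
  if (!is.finite(k)) k <- phToExchangeRate(ph)
  setAmideExchangeRate(spec@pools, k)
}

## dense reference z-spectrum of one tissue class, returned as a function
## of offset; queries beyond the simulated range are clamped.  When no B0
## field is present only the nominal offsets are simulated.
.classSpectrumFun <- function(pools, sat, nominal, b0_amp) {
  if (b0_amp == 0) {
    xs <- sort(unique(nominal))
    zs <- simulateZSpectrum(pools, sat, xs)
    return(function(q) {
      i <- match(round(q, 9), round(xs, 9))
      if (any(is.na(i))) stats::spline(xs, zs, xout = q)$y else zs[i]
    })
  }
  step <- 0.02
  xs <- seq(min(nominal) - b0_amp - step, max(nominal) + b0_amp + step,
            by = step)
  zs <- simulateZSpectrum(pools, sat, xs)
  function(q) stats::spline(xs, zs, xout = pmin(pmax(q, min(xs)),
                                                max(xs)))$y
}

.addNoise <- function(img, model, sigma) {
  if (model == "none" || sigma == 0) return(img)
  n1 <- matrix(stats::rnorm(length(img), sd = sigma), nrow(img))
  if (model == "gaussian") return(img + n1)
  n2 <- matrix(stats::rnorm(length(img), sd = sigma), nrow(img))
  sqrt((img + n1)^2 + n2^2)  # magnitude (Rician) noise
}

#' Place disjoint square lesion ROIs inside a lesion mask
#'
#' Deterministic stand-in for manual ROI placement: square ROIs of
#' `floor(sqrt(px))` by `ceiling(px / side)` pixels (within the requested
#' size bounds) are tiled greedily, left to right and top to bottom,
#' wherever they fit entirely inside the lesion mask without overlap.
#'
#' @param lesion_mask logical matrix.
#' @param n_px_min,n_px_max ROI pixel-count bounds (default 100-125).
#' @param max_rois cap on the number of ROIs returned.
#' @return list of logical ROI masks (>= 1, or an error when none fits).
#' @export
autoLesionROIs <- function(lesion_mask, n_px_min = 100, n_px_max = 125,
                           max_rois = 8L) {
  side_r <- 10L; side_c <- 11L   # 110 px, inside the default 100-125 bound
  if (side_r * side_c < n_px_min || side_r * side_c > n_px_max) {
    side_r <- side_c <- as.integer(floor(sqrt(n_px_max)))
  }
  taken <- matrix(FALSE, nrow(lesion_mask), ncol(lesion_mask))
  rois <- list()
  for (r in seq_len(nrow(lesion_mask) - side_r + 1L)) {
    for (cl in seq_len(ncol(lesion_mask) - side_c + 1L)) {
      if (length(rois) >= max_rois) break
      rows <- r:(r + side_r - 1L); cols <- cl:(cl + side_c - 1L)
      if (all(lesion_mask[rows, cols]) && !any(taken[rows, cols])) {
        m <- matrix(FALSE, nrow(lesion_mask), ncol(lesion_mask))
        m[rows, cols] <- TRUE
        taken[rows, cols] <- TRUE
        rois[[length(rois) + 1L]] <- m
      }
    }
  }
  if (!length(rois))
    stop("lesion mask too small to hold a single ROI of the requested size")
  rois
}

#' Build a synthetic z-spectrum phantom
#'
#' Simulates a circular-lesion phantom from the multi-pool
#' Bloch-McConnell model: per-voxel z-spectra follow the voxel's tissue
#' class, a voxel B0 shift of delta displaces its apparent spectrum so
#' the nominal offsets sample the class spectrum at (offset - delta),
#' repeated acquisitions receive independent noise, and optional rigid
#' per-frame jitter emulates patient motion.  Ground-truth maps (APTW,
#' APTR, B0) and an automatically placed [ROISet] accompany the series.
#'
#' @param spec a [PhantomSpec].
#' @return list with elements `series` ([ZSpectrumSeries]), `truth`
#'   (list of [VoxelMap]s: `aptw`, `aptr`, `b0`), `rois` ([ROISet]),
#'   `lesion_mask` (logical matrix) and `truth_values` (the per-class
#'   decompositions from [groundTruthDecomposition()]).
#' @examples
#' ph <- buildPhantom(phantomSpec(shape = c(32, 32), lesion_radius_px = 9,
#'                                b0_amplitude_ppm = 0))
#' @export
buildPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  shape <- spec@shape
  lesion <- .diskMask(shape, spec@lesion_center, spec@lesion_radius_px)
  b0 <- .b0Field(shape, spec@b0_amplitude_ppm, spec@seed)

  pools_bg <- .classPools(spec, "background")
  pools_ls <- .classPools(spec, "lesion")
  per_frame <- expandOffsets(spec@offset_table)
  zfun_bg <- .classSpectrumFun(pools_bg, spec@sat, per_frame,
                               spec@b0_amplitude_ppm)
  zfun_ls <- .classSpectrumFun(pools_ls, spec@sat, per_frame,
                               spec@b0_amplitude_ppm)

  # noiseless voxel values per unique offset, then expand to frames
  uoff <- offsets(spec@offset_table)
  vox_bg <- vapply(uoff, function(o) zfun_bg(o - b0[!lesion]),
                   numeric(sum(!lesion)))
  vox_ls <- vapply(uoff, function(o) zfun_ls(o - b0[lesion]),
                   numeric(sum(lesion)))
  base <- array(0, c(shape, length(uoff)))
  for (j in seq_along(uoff)) {
    m <- matrix(0, shape[1L], shape[2L])
    m[!lesion] <- vox_bg[, j]
    m[lesion] <- vox_ls[, j]
    base[, , j] <- m
  }

  texture <- .anatomyTexture(shape, spec@texture_amplitude, spec@seed)
  frames <- withr_seed(spec@seed, function() {
    out <- array(0, c(shape, length(per_frame)))
    jit <- NULL
    if (spec@motion_px > 0 || spec@motion_deg > 0)
      jit <- cbind(stats::runif(length(per_frame), -spec@motion_px,
                                spec@motion_px),
                   stats::runif(length(per_frame), -spec@motion_px,
                                spec@motion_px),
                   stats::runif(length(per_frame), -spec@motion_deg,
                                spec@motion_deg))
    for (i in seq_along(per_frame)) {
      img <- texture * base[, , match(per_frame[i], uoff)]
      if (!is.null(jit))
        img <- applyRigidTransform(img, rigidTransform2D(
          jit[i, 1L], jit[i, 2L], jit[i, 3L], dim(img)))
      out[, , i] <- .addNoise(img, spec@noise, spec@noise_sigma)
    }
    out
  })
  s0 <- withr_seed(spec@seed + 1L, function()
    .addNoise(texture, spec@noise, spec@noise_sigma))

  series <- zSpectrumSeries(frames, s0, spec@offset_table)

  dec_bg <- groundTruthDecomposition(pools_bg, spec@sat)
  dec_ls <- groundTruthDecomposition(pools_ls, spec@sat)
  paint <- function(vb, vl) {
    m <- matrix(vb, shape[1L], shape[2L]); m[lesion] <- vl; m
  }
  all_mask <- matrix(TRUE, shape[1L], shape[2L])
  truth <- list(
    aptw = voxelMap(paint(dec_bg$aptw_pct, dec_ls$aptw_pct), all_mask, "%"),
    aptr = voxelMap(paint(dec_bg$aptr_pct, dec_ls$aptr_pct), all_mask, "%"),
    b0 = voxelMap(b0, all_mask, "ppm"))

  # lesions too small for the conventional 100-125 px ROIs fall back to
  # a single whole-lesion ROI
  lesion_rois <- tryCatch(autoLesionROIs(lesion), error = function(e) NULL)
  rois <- if (is.null(lesion_rois))
    roiSet(list(lesion), whole_lesion = lesion, size_bounds = c(1, Inf))
  else roiSet(lesion_rois, cnawm = NULL, whole_lesion = lesion)

  list(series = series, truth = truth, rois = rois, lesion_mask = lesion,
       truth_values = list(background = dec_bg, lesion = dec_ls))
}
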