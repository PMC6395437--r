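#' @include AllClasses.R
NULL

#' Construct a rigid 2D transform
#'
#' @param tx_px,ty_px translation in pixels (x = column, y = row).
#' @param theta_deg counterclockwise rotation in degrees.
#' @param dim image dimensions (rows, cols) from which the default
#'   rotation center (the image center) is taken, or `NULL` when
#'   `center` is given.
#' @param center explicit `(x, y)` rotation center in pixel units.
#' @return a [RigidTransform2D].
#' @export
rigidTransform2D <- function(tx_px = 0, ty_px = 0, theta_deg = 0,
                             dim = NULL, center = NULL) {
  if (is.null(center)) {
    if (is.null(dim)) stop("either dim or center must be given")
    center <- c((dim[2L] + 1) / 2, (dim[1L] + 1) / 2)  # (x, y)
  }
  new("RigidTransform2D", tx_px = tx_px, ty_px = ty_px,
      theta_deg = theta_deg, center = as.numeric(center))
}

#' Invert / compose rigid transforms
#'
#' Transforms act on coordinates as `q = R(theta) (p - c) + c + t`.
#' The inverse therefore has angle `-theta` and translation
#' `-R(-theta) t`; composition `a`-then-`b` requires a shared center.
#'
#' @param tf,a,b [RigidTransform2D] objects.
#' @return a [RigidTransform2D].
#' @export
invertTransform <- function(tf) {
  th <- -tf@theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  t2 <- -as.vector(R %*% c(tf@tx_px, tf@ty_px))
  new("RigidTransform2D", tx_px = t2[1L], ty_px = t2[2L],
      theta_deg = -tf@theta_deg, center = tf@center)
}

#' @rdname invertTransform
#' @export
composeTransforms <- function(b, a) {
  if (max(abs(a@center - b@center)) > 1e-9)
    stop("transforms must share a rotation center")
  thb <- b@theta_deg * pi / 180
  R <- matrix(c(cos(thb), sin(thb), -sin(thb), cos(thb)), 2L)
  t2 <- as.vector(R %*% c(a@tx_px, a@ty_px)) + c(b@tx_px, b@ty_px)
  new("RigidTransform2D", tx_px = t2[1L], ty_px = t2[2L],
      theta_deg = a@theta_deg + b@theta_deg, center = a@center)
}

## bilinear sampling at arbitrary (x, y) with edge-value fill
.bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * nr + y0
  v00 <- img[i00];        v10 <- img[i00 + nr]
  v01 <- img[i00 + 1L];   v11 <- img[i00 + nr + 1L]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

#' Apply a rigid transform to an image
#'
#' Moves the image content by `(tx, ty)` pixels and rotates it by
#' `theta` about the transform center, using bilinear interpolation with
#' edge-value fill.
#'
#' @param img numeric matrix.
#' @param tf a [RigidTransform2D].
#' @return transformed image, same dimensions.
#' @export
applyRigidTransform <- function(img, tf) {
  stopifnot(is(tf, "RigidTransform2D"))
  nr <- nrow(img); nc <- ncol(img)
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr), nr, nc)
  # coordinates map forward as q = R(theta)(p - c) + c + t, so the
  # pull-back is source = R(-theta)(q - c - t) + c
  th <- -tf@theta_deg * pi / 180
  dx <- xs - tf@center[1L] - tf@tx_px
  dy <- ys - tf@center[2L] - tf@ty_px
  sx <- cos(th) * dx - sin(th) * dy + tf@center[1L]
  sy <- sin(th) * dx + cos(th) * dy + tf@center[2L]
  matrix(.bilinear(img, as.vector(sx), as.vector(sy)), nr, nc)
}

## separable Gaussian blur with edge renormalization
.gaussBlur <- function(img, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  conv1 <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (j in -r:r) {
      rows <- pmin(pmax(seq_len(nrow(m)) + j, 1L), nrow(m))
      out <- out + k[j + r + 1L] * m[rows, , drop = FALSE]
    }
    out / sum(k)
  }
  t(conv1(t(conv1(img))))
}

## high-pass prefilter: removes smooth intensity confounds (B0-induced
## shading, coil profiles) that would otherwise pull the fit off the
## anatomy; the residual structure drives the metric
.regPrefilter <- function(img, sigma = 6) img - .gaussBlur(img, sigma)

## standardized mean-squared difference between two images, evaluated on
## an interior region so edge-fill pixels cannot bias the fit.  The
## moving image is high-pass filtered once up front: the isotropic
## Gaussian commutes with rigid motion, so filtering before warping is
## equivalent to filtering the warped image.
.regObjective <- function(par, moving_f, fixed_std, center, interior) {
  tf <- new("RigidTransform2D", tx_px = par[1L], ty_px = par[2L],
            theta_deg = par[3L], center = center)
  w <- applyRigidTransform(moving_f, tf)[interior]
  s <- stats::sd(w)
  if (s == 0) return(Inf)
  mean(((w - mean(w)) / s - fixed_std)^2)
}

#' Register one image to a fixed reference
#'
#' Estimates the 3-degree-of-freedom rigid transform that, applied to
#' `moving`, minimizes the mean-squared difference to `fixed` (images are
#' intensity-standardized first, so S0 and saturated frames can share the
#' metric).  Optimization is a coarse grid search over translation and
#' rotation followed by Nelder-Mead refinement, with an additional
#' refinement started from the identity.
#'
#' @param moving,fixed numeric matrices of equal dimensions.
#' @param max_shift_px,max_rot_deg coarse-search bounds.
#' @param margin_px border width excluded from the metric (edge-value
#'   fill would otherwise bias the fit).
#' @return a [RigidTransform2D] with attributes `residual` (standardized
#'   MSE after alignment) and `residual_identity`.
#' @export
registerPair <- function(moving, fixed, max_shift_px = 4, max_rot_deg = 3,
                         margin_px = 5L) {
  stopifnot(identical(dim(moving), dim(fixed)))
  if (stats::sd(moving) == 0 || stats::sd(fixed) == 0)
    stop("cannot register constant images (no gradient information)")
  center <- c((ncol(fixed) + 1) / 2, (nrow(fixed) + 1) / 2)
  interior <- matrix(FALSE, nrow(fixed), ncol(fixed))
  m <- min(margin_px, floor((min(dim(fixed)) - 2L) / 2))
  interior[(1L + m):(nrow(fixed) - m), (1L + m):(ncol(fixed) - m)] <- TRUE
  fx <- .regPrefilter(fixed)[interior]
  if (stats::sd(fx) == 0)
    stop("fixed image has no structure after high-pass filtering")
  fixed_std_i <- (fx - mean(fx)) / stats::sd(fx)
  moving_f <- .regPrefilter(moving)
  obj <- function(par)
    .regObjective(par, moving_f, fixed_std_i, center, interior)

  grid <- expand.grid(tx = seq(-max_shift_px, max_shift_px,
                               length.out = 3L),
                      ty = seq(-max_shift_px, max_shift_px,
                               length.out = 3L),
                      th = seq(-max_rot_deg, max_rot_deg,
                               length.out = 3L))
  vals <- apply(grid, 1L, obj)
  starts <- list(as.numeric(grid[which.min(vals), ]), c(0, 0, 0))
  fits <- lapply(starts, function(s)
    stats::optim(s, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 600)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  out <- new("RigidTransform2D", tx_px = best$par[1L], ty_px = best$par[2L],
             theta_deg = best$par[3L], center = center)
  attr(out, "residual") <- best$value
  attr(out, "residual_identity") <- obj(c(0, 0, 0))
  out
}

.isIdentityPar <- function(tf)
  tf@tx_px == 0 && tf@ty_px == 0 && tf@theta_deg == 0

#' Register every frame of a series to the +3.5 ppm reference
#'
#' The fixed image is the first acquisition at the reference offset
#' (default +3.5 ppm).  Every other frame is aligned to it with
#' [registerPair()].  Frames within `exclude_ppm` of the water resonance
#' are never fitted directly: direct water saturation destroys their
#' anatomical contrast, so they inherit the transform of the
#' nearest-in-offset successfully registered frame; the same fallback
#' applies to frames whose fit fails to improve on the identity residual
#' or lands outside the plausibility bounds.  Estimates below
#' `snap_tol` (pixels / degrees) are snapped to the exact identity so
#' motion-free frames are not needlessly resampled.  The S0 image is
#' registered to the reference as well and resampled with its own
#' estimated transform.
#'
#' @param series a [ZSpectrumSeries].
#' @param reference_ppm reference offset (must be in the offset table).
#' @param register_s0 also align the unsaturated image (default TRUE).
#' @param exclude_ppm frames with `|offset| <= exclude_ppm` are not
#'   fitted directly (default 1).
#' @param max_shift_px,max_rot_deg plausibility bounds on accepted fits.
#' @param snap_tol snap-to-identity threshold.
#' @return list with `series` (resampled [ZSpectrumSeries]) and
#'   `transforms` (list of per-frame [RigidTransform2D], the reference
#'   frame's being the identity).
#' @export
registerSeries <- function(series, reference_ppm = NULL,
                           register_s0 = TRUE, exclude_ppm = 1,
                           max_shift_px = 4, max_rot_deg = 3,
                           snap_tol = 0.15) {
  stopifnot(is(series, "ZSpectrumSeries"))
  if (is.null(reference_ppm))
    reference_ppm <- series@offset_table@reference_ppm
  per_frame <- expandOffsets(series@offset_table)
  ref_idx <- which(abs(per_frame - reference_ppm) < 1e-9)[1L]
  if (is.na(ref_idx))
    stop(sprintf("reference offset %g ppm is not in the offset table",
                 reference_ppm))
  fixed <- series@frames[, , ref_idx]
  nf <- length(per_frame)
  tfs <- vector("list", nf)
  ok <- logical(nf)
  snap <- function(tf) {
    if (abs(tf@tx_px) < snap_tol && abs(tf@ty_px) < snap_tol &&
        abs(tf@theta_deg) < snap_tol)
      rigidTransform2D(dim = dim(fixed)) else tf
  }
  # the reference frame carries its own motion, so a correct frame-to-
  # reference transform can reach twice the per-frame motion bound
  plausible <- function(tf)
    abs(tf@tx_px) <= 2 * max_shift_px + 1 &&
      abs(tf@ty_px) <= 2 * max_shift_px + 1 &&
      abs(tf@theta_deg) <= 2 * max_rot_deg + 1
  for (i in seq_len(nf)) {
    if (i == ref_idx) {
      tfs[[i]] <- rigidTransform2D(dim = dim(fixed))
      ok[i] <- TRUE
      next
    }
    if (abs(per_frame[i]) <= exclude_ppm + 1e-9) next
    tf <- registerPair(series@frames[, , i], fixed,
                       max_shift_px = max_shift_px,
                       max_rot_deg = max_rot_deg)
    improved <- attr(tf, "residual") <
      attr(tf, "residual_identity") - 1e-12
    if ((improved && plausible(tf)) ||
        attr(tf, "residual_identity") < 1e-10) {
      tfs[[i]] <- snap(tf); ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("registration failed for every frame")
  # fallback: nearest-in-offset successful transform
  for (i in which(!ok)) {
    j <- which(ok)[which.min(abs(per_frame[ok] - per_frame[i]))]
    tfs[[i]] <- tfs[[j]]
  }
  frames <- series@frames
  for (i in seq_len(nf))
    if (!.isIdentityPar(tfs[[i]]))
      frames[, , i] <- applyRigidTransform(series@frames[, , i], tfs[[i]])
  s0 <- series@s0
  if (register_s0 && stats::sd(series@s0) > 0) {
    tf0 <- registerPair(series@s0, fixed, max_shift_px = max_shift_px,
                        max_rot_deg = max_rot_deg)
    if (attr(tf0, "residual") < attr(tf0, "residual_identity") - 1e-12 &&
        plausible(tf0) && !.isIdentityPar(snap(tf0)))
      s0 <- applyRigidTransform(series@s0, tf0)
  }
  list(series = zSpectrumSeries(frames, s0, series@offset_table,
                                series@pixel_size_mm),
       transforms = tfs)
}
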