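# Shared fixtures and independent oracles.  Everything here is built in
# code at test time; oracles are deliberately written without reusing the
# package's internal matrix builder or interpolation helpers.

## ---- analytic smooth test image (sum of Gaussian lumps) -------------------

# closed-form image function; warped fixtures are produced by evaluating
# it at analytically transformed coordinates, so known-transform
# fixtures carry no interpolation error
blobFun <- function(seed = 7, n = 64) {
  set.seed(seed)
  p <- cbind(runif(6, 0.28 * n, 0.72 * n), runif(6, 0.28 * n, 0.72 * n),
             runif(6, 3, 6), runif(6, 0.5, 1.5))
  function(x, y) {
    v <- 0
    for (i in seq_len(nrow(p)))
      v <- v + p[i, 4] * exp(-((x - p[i, 1])^2 + (y - p[i, 2])^2) /
                               (2 * p[i, 3]^2))
    v
  }
}

blobImage <- function(f, n = 64) {
  xs <- rep(seq_len(n), each = n)
  ys <- rep(seq_len(n), n)
  matrix(f(xs, ys), n)
}

# image content moved by (tx, ty) and rotated by theta about the image
# center, evaluated in closed form (the pull-back of the forward map
# q = R(theta)(p - c) + c + t)
blobImageMoved <- function(f, tx, ty, theta_deg, n = 64) {
  xs <- rep(seq_len(n), each = n)
  ys <- rep(seq_len(n), n)
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  th <- -theta_deg * pi / 180
  dx <- xs - ctr[1] - tx
  dy <- ys - ctr[2] - ty
  matrix(f(cos(th) * dx - sin(th) * dy + ctr[1],
           sin(th) * dx + cos(th) * dy + ctr[2]), n)
}

## ---- independent Bloch-McConnell oracle -----------------------------------

# Stiff-ODE integration of the coupled Bloch-McConnell equations with a
# hand-written right-hand side assembled directly from the pool
# parameters (no reuse of the package's coefficient-matrix builder).
bmOracleZ <- function(pool_df, field_T, b1_uT, duration_ms, offsets_ppm) {
  hz_per_ppm <- 42.5764 * field_T
  w1 <- 2 * pi * 42.5764 * b1_uT
  n <- nrow(pool_df)
  vapply(offsets_ppm, function(off) {
    dw <- 2 * pi * hz_per_ppm * (pool_df$shift_ppm - off)
    R1 <- 1 / pool_df$T1_s
    R2 <- 1 / pool_df$T2_s
    f <- pool_df$fraction
    k <- pool_df$k_per_s
    rhs <- function(t, y, parms) {
      Mx <- y[seq_len(n)]
      My <- y[n + seq_len(n)]
      Mz <- y[2 * n + seq_len(n)]
      dMx <- -R2 * Mx + dw * My
      dMy <- -dw * Mx - R2 * My + w1 * Mz
      dMz <- -w1 * My - R1 * (Mz - f)
      for (q in seq_len(n)[-1]) {        # exchange with water (pool 1)
        dMx[1] <- dMx[1] - k[q] * f[q] * Mx[1] + k[q] * Mx[q]
        dMx[q] <- dMx[q] + k[q] * f[q] * Mx[1] - k[q] * Mx[q]
        dMy[1] <- dMy[1] - k[q] * f[q] * My[1] + k[q] * My[q]
        dMy[q] <- dMy[q] + k[q] * f[q] * My[1] - k[q] * My[q]
        dMz[1] <- dMz[1] - k[q] * f[q] * Mz[1] + k[q] * Mz[q]
        dMz[q] <- dMz[q] + k[q] * f[q] * Mz[1] - k[q] * Mz[q]
      }
      list(c(dMx, dMy, dMz))
    }
    y0 <- c(rep(0, 2 * n), f)
    out <- deSolve::lsoda(y0, c(0, duration_ms / 1000), rhs, parms = NULL,
                          rtol = 1e-11, atol = 1e-13, maxsteps = 1e6)
    out[nrow(out), 2 * n + 2]            # water Mz (+1 for the time column)
  }, numeric(1))
}

## ---- analytic Lorentzian z-spectrum fixture -------------------------------

# broad single-line z-spectrum with a known center; closed form, so the
# B0 estimator can be checked against an exact oracle
lorentzZ <- function(offsets_ppm, center_ppm = 0, depth = 0.95,
                     gamma_ppm = 0.8) {
  1 - depth * gamma_ppm^2 / (gamma_ppm^2 + (offsets_ppm - center_ppm)^2)
}

## ---- small constructors ---------------------------------------------------

# one-voxel (or few-voxel) z-spectrum stack from explicit values
makeStack <- function(offsets_ppm, values) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  ord <- order(offsets_ppm)
  mask <- matrix(TRUE, nrow(values), 1)
  new("ZSpectrumStack", values = values[, ord, drop = FALSE],
      offsets_ppm = offsets_ppm[ord], mask = mask,
      valid = rep(TRUE, nrow(values)))
}

# quick small phantom spec for unit tests (32x32, no field)
smallPhantomSpec <- function(..., seed = 1L) {
  phantomSpec(shape = c(32L, 32L), lesion_center = c(16, 10),
              lesion_radius_px = 8, b0_amplitude_ppm = 0, seed = seed, ...)
}

# single-tissue phantom: both classes share one pH, so every voxel has
# the same pool set
uniformPhantomSpec <- function(ph = 6.4, ...) {
  phantomSpec(shape = c(16L, 16L), lesion_center = c(8, 8),
              lesion_radius_px = 4, lesion_ph = ph, background_ph = ph,
              b0_amplitude_ppm = 0, texture_amplitude = 0, seed = 1L, ...)
}
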