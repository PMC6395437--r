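test_that("repeat averaging collapses the protocol and reduces noise", {
  # identical frames: mean equals any single frame; all-n=1 is a no-op
  tab <- offsetTable(c(-3.5, 3.5), c(8L, 8L))
  one <- matrix(runif(64), 8, 8)
  frames <- array(rep(one, 16), c(8, 8, 16))
  ser <- zSpectrumSeries(frames, matrix(1, 8, 8), tab)
  avg <- averageRepeats(ser)
  expect_identical(nFrames(avg), 2L)
  expect_equal(avg@frames[, , 1], one, tolerance = 1e-12)

  ph <- buildPhantom(smallPhantomSpec())
  expect_identical(averageRepeats(averageRepeats(ph$series))@frames,
                   averageRepeats(ph$series)@frames)

  # zero-mean noise, 8 repeats: voxel SD shrinks ~ sqrt(8)
  set.seed(5)
  sigma <- 0.05
  noisy <- array(1 + rnorm(64 * 64 * 16, sd = sigma), c(64, 64, 16))
  ser2 <- zSpectrumSeries(noisy, matrix(1, 64, 64),
                          offsetTable(c(-3.5, 3.5), c(8L, 8L)))
  avg2 <- averageRepeats(ser2)
  ratio <- sigma / sd(as.vector(avg2@frames[, , 1]))
  expect_equal(ratio, sqrt(8), tolerance = 0.15)
})

test_that("normalization divides by S0 and respects the mask", {
  tab <- offsetTable(c(-3.5, 3.5), 1L)
  s0 <- matrix(2, 4, 4)
  fr <- array(c(rep(2, 16), rep(1, 16)), c(4, 4, 2))
  mask <- matrix(FALSE, 4, 4); mask[1:2, ] <- TRUE
  st <- normalizeSeries(zSpectrumSeries(fr, s0, tab), mask)
  expect_equal(unname(stackValues(st)[, 1]), rep(1, 8))     # S_sat = S_0
  expect_equal(unname(stackValues(st)[, 2]), rep(0.5, 8))   # S_sat = S_0/2
  expect_identical(nrow(stackValues(st)), 8L)               # masked only

  # nonpositive S0 voxels are flagged invalid, not zeroed
  s0[1, 1] <- 0
  st2 <- normalizeSeries(zSpectrumSeries(fr, s0, tab), mask)
  expect_false(st2@valid[1])
  expect_true(all(is.na(stackValues(st2)[1, ])))

  # repeats must be averaged first
  ph <- buildPhantom(smallPhantomSpec())
  expect_error(normalizeSeries(ph$series), "average repeats")
})

test_that("B0 estimation recovers known displacements of an analytic line", {
  offs <- sort(offsets(defaultOffsetTable()))
  # symmetric noise-free spectrum centered at 0
  st0 <- makeStack(offs, lorentzZ(offs, 0))
  expect_lt(abs(mapValues(estimateB0(st0))[1, 1]), 0.01)
  # displaced by +0.30 and -0.50 ppm (inside the window)
  for (d in c(0.30, -0.50)) {
    st <- makeStack(offs, lorentzZ(offs, d))
    expect_lt(abs(mapValues(estimateB0(st))[1, 1] - d), 0.02)
  }
  # single-pass coarse-grid variant stays within the same tolerance
  st <- makeStack(offs, lorentzZ(offs, 0.30))
  expect_lt(abs(mapValues(estimateB0(st, grid = 0.01,
                                     passes = 1L))[1, 1] - 0.30), 0.02)
})

test_that("B0 estimation validates its window and flags edge minima", {
  offs <- sort(offsets(defaultOffsetTable()))
  st <- makeStack(offs, lorentzZ(offs, 0))
  expect_error(estimateB0(st, window = 7), "beyond the sampled")
  narrow <- makeStack(c(-1, 0, 1), lorentzZ(c(-1, 0, 1), 0))
  expect_error(estimateB0(narrow), "at least 5")
  # monotone spectrum inside the window: no interior minimum -> invalid
  mono <- makeStack(offs, 0.2 + 0.1 * (offs - min(offs)) / diff(range(offs)))
  expect_true(is.na(mapValues(estimateB0(mono))[1, 1]))
})

test_that("B0 correction undoes known shifts and is the identity at 0", {
  offs <- sort(offsets(defaultOffsetTable()))
  st <- makeStack(offs, lorentzZ(offs, 0.30))
  zero_map <- voxelMap(matrix(0, 1, 1), matrix(TRUE, 1, 1), "ppm")
  expect_lt(max(abs(stackValues(correctB0(st, zero_map)) -
                      stackValues(st))), 1e-6)

  b0 <- estimateB0(st)
  corr <- correctB0(st, b0)
  truth <- lorentzZ(offs, 0)
  inner <- abs(offs) < 5.5       # end offsets are clamped
  expect_lt(max(abs(stackValues(corr)[1, inner] - truth[inner])), 1e-3)

  # invalid voxels propagate
  st2 <- makeStack(offs, rbind(lorentzZ(offs, 0.1), lorentzZ(offs, 0.1)))
  bad_map <- voxelMap(matrix(c(0.1, NA), 2, 1), matrix(TRUE, 2, 1), "ppm")
  corr2 <- correctB0(st2, bad_map)
  expect_false(corr2@valid[2])
  expect_true(all(is.na(stackValues(corr2)[2, ])))
})

test_that("MTR asymmetry follows its defining arithmetic", {
  offs <- c(-3.5, 0, 3.5)
  st <- makeStack(offs, matrix(c(650, 1000, 700) / 1000, 1))
  expect_equal(mtrAsym(st, 3.5), -0.05)          # worked example
  expect_equal(mtrAsym(st, 0), 0)                # MTRasym(0) = 0 always
  expect_equal(mtrAsym(st, -3.5), 0.05)          # antisymmetry
  expect_error(mtrAsym(st, 2), "not sampled")    # no silent interpolation

  # symmetric spectrum: zero at every offset
  offs2 <- sort(offsets(defaultOffsetTable()))
  sym <- makeStack(offs2, lorentzZ(offs2, 0))
  for (x in c(1, 2, 3.5)) expect_lt(abs(mtrAsym(sym, x)), 1e-12)
})

test_that("APTW maps match direct simulation on a uniform phantom", {
  spec <- uniformPhantomSpec(ph = 6.4)
  ph <- buildPhantom(spec)
  direct <- simulateMTRasym(setAmideExchangeRate(
    spec@pools, phToExchangeRate(6.4)))
  # map computation itself agrees with the simulation oracle to 1e-4
  stack <- normalizeSeries(averageRepeats(ph$series))
  vals0 <- mapValues(computeAPTWMap(stack))
  expect_lt(max(abs(vals0 - direct)), 1e-4)
  expect_lt(diff(range(vals0)), 1e-8)            # constant map
  # through the full pipeline the B0 stage adds at most its documented
  # estimator error (~0.001 ppm ~ 0.02 pp)
  res <- processSeries(ph$series, register = FALSE)
  expect_lt(max(abs(mapValues(res$aptw) - direct)), 0.03)
})

test_that("mirror-symmetric pools yield a near-zero APTW map", {
  mirror <- poolParameterSet(data.frame(
    name = c("water", "up", "down"),
    shift_ppm = c(0, 3.5, -3.5), fraction = c(1, 0.003, 0.003),
    T1_s = c(1.2, 1, 1), T2_s = c(0.07, 0.02, 0.02),
    k_per_s = c(0, 40, 40)))
  # no amide pool: the pH-to-rate mapping is bypassed and both tissue
  # classes share the symmetric template unchanged
  spec <- phantomSpec(shape = c(16L, 16L), lesion_center = c(8, 5),
                      lesion_radius_px = 4, lesion_ph = 7, background_ph = 7,
                      pools = mirror, b0_amplitude_ppm = 0, seed = 1L)
  ph <- buildPhantom(spec)
  res <- processSeries(ph$series, register = FALSE)
  expect_lt(max(abs(mapValues(res$aptw))), 1e-6)
})

test_that("lesion-mean APTW is unbiased under Rician noise with repeat
           averaging", {
  # sigma 1% of S0 with 8 repeats at +/-3.5 ppm: the lesion-ROI mean
  # over replicate phantoms must not drift from the noise-free value
  spec0 <- smallPhantomSpec()
  truth <- buildPhantom(spec0)$truth_values$lesion$aptw_pct
  lesion <- buildPhantom(spec0)$lesion_mask
  means <- vapply(1:50, function(s) {
    ph <- buildPhantom(smallPhantomSpec(noise = "rician",
                                        noise_sigma = 0.01, seed = s))
    res <- processSeries(ph$series, register = FALSE)
    mean(mapValues(res$aptw)[lesion], na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(means) - truth), 0.2)
})

test_that("ROI MTRasym spectra summarize voxels with standard errors", {
  ph <- buildPhantom(smallPhantomSpec())
  res <- processSeries(ph$series, register = FALSE)
  spec_df <- mtrAsymSpectrum(res$stack, ph$lesion_mask)
  expect_true(all(spec_df$offset_ppm > 0))
  expect_true(all(spec_df$se_pct < 1e-6))        # noise-free uniform ROI
  at35 <- spec_df$mean_pct[abs(spec_df$offset_ppm - 3.5) < 1e-9]
  expect_equal(at35, ph$truth_values$lesion$aptw_pct, tolerance = 0.1)
  expect_error(mtrAsymSpectrum(res$stack, matrix(FALSE, 32, 32)), "empty")
})
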