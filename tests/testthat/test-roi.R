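paintMap <- function(n = 32, base = 0) {
  voxelMap(matrix(base, n, n), matrix(TRUE, n, n), "%")
}

squareROI <- function(rows, cols, n = 32) {
  m <- matrix(FALSE, n, n)
  m[rows, cols] <- TRUE
  m
}

test_that("ROI means are exact on painted maps and flag invalid voxels", {
  map <- paintMap(base = -1.0)
  rois <- list(squareROI(2:11, 2:12), squareROI(14:23, 2:12),
               squareROI(2:11, 16:26))
  expect_equal(roiMeans(map, rois)$mean, rep(-1.0, 3))

  vals <- matrix(0, 32, 32)
  vals[rois[[1]]] <- -2.0; vals[rois[[2]]] <- -1.0; vals[rois[[3]]] <- 0
  map2 <- voxelMap(vals, matrix(TRUE, 32, 32), "%")
  expect_equal(roiMeans(map2, rois)$mean, c(-2.0, -1.0, 0.0))

  # single-voxel ROI returns that voxel
  one <- squareROI(5, 7)
  expect_equal(roiMeans(map2, list(one))$mean, vals[5, 7])

  # > 20% invalid voxels flagged; all-invalid is an error
  mask <- matrix(TRUE, 32, 32); mask[2:11, 2:4] <- FALSE
  map3 <- voxelMap(vals, mask, "%")
  mm <- roiMeans(map3, rois)
  expect_true(mm$flagged[1])
  expect_false(mm$flagged[3])
  empty_mask <- matrix(FALSE, 32, 32)
  expect_error(roiMeans(voxelMap(vals, empty_mask, "%"), rois), "no valid")
  expect_error(roiMeans(map2, list(matrix(FALSE, 32, 32))), "empty")
})

test_that("the lowest-ROI rule picks the minimum with a stable tie-break", {
  expect_identical(lowestROI(c(-2, -1, 0)), list(value = -2, index = 1L))
  expect_identical(lowestROI(c(0, -1, -2)), list(value = -2, index = 3L))
  expect_identical(lowestROI(-1.5), list(value = -1.5, index = 1L))
  expect_identical(lowestROI(c(-1, -1))$index, 1L)     # tie -> lowest index
  expect_error(lowestROI(numeric()), "no ROI")
})

test_that("midline mirroring follows the reflection formula", {
  roi <- squareROI(5:14, 3:13, n = 64)
  mir <- mirrorROI(roi)                      # default midline (64+1)/2
  idx <- which(roi, arr.ind = TRUE)
  expect_true(all(mir[cbind(idx[, 1], 65 - idx[, 2])]))
  expect_identical(sum(mir), sum(roi))
  expect_identical(mirrorROI(mir), roi)      # involution

  # ROI symmetric about the midline maps to itself
  sym <- squareROI(10:20, 30:35, n = 64)
  expect_identical(mirrorROI(sym), sym)

  # out-of-image pixels are dropped with a warning; empty mirror errors
  edge <- squareROI(5:14, 1:11, n = 64)
  expect_warning(m2 <- mirrorROI(edge, midline = 5), "outside")
  expect_lt(sum(m2), sum(edge))
  expect_error(suppressWarnings(mirrorROI(squareROI(5, 1, n = 64),
                                          midline = 0.4)), "empty")
})

test_that("lesion measurement assembles the published ROI rules", {
  vals <- matrix(0.36, 64, 64)               # CNAWM-like background
  lesion_rois <- list(squareROI(20:29, 5:15, n = 64),
                      squareROI(32:41, 5:15, n = 64))
  vals[lesion_rois[[1]]] <- -1.01            # the reported lesion value
  vals[lesion_rois[[2]]] <- -0.50
  whole <- lesion_rois[[1]] | lesion_rois[[2]]
  map <- voxelMap(vals, matrix(TRUE, 64, 64), "%")
  rs <- roiSet(lesion_rois, whole_lesion = whole)

  m <- measureLesion(map, rs)
  expect_equal(m$lesion_aptw_pct, -1.01)
  expect_identical(m$selected_roi_index, 1L)
  expect_equal(m$cnawm_aptw_pct, 0.36)       # mirrored ROI lands on 0.36
  expect_equal(m$contrast_pct, -1.37)        # - (Table-consistent identity)
  expect_identical(m$contrast_pct, m$lesion_aptw_pct - m$cnawm_aptw_pct)
  expect_equal(m$lesion_aptw_mean_pct, mean(c(-1.01, -0.50)))

  # lesion == CNAWM value gives zero contrast
  flat <- voxelMap(matrix(0.2, 64, 64), matrix(TRUE, 64, 64), "%")
  expect_equal(measureLesion(flat, rs)$contrast_pct, 0)

  # an explicit CNAWM ROI takes precedence over mirroring
  cn <- squareROI(20:29, 45:55, n = 64)
  vals2 <- vals; vals2[cn] <- 0.80
  rs2 <- roiSet(lesion_rois, cnawm = cn, whole_lesion = whole)
  m2 <- measureLesion(voxelMap(vals2, matrix(TRUE, 64, 64), "%"), rs2)
  expect_equal(m2$cnawm_aptw_pct, 0.80)
})

test_that("lowest-ROI value never exceeds the whole-lesion mean on a
           spatially varying noise-free map", {
  set.seed(12)
  for (rep in 1:5) {
    grad <- outer(seq(-1, 1, length.out = 64),
                  seq(-0.5, 0.5, length.out = 64), `+`)
    vals <- runif(1, -1.5, -0.5) + runif(1, 0.5, 2) * grad
    lesion <- squareROI(18:43, 6:31, n = 64)
    rois <- autoLesionROIs(lesion)
    map <- voxelMap(vals, matrix(TRUE, 64, 64), "%")
    m <- measureLesion(map, roiSet(rois, whole_lesion = lesion))
    expect_lte(m$lesion_aptw_pct,
               roiMeans(map, list(lesion))$mean + 1e-12)
  }
})

test_that("phantom lesion measurements recover the embedded truth", {
  target <- -1.3
  k <- calibrateAmideExchange(target)
  ph <- buildPhantom(phantomSpec(shape = c(48L, 48L),
                                 lesion_center = c(24, 14),
                                 lesion_radius_px = 10,
                                 lesion_amide_k = k,
                                 b0_amplitude_ppm = 0, seed = 2L))
  res <- processSeries(ph$series, register = FALSE)
  m <- measureLesion(res$aptw, ph$rois)
  expect_lt(abs(m$lesion_aptw_pct - target), 0.1)
  expect_lt(abs(m$lesion_aptw_mean_pct - target), 0.1)
})
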