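test_that("spectrometer calibration recovers the affine map", {
  cal <- noiselessCalibration()
  expect_lt(abs(cal@slope - 16 / 512) / (16 / 512), 1e-3)
  expect_lt(abs(cal@intercept - (-8)), 0.02)
  expect_lt(cal@residualRms, 1e-3)
  expect_setequal(cal@references$liquid, c("water", "acetone", "methanol"))

  ## two references interpolate essentially exactly: with noiseless
  ## symmetric peak pairs the four points are collinear up to the peak
  ## refinement precision
  shifts <- brillouinReferenceShifts()[c("water", "methanol")]
  specs <- lapply(seq_along(shifts), function(i)
    simulateBrillouinSpectrum(shifts[[i]], noiseSd = 0, seed = i))
  names(specs) <- names(shifts)
  cal2 <- calibrateSpectrometer(specs, shifts)
  expect_lt(cal2@residualRms, 1e-4)

  ## identical shifts are degenerate
  same <- list(water = specs[[1L]], fake = specs[[1L]])
  expect_error(calibrateSpectrometer(same, c(water = 5.96, fake = 5.96)),
               "degenerate")
})

test_that("shift fitting recovers truth and flags noise-only spectra", {
  cal <- noiselessCalibration()
  fit <- fitBrillouinShift(simulateBrillouinSpectrum(5.10, noiseSd = 0), cal)
  expect_true(fit$valid)
  expect_lt(abs(fit$nu - 5.10), 1e-3)
  expect_equal(fit$linewidth, 0.3, tolerance = 0.05)
  expect_gt(fit$quality, 0.99)

  set.seed(3)
  noiseOnly <- BrillouinSpectrum(abs(rnorm(512L, 50, 5)))
  bad <- fitBrillouinShift(noiseOnly, cal)
  expect_false(bad$valid)
  expect_true(is.na(bad$nu))
})

test_that("noisy shift recovery is unbiased well below the linewidth", {
  cal <- noiselessCalibration()
  errs <- vapply(1:30, function(seed) {
    s <- simulateBrillouinSpectrum(5.1, noiseSd = 100, seed = seed)
    fitBrillouinShift(s, cal)$nu - 5.1
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.3 / 10)
})

test_that("segmentation recovers phantoms and is idempotent", {
  ph <- uniformPhantom(2, shellRadius = 0.4, coreRadius = 0.28)
  octClean <- simulateOCTVolume(ph, voxelSize = 0.02, snr = Inf)
  m <- segmentOrganoid(octClean)
  expect_identical(m@mask, octClean@truthMask)
  expect_true(all(m@boundary[m@boundary] & m@mask[m@boundary]))

  ## speckled volumes still overlap truth almost perfectly
  dice <- vapply(1:2, function(seed) {
    oct <- simulateOCTVolume(ph, voxelSize = 0.02, snr = 5, seed = seed)
    ms <- segmentOrganoid(oct)
    2 * sum(ms@mask & oct@truthMask) /
      (sum(ms@mask) + sum(oct@truthMask))
  }, numeric(1))
  expect_true(all(dice >= 0.95))

  ## idempotent on its own output mask
  again <- segmentOrganoid(new("OCTVolume", intensity = m@mask + 0,
                               voxelSize = 0.02,
                               truthMask = array(FALSE, dim(m@mask))))
  expect_identical(again@mask, m@mask)
})

test_that("surface-wise shift summaries use the boundary shell", {
  ## constant shifts: mean = c, sd = 0
  ph <- uniformPhantom(2, shellRadius = 0.3, coreRadius = 0.21)
  oct <- simulateOCTVolume(ph, voxelSize = 0.02, snr = Inf)
  m <- segmentOrganoid(oct)
  coords <- which(m@boundary, arr.ind = TRUE)[1:20, ]
  sm <- new("ShiftMap", coords = unname(coords), nu = rep(5.2, 20L),
            linewidth = rep(0.3, 20L), quality = rep(1, 20L))
  s <- surfaceMeanShift(sm, m)
  expect_equal(s$meanShift, 5.2)
  expect_equal(s$sdShift, 0)
  expect_equal(s$n, 20L)

  expect_error(surfaceMeanShift(sm), "mask is required")

  ## stiff shell / softer core: surface mean exceeds whole-mask mean
  ph2 <- OrganoidPhantom(shellRadius = 0.3, coreRadius = 0.21,
                         shiftShell = 5.4, shiftCore = 5.0)
  oct2 <- simulateOCTVolume(ph2, voxelSize = 0.02, snr = Inf)
  m2 <- segmentOrganoid(oct2)
  cal <- noiselessCalibration()
  surfMap <- simulateShiftMap(ph2, m2, cal, where = "boundary",
                              nPoints = 25L, seed = 4L)
  bulkMap <- simulateShiftMap(ph2, m2, cal, where = "mask",
                              nPoints = 25L, seed = 4L)
  expect_gt(surfaceMeanShift(surfMap, m2)$meanShift,
            surfaceMeanShift(bulkMap, m2, where = "mask")$meanShift)
})

test_that("surface mean is invariant to rigid translation of the object", {
  ## build two binary volumes with the same sphere at different positions
  mkVol <- function(cx) {
    d <- c(41L, 41L, 41L)
    ax <- lapply(1:3, function(i) seq_len(d[i]) - 21)
    r2 <- outer(outer((ax[[1]] - cx)^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
    new("OCTVolume", intensity = (r2 <= 8^2) * 1 + 0.0,
        voxelSize = 0.02, truthMask = array(FALSE, d))
  }
  mA <- segmentOrganoid(mkVol(0))
  mB <- segmentOrganoid(mkVol(5))
  expect_equal(sum(mA@boundary), sum(mB@boundary))
  shiftFor <- function(m) {
    coords <- which(m@boundary, arr.ind = TRUE)
    new("ShiftMap", coords = unname(coords),
        nu = rep(5.3, nrow(coords)), linewidth = rep(0.3, nrow(coords)),
        quality = rep(1, nrow(coords)))
  }
  expect_equal(surfaceMeanShift(shiftFor(mA), mA)$meanShift,
               surfaceMeanShift(shiftFor(mB), mB)$meanShift)
})
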