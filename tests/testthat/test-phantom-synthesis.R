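test_that("reverberant simulator is seeded and spectrally ring-concentrated", {
  acq <- fullAcq()
  ph <- uniformPhantom(2)
  sim <- SimSpec(seed = 42L)
  f1 <- simulateReverberantField(ph, acq, sim)
  f2 <- simulateReverberantField(ph, acq, sim)
  expect_identical(f1@vz, f2@vz)

  ## spatial power spectrum of the harmonic snapshot concentrates on the
  ## ring |k| = 2*pi*F/vs, within one spectral bin
  h <- extractHarmonic(f1)
  P <- Mod(fft(h@amp))^2
  dxm <- gridSpacing(acq) * 1e-3
  kx <- 2 * pi * organoidKit:::fftFreqs(101L, dxm[1L])
  kr <- sqrt(outer(kx^2, kx^2, "+"))
  binWidth <- 2 * pi / (acq@scanExtent[1L] * 1e-3)
  bins <- round(as.vector(kr) / binWidth)
  radial <- tapply(as.vector(P), bins, mean)
  peakK <- as.numeric(names(radial)[which.max(radial)]) * binWidth
  kTrue <- 2 * pi * acq@excitationFreq / 2
  expect_lt(abs(peakK - kTrue), binWidth + 1e-9)
})

test_that("a single plane wave travels at the excitation frequency", {
  acq <- smallAcq()
  ph <- uniformPhantom(2)
  f <- simulateReverberantField(ph, acq, SimSpec(nPlaneWaves = 1L, seed = 5L))
  ## temporal FFT at a pixel has a single dominant peak at F
  ts <- f@vz[, 21L, 21L]
  spec <- Mod(fft(ts))[seq_len(50L)]          # positive frequencies
  fAxis <- (seq_len(50L) - 1L) / (acq@nTimepoints * deltaT(acq))
  expect_equal(fAxis[which.max(spec)], acq@excitationFreq)
  expect_gt(max(spec), 20 * median(spec))
})

test_that("phase encoding wraps into (-pi, pi] and round-trips", {
  acq <- smallAcq(n = 11L, nt = 5L)
  wrapLimit <- acq@lambda0 / (4 * acq@nRefractive * deltaT(acq))

  vz0 <- array(0, c(5L, 11L, 11L))
  expect_equal(fieldToPhaseVolume(fieldFromArray(vz0, acq))@dphi, vz0)

  ## the wrap-boundary velocity maps to exactly pi
  vzB <- array(wrapLimit, c(5L, 11L, 11L))
  expect_equal(max(abs(fieldToPhaseVolume(fieldFromArray(vzB, acq))@dphi - pi)),
               0, tolerance = 1e-12)

  set.seed(1)
  vz <- array(runif(5L * 11L * 11L, -0.9, 0.9) * wrapLimit, c(5L, 11L, 11L))
  rt <- phaseToVelocity(fieldToPhaseVolume(fieldFromArray(vz, acq)))
  expect_equal(rt@vz, vz, tolerance = 1e-12)

  ## beyond the wrap limit phases stay in the principal interval
  vzW <- array(2.4 * wrapLimit, c(5L, 11L, 11L))
  dphi <- fieldToPhaseVolume(fieldFromArray(vzW, acq))@dphi
  expect_true(all(dphi > -pi & dphi <= pi))
})

test_that("under-resolved wavelengths are rejected with the region named", {
  acq <- AcquisitionConfig(gridPoints = c(41L, 41L), scanExtent = c(2, 2))
  ph <- OrganoidPhantom(vsShell = 2, vsCore = 0.5, vsBackground = 2)
  ## core wavelength 0.167 mm at 0.05 mm spacing -> 3.3 samples
  expect_error(simulateReverberantField(ph, acq, SimSpec(nPlaneWaves = 10L)),
               "core")
})

test_that("count simulator matches its negative-binomial ground truth", {
  ## no effects, no dispersion, equal libraries: sample means approach the
  ## baseline within 3 standard errors
  design <- organoidDesign(nRep = 40L)          # 200 samples
  mu <- setNames(rep(100, 50L), NULL)
  se <- simulateCounts(design = design, nGenes = 50L, baselineMu = mu,
                       dispersion = 0, libFactor = 1,
                       effects = data.frame(gene = character(),
                                            arm = character(),
                                            log2fc = numeric()),
                       seed = 9L)
  m <- rowMeans(assay(se, "counts"))
  seMean <- sqrt(100 / nrow(design))
  expect_true(all(abs(m - 100) < 3 * seMean))

  ## marginal variance tracks mu + dispersion * mu^2
  se2 <- simulateCounts(design = design, nGenes = 50L, baselineMu = mu,
                        dispersion = 0.1, libFactor = 1,
                        effects = data.frame(gene = character(),
                                             arm = character(),
                                             log2fc = numeric()),
                        seed = 10L)
  v <- apply(assay(se2, "counts"), 1L, var)
  expect_equal(mean(v), 100 + 0.1 * 100^2, tolerance = 0.15)

  ## determinism and ground-truth metadata
  seA <- simulateCounts(nGenes = 100L, seed = 3L)
  seB <- simulateCounts(nGenes = 100L, seed = 3L)
  expect_identical(assay(seA, "counts"), assay(seB, "counts"))
  expect_true(all(c("FOLR1", neuroDevGenes()) %in% rownames(seA)))

  expect_error(
    simulateCounts(nGenes = 50L,
                   effects = data.frame(gene = "NOPE", arm = "DTG10",
                                        log2fc = 2)),
    "NOPE")
})

test_that("OCT simulator stores recoverable ground truth", {
  ph <- uniformPhantom(2, shellRadius = 0.4, coreRadius = 0.28)
  ## noiseless: midpoint threshold recovers the stored mask exactly
  oct <- simulateOCTVolume(ph, voxelSize = 0.02, snr = Inf)
  expect_identical(oct@intensity > 0.55, oct@truthMask)

  ## segmented equivalent diameter within 2 voxels of the true 0.8 mm
  m <- segmentOrganoid(oct)
  morph <- organoidMorphometry(mask = m)
  expect_lt(abs(morph@dMean - 0.8), 2 * 0.02)

  ## background-only volume reports no object
  empty <- segmentOrganoid(simulateOCTVolume(NULL, snr = 5, seed = 2L))
  expect_false(hasObject(empty))

  expect_error(simulateOCTVolume(ph, voxelSize = 0.1), "shell thickness")
})

test_that("Brillouin spectrum simulator is calibration-consistent", {
  s <- simulateBrillouinSpectrum(5.1, noiseSd = 0)
  nu <- (16 / 512) * seq_len(512L) - 8
  peak <- nu[which.max(s@intensity * (nu > 0))]
  expect_lt(abs(peak - 5.1), 16 / 512)         # argmax within one pixel

  s1 <- simulateBrillouinSpectrum(5.0, linewidth = 0.3, noiseSd = 20,
                                  seed = 7L)
  s2 <- simulateBrillouinSpectrum(5.0, linewidth = 0.3, noiseSd = 20,
                                  seed = 7L)
  expect_identical(s1@intensity, s2@intensity)

  expect_error(simulateBrillouinSpectrum(9.5), "range")
})
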