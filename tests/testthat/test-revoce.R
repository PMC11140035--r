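test_that("phase-to-velocity follows the OCT velocity equation", {
  acq <- smallAcq(n = 5L, nt = 3L)
  d <- c(3L, 5L, 5L)
  pv <- function(x) new("PhaseVolume", dphi = array(x, d), acq = acq)

  expect_equal(phaseToVelocity(pv(0))@vz, array(0, d))
  ## dphi = pi with lambda0 = 840 nm, n = 1.34, dt = 40 us
  expect_equal(phaseToVelocity(pv(pi))@vz[1L],
               840e-9 / (4 * 1.34 * 40e-6), tolerance = 1e-12)
  ## linearity
  expect_equal(phaseToVelocity(pv(1.2))@vz, 2 * phaseToVelocity(pv(0.6))@vz,
               tolerance = 1e-12)
})

test_that("temporal unwrapping recovers super-wrap velocities", {
  acq <- smallAcq(n = 3L, nt = 100L)
  wrapLimit <- acq@lambda0 / (4 * acq@nRefractive * deltaT(acq))
  tt <- seq_len(100L)
  vz <- array(rep(1.7 * wrapLimit * sin(2 * pi * tt / 50), 9L),
              c(100L, 3L, 3L))
  p <- fieldToPhaseVolume(fieldFromArray(vz, acq))
  expect_gt(max(abs(phaseToVelocity(p)@vz - vz)), wrapLimit)  # wrapped
  expect_equal(phaseToVelocity(p, unwrap = TRUE)@vz, vz, tolerance = 1e-10)
})

test_that("harmonic extraction recovers tones and rejects bad frequencies", {
  acq <- smallAcq(nt = 100L)
  tt <- (seq_len(100L) - 1L) * deltaT(acq)
  tone <- 2e-3 * cos(2 * pi * 3000 * tt - 0.7)
  vz <- array(rep(tone, 41L * 41L), c(100L, 41L, 41L))
  h <- extractHarmonic(fieldFromArray(vz, acq))
  expect_equal(Mod(h@amp[1L, 1L]), 2e-3, tolerance = 1e-6)

  dc <- array(1e-3, c(100L, 41L, 41L))
  hdc <- extractHarmonic(fieldFromArray(dc, acq))
  expect_lt(max(Mod(hdc@amp)), 1e-15)

  expect_error(extractHarmonic(fieldFromArray(vz, acq), freq = 13000),
               "Nyquist")

  ## white noise: E|amp|^2 = 4 sigma^2 / nt for this amplitude convention
  set.seed(8)
  sigma <- 1e-3
  noise <- array(rnorm(100L * 41L * 41L, sd = sigma), c(100L, 41L, 41L))
  hn <- extractHarmonic(fieldFromArray(noise, acq))
  expect_equal(mean(Mod(hn@amp)^2), 4 * sigma^2 / 100, tolerance = 0.1)
})

test_that("spatial bandpass keeps the band and never adds energy", {
  acq <- smallAcq()
  dxm <- gridSpacing(acq)[1L] * 1e-3
  kBin <- 2 * pi / (41 * dxm)                   # DFT bin spacing, rad/m
  kIn <- 2 * kBin                               # ~10217 rad/m, inside band
  kOut <- 8 * kBin                              # ~40868 rad/m, outside
  wave <- function(k) {
    x <- (seq_len(41L) - 1L) * dxm
    ph <- outer(x, rep(0, 41L), function(xx, yy) k * xx)
    matrix(complex(modulus = 1, argument = ph), 41L, 41L)
  }
  hIn <- harmonicFromMatrix(wave(kIn), acq)
  hOut <- harmonicFromMatrix(wave(kOut), acq)

  filtIn <- spatialBandpass(hIn, 4000, 20000)
  expect_equal(filtIn@amp, hIn@amp, tolerance = 1e-3)

  filtOut <- spatialBandpass(hOut, 4000, 20000)
  expect_lt(sum(Mod(filtOut@amp)^2) / sum(Mod(hOut@amp)^2), 1e-4)

  ## Parseval: masked output energy never exceeds the input energy
  set.seed(2)
  rnd <- matrix(complex(real = rnorm(41^2), imaginary = rnorm(41^2)),
                41L, 41L)
  hr <- harmonicFromMatrix(rnd, acq)
  expect_lte(sum(Mod(spatialBandpass(hr, 4000, 20000)@amp)^2),
             sum(Mod(rnd)^2))

  expect_error(spatialBandpass(hIn, -1, 20000), "band edges")
  expect_warning(spatialBandpass(hIn, 4000, 20000, vsExpected = 0.2),
                 "nominal ring")
})

test_that("the analytic kernel matches independent quadrature", {
  ## oracle: B(a) = E[p_z^2 cos(a n_x)] / E[p_z^2] for directions uniform
  ## on the sphere and uniform transverse polarization. Conditional on
  ## n_x = u, E[p_z^2] = (1 - E[n_z^2 | u]) / 2 = (1 + u^2) / 4, and u is
  ## uniform on [-1, 1]; the normaliser is E[p_z^2] = 1/3
  oracle <- vapply(seq(0, 2 * pi, length.out = 41L), function(a) {
    num <- stats::integrate(function(u) (1 + u^2) / 4 * cos(a * u) / 2,
                            -1, 1, rel.tol = 1e-10)$value
    num / (1 / 3)
  }, numeric(1))
  a <- seq(0, 2 * pi, length.out = 41L)
  expect_equal(reverberantKernel(a), oracle, tolerance = 1e-7)
  ## series branch joins the closed form continuously
  expect_equal(reverberantKernel(9.9e-5), reverberantKernel(1.01e-4),
               tolerance = 1e-6)
})

test_that("wavenumber maps recover homogeneous and layered truth", {
  acq <- fullAcq()
  f <- simulateReverberantField(uniformPhantom(2), acq, SimSpec(seed = 21L))
  km <- estimateWavenumberMap(extractHarmonic(f))
  kTrue <- 2 * pi * 3000 / 2
  expect_lt(abs(median(wavenumbers(km), na.rm = TRUE) - kTrue) / kTrue, 0.05)
  expect_true(all(fitQuality(km) >= 0 & fitQuality(km) <= 1))

  ## layered phantom: higher wavenumber (softer) in the core
  ph2 <- OrganoidPhantom(vsShell = 3, vsCore = 1.5, vsBackground = 3)
  f2 <- simulateReverberantField(ph2, acq, SimSpec(seed = 22L))
  km2 <- estimateWavenumberMap(extractHarmonic(f2))
  cx <- matrix(km2@centersX, nrow(km2@k), ncol(km2@k))
  cy <- matrix(km2@centersY, nrow(km2@k), ncol(km2@k), byrow = TRUE)
  rho <- sqrt(cx^2 + cy^2)
  kCore <- km2@k[rho <= 0.42]
  kShell <- km2@k[rho > 0.42 & rho <= 0.6]
  expect_gt(median(kCore, na.rm = TRUE), median(kShell, na.rm = TRUE))

  expect_error(estimateWavenumberMap(extractHarmonic(f), windowSize = 0.01),
               "3 x 3")
})

test_that("spatial white noise yields almost no valid windows", {
  acq <- fullAcq()
  fracs <- vapply(1:5, function(seed) {
    set.seed(seed)
    amp <- matrix(complex(real = rnorm(101^2), imaginary = rnorm(101^2)),
                  101L, 101L)
    km <- suppressWarnings(
      estimateWavenumberMap(harmonicFromMatrix(amp, acq)))
    mean(!is.na(wavenumbers(km)))
  }, numeric(1))
  expect_lte(mean(fracs), 0.1)
})

test_that("speed conversion is exact and propagates invalids", {
  km <- new("WavenumberMap",
            k = matrix(c(2 * pi * 1e3, NA, 4 * pi * 1e3, 9424.8), 2L),
            r2 = matrix(c(0.9, 0.1, 0.95, 0.99), 2L),
            centersX = c(0, 1), centersY = c(0, 1),
            windowSize = 0.5, freq = 3000)
  sm <- wavenumberToSpeed(km)
  expect_equal(speedValues(sm)[1L, 1L], 3.0, tolerance = 1e-12)
  expect_true(is.na(speedValues(sm)[2L, 1L]))
  ## product invariant and inverse proportionality
  valid <- !is.na(km@k)
  expect_equal(speedValues(sm)[valid] * km@k[valid],
               rep(2 * pi * 3000, sum(valid)), tolerance = 1e-12)
  km2 <- km; km2@k <- km@k * 2
  expect_equal(speedValues(wavenumberToSpeed(km2))[valid],
               speedValues(sm)[valid] / 2, tolerance = 1e-12)
})

test_that("region summaries split surface from core sensibly", {
  vs <- matrix(2.5, 7L, 7L)
  sm <- new("SpeedMap", vs = vs, r2 = matrix(1, 7L, 7L),
            centersX = seq(-0.6, 0.6, length.out = 7L),
            centersY = seq(-0.6, 0.6, length.out = 7L), freq = 3000)
  mask <- matrix(TRUE, 7L, 7L)
  reg <- regionSpeedSummary(sm, mask)
  expect_equal(reg$mean, c(2.5, 2.5))
  expect_equal(reg$region, c("surface", "core"))
  expect_equal(sum(reg$nTotal), 49L)

  expect_error(regionSpeedSummary(sm, matrix(FALSE, 7L, 7L)), "empty")
  expect_error(regionSpeedSummary(sm), "mask or a phantom")
})

test_that("spherical volumetry is exact and scales cubically", {
  m <- organoidMorphometry(1.0, 1.0)
  expect_equal(organoidVolumeMm3(m), 4 / 3 * pi * 0.5^3, tolerance = 1e-15)
  expect_equal(round(organoidVolumeMm3(m), 4), 0.5236)

  ## averaging: (0.8 + 1.2)/2 gives the same volume as (1, 1)
  expect_equal(organoidVolumeMm3(organoidMorphometry(0.8, 1.2)),
               organoidVolumeMm3(m), tolerance = 1e-15)

  for (d in c(0.3, 0.77, 1.9)) {
    expect_equal(organoidVolumeMm3(organoidMorphometry(2 * d, 2 * d)),
                 8 * organoidVolumeMm3(organoidMorphometry(d, d)),
                 tolerance = 1e-12)
  }
  expect_error(organoidMorphometry(-1, 1), "positive")
})
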