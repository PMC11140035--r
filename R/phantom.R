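## Synthetic reverberant shear-wave fields over spherical organoid phantoms.
##
## The field is a superposition of shear plane waves with directions drawn
## uniformly on the sphere and random transverse polarizations; only the
## axial (z) polarization component is observed, matching what a
## phase-sensitive OCT system measures. All waves share the excitation
## frequency, so the space/time dependence factorises into a complex
## spatial amplitude times exp(-i*2*pi*F*t). Heterogeneity is realised by
## synthesising one amplitude field per phantom compartment with the local
## wavenumber k = 2*pi*F / vs and blending them over a 2-pixel transition
## band: the wavenumber estimator is local and windowed, so local-k
## synthesis is the standard test harness for reverberant estimators.

## scan-centred lateral grid coordinates (mm)
gridCoords <- function(acq) {
  sp <- gridSpacing(acq)
  list(x = (seq_len(acq@gridPoints[1L]) - 1L) * sp[1L] -
         acq@scanExtent[1L] / 2,
       y = (seq_len(acq@gridPoints[2L]) - 1L) * sp[2L] -
         acq@scanExtent[2L] / 2)
}

## smooth radial membership: 1 inside radius R, 0 outside, cosine ramp of
## total width 2*halfWidth centred on R
smoothInside <- function(rho, R, halfWidth) {
  t <- pmin(pmax((rho - (R - halfWidth)) / (2 * halfWidth), 0), 1)
  0.5 * (1 + cos(pi * t))
}

## per-region smooth weights on the scan plane through the phantom equator
regionWeights <- function(phantom, acq) {
  g <- gridCoords(acq)
  rho <- sqrt(outer((g$x - phantom@center[1L])^2,
                    (g$y - phantom@center[2L])^2, "+"))
  hw <- max(gridSpacing(acq))           # 2-pixel transition band
  wOrg <- smoothInside(rho, phantom@shellRadius, hw)
  wCore <- smoothInside(rho, phantom@coreRadius, hw)
  list(core = wCore, shell = wOrg - wCore, background = 1 - wOrg)
}

regionSpeedsOf <- function(phantom) {
  c(core = phantom@vsCore, shell = phantom@vsShell,
    background = phantom@vsBackground)
}

#' Simulate a reverberant shear-wave field over an organoid phantom
#'
#' Synthesises the axial particle-velocity field `vz(t, x, y)` produced by
#' a diffuse (reverberant) superposition of shear plane waves inside and
#' around a two-compartment spherical phantom, observed on the lateral
#' scan plane through the phantom equator. Each compartment carries the
#' local wavenumber `k = 2*pi*F / vs`; compartment fields are blended over
#' a 2-pixel transition band. The field is scaled to the requested RMS
#' amplitude, and Gaussian velocity noise is added per time sample.
#'
#' A region whose shear wavelength is sampled by fewer than 4 grid points
#' cannot be represented on the grid and is rejected with a diagnostic.
#'
#' @param phantom an [OrganoidPhantom-class].
#' @param acq an [AcquisitionConfig-class].
#' @param sim a [SimSpec-class]; identical specs give identical fields.
#' @return a [VelocityField-class].
#' @examples
#' acq <- AcquisitionConfig(gridPoints = c(41L, 41L), nTimepoints = 100L)
#' ph <- OrganoidPhantom(vsShell = 2, vsCore = 2, vsBackground = 2)
#' vf <- simulateReverberantField(ph, acq, SimSpec(nPlaneWaves = 200L))
#' @export
simulateReverberantField <- function(phantom, acq = AcquisitionConfig(),
                                     sim = SimSpec()) {
  stopifnot(is(phantom, "OrganoidPhantom"), is(acq, "AcquisitionConfig"),
            is(sim, "SimSpec"))
  validObject(phantom); validObject(acq); validObject(sim)

  vs <- regionSpeedsOf(phantom)
  lambdaMm <- vs / acq@excitationFreq * 1e3     # shear wavelength, mm
  samplesPerWavelength <- lambdaMm / max(gridSpacing(acq))
  bad <- names(vs)[samplesPerWavelength < 4]
  if (length(bad))
    stop("shear wavelength under-resolved on the grid in region(s): ",
         paste(bad, collapse = ", "),
         sprintf(" (< 4 samples per wavelength at F = %g Hz)",
                 acq@excitationFreq))

  set.seed(sim@seed)
  Q <- sim@nPlaneWaves
  ## directions uniform on the sphere
  n <- matrix(rnorm(3L * Q), nrow = 3L)
  n <- sweep(n, 2L, sqrt(colSums(n^2)), "/")
  ## random transverse (shear) polarization; only its z component couples
  ## to the measured axial velocity
  aux <- matrix(rnorm(3L * Q), nrow = 3L)
  e1 <- aux - sweep(n, 2L, colSums(aux * n), "*")
  e1 <- sweep(e1, 2L, sqrt(colSums(e1^2)), "/")
  e2 <- rbind(n[2L, ] * e1[3L, ] - n[3L, ] * e1[2L, ],
              n[3L, ] * e1[1L, ] - n[1L, ] * e1[3L, ],
              n[1L, ] * e1[2L, ] - n[2L, ] * e1[1L, ])
  psi <- runif(Q, 0, 2 * pi)
  pz <- cos(psi) * e1[3L, ] + sin(psi) * e2[3L, ]
  amp <- switch(sim@amplitudeModel,
                constant = rep(1, Q),
                rayleigh = sqrt(rexp(Q, rate = 1)))
  w <- amp * pz * exp(1i * runif(Q, 0, 2 * pi))

  ## pixel positions (m) relative to the phantom centre, z on the equator
  g <- gridCoords(acq)
  nx <- acq@gridPoints[1L]; ny <- acq@gridPoints[2L]
  px <- rep(g$x - phantom@center[1L], times = ny) * 1e-3
  py <- rep(g$y - phantom@center[2L], each = nx) * 1e-3
  ## directional phase n . r, reused across compartments (z term = 0 on
  ## the equatorial plane)
  proj <- outer(px, n[1L, ]) + outer(py, n[2L, ])   # npix x Q

  kOf <- 2 * pi * acq@excitationFreq / vs
  homogeneous <- (max(vs) - min(vs)) < 1e-12
  regionField <- function(k) {
    U <- complex(length.out = length(px))
    chunk <- 200L
    for (j0 in seq(1L, Q, by = chunk)) {
      jj <- j0:min(j0 + chunk - 1L, Q)
      U <- U + exp(1i * k * proj[, jj, drop = FALSE]) %*% w[jj]
    }
    as.vector(U)
  }

  if (homogeneous) {
    U <- regionField(kOf[["background"]])
  } else {
    wts <- regionWeights(phantom, acq)
    U <- complex(length.out = length(px))
    for (reg in names(kOf)) {
      if (any(wts[[reg]] > 0))
        U <- U + as.vector(wts[[reg]]) * regionField(kOf[[reg]])
    }
  }

  U <- U * sim@fieldRms / sqrt(mean(Mod(U)^2) / 2)

  tt <- (seq_len(acq@nTimepoints) - 1L) * deltaT(acq)
  omega <- 2 * pi * acq@excitationFreq
  vz <- outer(cos(omega * tt), Re(U)) + outer(sin(omega * tt), Im(U))
  if (sim@noiseSd > 0)
    vz <- vz + rnorm(length(vz), sd = sim@noiseSd)
  dim(vz) <- c(acq@nTimepoints, nx, ny)
  new("VelocityField", vz = vz, acq = acq)
}

#' Encode a velocity field as wrapped phase differences
#'
#' Inverse of the phase-sensitive OCT velocity readout: the phase shift
#' between sequential A-lines is `dphi = 4*pi*n*dt*vz / lambda0`, wrapped
#' into `(-pi, pi]`. Round-trips exactly with [phaseToVelocity()] whenever
#' no wrapping occurs, i.e. for `|vz| < lambda0 / (4*n*dt)`.
#'
#' @param v a [VelocityField-class].
#' @return a [PhaseVolume-class].
#' @examples
#' wrapLimit <- 840e-9 / (4 * 1.34 * 40e-6)   # ~3.918e-3 m/s
#' @export
fieldToPhaseVolume <- function(v) {
  stopifnot(is(v, "VelocityField"))
  acq <- v@acq
  raw <- 4 * pi * acq@nRefractive * deltaT(acq) * v@vz / acq@lambda0
  wrapped <- raw - 2 * pi * ceiling((raw - pi) / (2 * pi))
  new("PhaseVolume", dphi = wrapped, acq = acq)
}
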