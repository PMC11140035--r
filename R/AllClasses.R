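#' @import methods
#' @importFrom stats median sd var mad optimize fft rnorm runif rnbinom
#'   rpois rlnorm rexp rgamma pf pt binom.test setNames lm coef resid
#' @importFrom utils write.csv read.csv write.table combn
NULL

## ---------------------------------------------------------------------------
## Acquisition / simulation configuration
## ---------------------------------------------------------------------------

#' Phase-sensitive OCT acquisition configuration
#'
#' Geometry and timing of an M-C mode Rev-OCE acquisition: repeated A-lines
#' (M-mode) at every point of a lateral C-scan grid. Defaults follow a
#' typical spectral-domain system running at a 25 kHz A-line rate with a
#' 3 kHz quasi-harmonic mechanical excitation, a 101 x 101 lateral grid over
#' 2 x 2 mm and 0.5 x 0.5 mm analysis windows.
#'
#' @slot lambda0 centre wavelength of the source (m).
#' @slot nRefractive refractive index of the sample (dimensionless; 1.34
#'   for brain tissue).
#' @slot alineRate A-line acquisition rate (Hz). The inter-A-line interval
#'   is `1 / alineRate` (40 us at 25 kHz).
#' @slot excitationFreq mechanical excitation frequency F (Hz).
#' @slot nTimepoints number of sequential A-lines per lateral position.
#' @slot gridPoints integer vector `(nx, ny)` of lateral grid points.
#' @slot scanExtent numeric vector `(ex, ey)` lateral scan extent (mm).
#' @slot windowSize side length of the square analysis window (mm).
#'
#' @export
setClass("AcquisitionConfig",
  slots = c(
    lambda0        = "numeric",
    nRefractive    = "numeric",
    alineRate      = "numeric",
    excitationFreq = "numeric",
    nTimepoints    = "integer",
    gridPoints     = "integer",
    scanExtent     = "numeric",
    windowSize     = "numeric"
  )
)

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  if (length(object@lambda0) != 1L || object@lambda0 <= 0)
    msg <- c(msg, "'lambda0' must be a single positive wavelength in metres")
  if (length(object@nRefractive) != 1L || object@nRefractive < 1)
    msg <- c(msg, "'nRefractive' must be a single value >= 1")
  if (length(object@alineRate) != 1L || object@alineRate <= 0)
    msg <- c(msg, "'alineRate' must be positive")
  if (length(object@excitationFreq) != 1L || object@excitationFreq <= 0)
    msg <- c(msg, "'excitationFreq' must be positive")
  if (object@excitationFreq >= object@alineRate / 2)
    msg <- c(msg, sprintf(
      "excitation frequency %g Hz violates Nyquist for A-line rate %g Hz",
      object@excitationFreq, object@alineRate))
  if (length(object@nTimepoints) != 1L || object@nTimepoints < 2L)
    msg <- c(msg, "'nTimepoints' must be an integer >= 2")
  if (length(object@gridPoints) != 2L || any(object@gridPoints < 2L))
    msg <- c(msg, "'gridPoints' must be two integers >= 2")
  if (length(object@scanExtent) != 2L || any(object@scanExtent <= 0))
    msg <- c(msg, "'scanExtent' must be two positive lengths in mm")
  if (length(object@windowSize) != 1L || object@windowSize <= 0)
    msg <- c(msg, "'windowSize' must be a single positive length in mm")
  else if (object@windowSize > min(object@scanExtent))
    msg <- c(msg, "'windowSize' cannot exceed the smallest scan extent")
  if (length(msg)) msg else TRUE
})

#' @rdname AcquisitionConfig-class
#' @param lambda0,nRefractive,alineRate,excitationFreq,nTimepoints,gridPoints,scanExtent,windowSize
#'   see the corresponding slots.
#' @return `AcquisitionConfig()` returns a validated configuration object.
#' @examples
#' acq <- AcquisitionConfig()
#' deltaT(acq)          # 4e-05 s at a 25 kHz A-line rate
#' gridSpacing(acq)     # mm between lateral grid points
#' @export
AcquisitionConfig <- function(lambda0 = 840e-9, nRefractive = 1.34,
                              alineRate = 25000, excitationFreq = 3000,
                              nTimepoints = 500L, gridPoints = c(101L, 101L),
                              scanExtent = c(2, 2), windowSize = 0.5) {
  new("AcquisitionConfig",
      lambda0 = lambda0, nRefractive = nRefractive, alineRate = alineRate,
      excitationFreq = excitationFreq,
      nTimepoints = as.integer(nTimepoints),
      gridPoints = as.integer(gridPoints),
      scanExtent = as.numeric(scanExtent), windowSize = windowSize)
}

## ---------------------------------------------------------------------------
## Phantom and simulation spec
## ---------------------------------------------------------------------------

#' Two-compartment spherical organoid phantom
#'
#' Ground-truth geometry and mechanics for simulation: a spherical shell
#' (stiffer surface) around a softer core, embedded in agarose. Shear-wave
#' speeds parameterise the Rev-OCE field; Brillouin shifts parameterise the
#' spectral simulator. All lengths in mm, speeds in m/s, shifts in GHz.
#'
#' @slot center phantom centre `(x, y, z)` (mm) in scan coordinates whose
#'   origin is the centre of the lateral scan.
#' @slot shellRadius outer radius of the organoid (mm).
#' @slot coreRadius radius of the inner core (mm), strictly less than
#'   `shellRadius`.
#' @slot vsShell,vsCore,vsBackground shear-wave speed (m/s) in shell, core
#'   and embedding medium.
#' @slot shiftShell,shiftCore Brillouin frequency shift (GHz) of shell and
#'   core material.
#' @export
setClass("OrganoidPhantom",
  slots = c(
    center       = "numeric",
    shellRadius  = "numeric",
    coreRadius   = "numeric",
    vsShell      = "numeric",
    vsCore       = "numeric",
    vsBackground = "numeric",
    shiftShell   = "numeric",
    shiftCore    = "numeric"
  )
)

setValidity("OrganoidPhantom", function(object) {
  msg <- character()
  if (length(object@center) != 3L)
    msg <- c(msg, "'center' must be (x, y, z) in mm")
  if (object@shellRadius <= 0 || object@coreRadius <= 0)
    msg <- c(msg, "radii must be positive")
  if (object@coreRadius >= object@shellRadius)
    msg <- c(msg, "'coreRadius' must be strictly inside 'shellRadius'")
  if (any(c(object@vsShell, object@vsCore, object@vsBackground) <= 0))
    msg <- c(msg, "all shear speeds must be positive")
  if (any(c(object@shiftShell, object@shiftCore) <= 0))
    msg <- c(msg, "Brillouin shifts must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname OrganoidPhantom-class
#' @param center,shellRadius,coreRadius,vsShell,vsCore,vsBackground,shiftShell,shiftCore
#'   see the corresponding slots.
#' @return `OrganoidPhantom()` returns a validated phantom.
#' @examples
#' ph <- OrganoidPhantom(vsShell = 3, vsCore = 1.5)
#' @export
OrganoidPhantom <- function(center = c(0, 0, 0), shellRadius = 0.6,
                            coreRadius = 0.42, vsShell = 3, vsCore = 1.5,
                            vsBackground = 3, shiftShell = 5.4,
                            shiftCore = 5.1) {
  new("OrganoidPhantom", center = as.numeric(center),
      shellRadius = shellRadius, coreRadius = coreRadius,
      vsShell = vsShell, vsCore = vsCore, vsBackground = vsBackground,
      shiftShell = shiftShell, shiftCore = shiftCore)
}

#' Reverberant-field simulation specification
#'
#' Controls the plane-wave superposition used to synthesise a diffuse shear
#' field: number of plane waves, seeded randomness, the target RMS axial
#' particle velocity, additive measurement noise and the per-wave amplitude
#' model.
#'
#' @slot nPlaneWaves number of superposed shear plane waves.
#' @slot seed integer RNG seed; identical specs give bit-identical fields.
#' @slot fieldRms target root-mean-square axial particle velocity (m/s).
#' @slot noiseSd standard deviation of additive Gaussian velocity noise
#'   (m/s) applied per time sample.
#' @slot amplitudeModel `"constant"` (equal wave amplitudes, random phases)
#'   or `"rayleigh"` (Rayleigh-distributed amplitudes).
#' @export
setClass("SimSpec",
  slots = c(
    nPlaneWaves    = "integer",
    seed           = "integer",
    fieldRms       = "numeric",
    noiseSd        = "numeric",
    amplitudeModel = "character"
  )
)

setValidity("SimSpec", function(object) {
  msg <- character()
  if (object@nPlaneWaves < 1L)
    msg <- c(msg, "'nPlaneWaves' must be >= 1")
  if (object@fieldRms <= 0)
    msg <- c(msg, "'fieldRms' must be positive")
  if (object@noiseSd < 0)
    msg <- c(msg, "'noiseSd' must be >= 0")
  if (!object@amplitudeModel %in% c("constant", "rayleigh"))
    msg <- c(msg, "'amplitudeModel' must be 'constant' or 'rayleigh'")
  if (length(msg)) msg else TRUE
})

#' @rdname SimSpec-class
#' @param nPlaneWaves,seed,fieldRms,noiseSd,amplitudeModel see slots.
#' @return `SimSpec()` returns a validated simulation spec.
#' @export
SimSpec <- function(nPlaneWaves = 1000L, seed = 1L, fieldRms = 5e-4,
                    noiseSd = 0, amplitudeModel = "constant") {
  new("SimSpec", nPlaneWaves = as.integer(nPlaneWaves),
      seed = as.integer(seed), fieldRms = fieldRms, noiseSd = noiseSd,
      amplitudeModel = amplitudeModel)
}

## ---------------------------------------------------------------------------
## Field-level containers
## ---------------------------------------------------------------------------

#' Axial particle-velocity field
#'
#' `vz(t, x, y)` in m/s on the scan grid, sampled at the A-line interval.
#'
#' @slot vz numeric array `(t, x, y)`.
#' @slot acq the [AcquisitionConfig-class] the field was sampled under.
#' @export
setClass("VelocityField",
  slots = c(vz = "array", acq = "AcquisitionConfig"))

setValidity("VelocityField", function(object) {
  d <- dim(object@vz)
  if (length(d) != 3L)
    return("'vz' must be a (t, x, y) array")
  if (d[1L] != object@acq@nTimepoints)
    return("time dimension does not match acq@nTimepoints")
  if (!all(d[2:3] == object@acq@gridPoints))
    return("lateral dimensions do not match acq@gridPoints")
  if (!all(is.finite(object@vz)))
    return("'vz' must be finite")
  TRUE
})

#' Wrapped phase-difference volume
#'
#' Phase shift between sequential A-lines at each lateral position,
#' wrapped into (-pi, pi].
#'
#' @slot dphi numeric array `(t, x, y)` of phase differences (radians).
#' @slot acq the [AcquisitionConfig-class].
#' @export
setClass("PhaseVolume",
  slots = c(dphi = "array", acq = "AcquisitionConfig"))

setValidity("PhaseVolume", function(object) {
  d <- dim(object@dphi)
  if (length(d) != 3L)
    return("'dphi' must be a (t, x, y) array")
  if (d[1L] != object@acq@nTimepoints)
    return("time dimension does not match acq@nTimepoints")
  if (!all(is.finite(object@dphi)))
    return("'dphi' must be finite")
  if (any(object@dphi > pi + 1e-12) || any(object@dphi <= -pi - 1e-12))
    return("'dphi' must be wrapped into (-pi, pi]")
  TRUE
})

#' Complex temporal-harmonic field
#'
#' Per-pixel complex amplitude of the axial velocity at the excitation
#' frequency, obtained by temporal demodulation of a [VelocityField-class].
#'
#' @slot amp complex matrix `(x, y)`; `vz(t) = Re(amp * exp(-2i*pi*F*t))`.
#' @slot freq demodulation frequency F (Hz).
#' @slot acq the [AcquisitionConfig-class] (carries the grid geometry).
#' @export
setClass("HarmonicField",
  slots = c(amp = "matrix", freq = "numeric", acq = "AcquisitionConfig"))

setValidity("HarmonicField", function(object) {
  if (!is.complex(object@amp))
    return("'amp' must be a complex matrix")
  if (!all(is.finite(Mod(object@amp))))
    return("'amp' must be finite")
  if (length(object@freq) != 1L || object@freq <= 0)
    return("'freq' must be a single positive frequency (Hz)")
  TRUE
})

#' Local wavenumber map
#'
#' Local wavenumber `k` (rad/m) and fit quality per sliding analysis
#' window. Windows whose autocorrelation fit falls below the R-squared
#' threshold are marked invalid (`NA`).
#'
#' @slot k numeric matrix of wavenumbers over window centres (rad/m),
#'   `NA` where invalid.
#' @slot r2 fit R-squared per window, in `[0, 1]`.
#' @slot centersX,centersY window-centre coordinates (mm, scan-centred).
#' @slot windowSize analysis window side (mm).
#' @slot freq excitation frequency (Hz) carried for speed conversion.
#' @export
setClass("WavenumberMap",
  slots = c(k = "matrix", r2 = "matrix", centersX = "numeric",
            centersY = "numeric", windowSize = "numeric", freq = "numeric"))

setValidity("WavenumberMap", function(object) {
  if (!all(dim(object@k) == dim(object@r2)))
    return("'k' and 'r2' must have identical dimensions")
  if (nrow(object@k) != length(object@centersX) ||
      ncol(object@k) != length(object@centersY))
    return("centre coordinates do not match map dimensions")
  if (any(object@k[!is.na(object@k)] <= 0))
    return("valid wavenumbers must be positive")
  TRUE
})

#' Shear-wave speed map
#'
#' Pointwise `vs = 2*pi*F / k` over valid analysis windows.
#'
#' @slot vs shear-wave speed (m/s) per window centre, `NA` where invalid.
#' @slot r2 fit quality inherited from the wavenumber map.
#' @slot centersX,centersY window-centre coordinates (mm).
#' @slot freq excitation frequency F (Hz).
#' @export
setClass("SpeedMap",
  slots = c(vs = "matrix", r2 = "matrix", centersX = "numeric",
            centersY = "numeric", freq = "numeric"))

#' Spherical morphometry record
#'
#' Organoid size summary under the sphericity assumption: the mean of the
#' horizontal and vertical diameters gives the radius, and the volume is
#' `(4/3) * pi * r^3`.
#'
#' @slot dHorizontal,dVertical measured diameters (mm).
#' @slot dMean mean diameter (mm).
#' @slot r radius `dMean / 2` (mm).
#' @slot volume spherical volume (mm^3).
#' @export
setClass("Morphometry",
  slots = c(dHorizontal = "numeric", dVertical = "numeric",
            dMean = "numeric", r = "numeric", volume = "numeric"))

setValidity("Morphometry", function(object) {
  msg <- character()
  if (object@dHorizontal <= 0 || object@dVertical <= 0)
    msg <- c(msg, "diameters must be positive")
  if (abs(object@dMean - (object@dHorizontal + object@dVertical) / 2) > 1e-12)
    msg <- c(msg, "'dMean' must equal the average of the two diameters")
  if (abs(object@volume - 4 / 3 * pi * object@r^3) >
      1e-12 * max(1, object@volume))
    msg <- c(msg, "'volume' must equal (4/3)*pi*r^3")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Brillouin / OCT containers
## ---------------------------------------------------------------------------

#' Brillouin spectrometer trace
#'
#' Intensity versus spectrometer pixel for a single acquisition.
#'
#' @slot intensity non-negative counts per pixel (length >= 32).
#' @slot exposureTime camera acquisition time (s).
#' @export
setClass("BrillouinSpectrum",
  slots = c(intensity = "numeric", exposureTime = "numeric"))

setValidity("BrillouinSpectrum", function(object) {
  if (length(object@intensity) < 32L)
    return("spectra must have at least 32 pixels")
  if (any(object@intensity < 0))
    return("'intensity' must be non-negative")
  if (object@exposureTime <= 0)
    return("'exposureTime' must be positive")
  TRUE
})

#' @rdname BrillouinSpectrum-class
#' @param intensity,exposureTime see slots.
#' @return `BrillouinSpectrum()` returns a validated spectrum.
#' @export
BrillouinSpectrum <- function(intensity, exposureTime = 0.2) {
  new("BrillouinSpectrum", intensity = as.numeric(intensity),
      exposureTime = exposureTime)
}

#' Spectrometer pixel-to-GHz calibration
#'
#' Affine map `GHz = slope * pixel + intercept` fitted to the Stokes /
#' anti-Stokes peak positions of reference liquids with known shifts.
#'
#' @slot slope GHz per pixel (non-zero).
#' @slot intercept GHz at pixel 0.
#' @slot residualRms RMS calibration residual (GHz).
#' @slot references data.frame (liquid, shift, peak pixel positions used).
#' @export
setClass("CalibrationModel",
  slots = c(slope = "numeric", intercept = "numeric",
            residualRms = "numeric", references = "data.frame"))

setValidity("CalibrationModel", function(object) {
  if (length(object@slope) != 1L || object@slope == 0)
    return("'slope' must be a single non-zero value")
  if (!is.finite(object@residualRms) || object@residualRms < 0)
    return("'residualRms' must be reported and non-negative")
  TRUE
})

#' Sampled Brillouin shift map
#'
#' Fitted frequency shifts at sampled OCT-grid points.
#'
#' @slot coords integer matrix (n x 3) of voxel indices on the OCT grid.
#' @slot nu fitted Brillouin shift per point (GHz), `NA` where the fit
#'   failed.
#' @slot linewidth fitted FWHM linewidth (GHz).
#' @slot quality fit R-squared per point.
#' @export
setClass("ShiftMap",
  slots = c(coords = "matrix", nu = "numeric", linewidth = "numeric",
            quality = "numeric"))

setValidity("ShiftMap", function(object) {
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3L)
    return("'coords' must be an n x 3 voxel-index matrix")
  if (length(object@nu) != n || length(object@linewidth) != n ||
      length(object@quality) != n)
    return("per-point vectors must match the number of coordinates")
  TRUE
})

#' OCT structural intensity volume
#'
#' @slot intensity 3D intensity array (x, y, z).
#' @slot voxelSize isotropic voxel size (mm).
#' @slot truthMask logical array of ground-truth object voxels (simulated
#'   volumes only; otherwise an empty array).
#' @export
setClass("OCTVolume",
  slots = c(intensity = "array", voxelSize = "numeric", truthMask = "array"))

setValidity("OCTVolume", function(object) {
  if (length(dim(object@intensity)) != 3L)
    return("'intensity' must be a 3D array")
  if (object@voxelSize <= 0)
    return("'voxelSize' must be positive")
  TRUE
})

#' Binary segmentation mask with boundary shell
#'
#' @slot mask logical 3D array of object voxels.
#' @slot boundary logical 3D array, the morphological boundary shell of
#'   `mask` (a subset of `mask`).
#' @slot voxelSize voxel size (mm).
#' @export
setClass("SegmentationMask",
  slots = c(mask = "array", boundary = "array", voxelSize = "numeric"))

setValidity("SegmentationMask", function(object) {
  if (!is.logical(object@mask) || !is.logical(object@boundary))
    return("'mask' and 'boundary' must be logical arrays")
  if (!all(dim(object@mask) == dim(object@boundary)))
    return("'mask' and 'boundary' must have identical dimensions")
  if (any(object@boundary & !object@mask))
    return("'boundary' must be a subset of 'mask'")
  TRUE
})
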