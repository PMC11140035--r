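## Shared fixtures: everything is generated in code, scaled down from the
## full acquisition geometry where a test does not need it.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

## default-geometry acquisition (101 x 101, 500 timepoints)
fullAcq <- function() AcquisitionConfig()

## reduced acquisition for fast tests; keeps the 25 kHz / 3 kHz timing
smallAcq <- function(n = 41L, extent = 1.2, nt = 100L) {
  AcquisitionConfig(gridPoints = c(n, n), scanExtent = c(extent, extent),
                    nTimepoints = nt, windowSize = 0.5)
}

uniformPhantom <- function(vs, shellRadius = 0.6, coreRadius = 0.42) {
  OrganoidPhantom(vsShell = vs, vsCore = vs, vsBackground = vs,
                  shellRadius = shellRadius, coreRadius = coreRadius)
}

## velocity field holding an arbitrary array (for operator-level tests)
fieldFromArray <- function(vz, acq) new("VelocityField", vz = vz, acq = acq)

harmonicFromMatrix <- function(amp, acq, freq = acq@excitationFreq)
  new("HarmonicField", amp = amp, freq = freq, acq = acq)

## noiseless calibrated spectrometer shared by Brillouin tests
noiselessCalibration <- function() {
  shifts <- brillouinReferenceShifts()
  specs <- lapply(seq_along(shifts), function(i)
    simulateBrillouinSpectrum(shifts[[i]], noiseSd = 0, seed = i))
  names(specs) <- names(shifts)
  calibrateSpectrometer(specs, shifts)
}
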