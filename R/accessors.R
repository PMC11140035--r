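## Accessors and show methods; slots are never reached into from user code.

#' @rdname AcquisitionConfig-class
#' @aliases deltaT,AcquisitionConfig-method
#' @export
setMethod("deltaT", "AcquisitionConfig", function(object) 1 / object@alineRate)

#' @describeIn AcquisitionConfig-class lateral grid spacing
#'   `scanExtent / (gridPoints - 1)` per axis (mm).
#' @export
setMethod("gridSpacing", "AcquisitionConfig", function(object)
  object@scanExtent / (object@gridPoints - 1L))

setMethod("show", "AcquisitionConfig", function(object) {
  cat("AcquisitionConfig\n")
  cat(sprintf("  lambda0: %g nm, n = %g\n", object@lambda0 * 1e9,
              object@nRefractive))
  cat(sprintf("  A-line rate: %g kHz (delta t = %g us)\n",
              object@alineRate / 1e3, 1e6 / object@alineRate))
  cat(sprintf("  excitation: %g kHz, %d timepoints\n",
              object@excitationFreq / 1e3, object@nTimepoints))
  cat(sprintf("  grid: %d x %d over %g x %g mm, window %g mm\n",
              object@gridPoints[1L], object@gridPoints[2L],
              object@scanExtent[1L], object@scanExtent[2L],
              object@windowSize))
})

setMethod("show", "OrganoidPhantom", function(object) {
  cat("OrganoidPhantom\n")
  cat(sprintf("  shell radius %g mm (vs = %g m/s, shift = %g GHz)\n",
              object@shellRadius, object@vsShell, object@shiftShell))
  cat(sprintf("  core radius %g mm (vs = %g m/s, shift = %g GHz)\n",
              object@coreRadius, object@vsCore, object@shiftCore))
  cat(sprintf("  background vs = %g m/s\n", object@vsBackground))
})

setMethod("show", "VelocityField", function(object) {
  d <- dim(object@vz)
  cat(sprintf("VelocityField: %d x %d x %d (t, x, y), rms %.3g m/s\n",
              d[1L], d[2L], d[3L], sqrt(mean(object@vz^2))))
})

setMethod("show", "PhaseVolume", function(object) {
  d <- dim(object@dphi)
  cat(sprintf("PhaseVolume: %d x %d x %d (t, x, y), |dphi| max %.3g rad\n",
              d[1L], d[2L], d[3L], max(abs(object@dphi))))
})

setMethod("show", "HarmonicField", function(object) {
  d <- dim(object@amp)
  cat(sprintf("HarmonicField at %g Hz: %d x %d, |amp| rms %.3g m/s\n",
              object@freq, d[1L], d[2L], sqrt(mean(Mod(object@amp)^2))))
})

#' @describeIn WavenumberMap-class wavenumber matrix (rad/m), `NA` where
#'   the window fit was rejected.
#' @export
setMethod("wavenumbers", "WavenumberMap", function(object) object@k)

#' @describeIn WavenumberMap-class per-window fit R-squared.
#' @export
setMethod("fitQuality", "WavenumberMap", function(object) object@r2)

setMethod("show", "WavenumberMap", function(object) {
  nv <- sum(!is.na(object@k))
  cat(sprintf(
    "WavenumberMap: %d x %d windows (%g mm), %d valid, median k %.1f rad/m\n",
    nrow(object@k), ncol(object@k), object@windowSize, nv,
    if (nv) median(object@k, na.rm = TRUE) else NA_real_))
})

#' @describeIn SpeedMap-class shear-speed matrix (m/s), `NA` where invalid.
#' @export
setMethod("speedValues", "SpeedMap", function(object) object@vs)

#' @describeIn SpeedMap-class fit R-squared inherited from the wavenumber
#'   fit.
#' @export
setMethod("fitQuality", "SpeedMap", function(object) object@r2)

setMethod("show", "SpeedMap", function(object) {
  nv <- sum(!is.na(object@vs))
  cat(sprintf(
    "SpeedMap at %g Hz: %d x %d windows, %d valid, median vs %.2f m/s\n",
    object@freq, nrow(object@vs), ncol(object@vs), nv,
    if (nv) median(object@vs, na.rm = TRUE) else NA_real_))
})

#' @describeIn Morphometry-class spherical volume in mm^3.
#' @export
setMethod("organoidVolumeMm3", "Morphometry", function(object) object@volume)

setMethod("show", "Morphometry", function(object) {
  cat(sprintf(
    "Morphometry: d = (%.3g + %.3g)/2 = %.3g mm, V = %.4g mm^3\n",
    object@dHorizontal, object@dVertical, object@dMean, object@volume))
})

setMethod("show", "BrillouinSpectrum", function(object) {
  cat(sprintf("BrillouinSpectrum: %d pixels, exposure %g s, max %g counts\n",
              length(object@intensity), object@exposureTime,
              max(object@intensity)))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf(
    "CalibrationModel: %.5g GHz/pixel + %.5g GHz (residual RMS %.3g GHz)\n",
    object@slope, object@intercept, object@residualRms))
  cat(sprintf("  references: %s\n",
              paste(object@references$liquid, collapse = ", ")))
})

setMethod("show", "ShiftMap", function(object) {
  nv <- sum(!is.na(object@nu))
  cat(sprintf("ShiftMap: %d points, %d valid, mean shift %.3f GHz\n",
              nrow(object@coords), nv,
              if (nv) mean(object@nu, na.rm = TRUE) else NA_real_))
})

setMethod("show", "OCTVolume", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("OCTVolume: %d x %d x %d voxels at %g mm\n",
              d[1L], d[2L], d[3L], object@voxelSize))
})

#' @describeIn SegmentationMask-class `TRUE` when the mask contains any
#'   object voxel.
#' @export
setMethod("hasObject", "SegmentationMask", function(object) any(object@mask))

setMethod("show", "SegmentationMask", function(object) {
  cat(sprintf("SegmentationMask: %s, %d object voxels (%d boundary)\n",
              paste(dim(object@mask), collapse = " x "),
              sum(object@mask), sum(object@boundary)))
})
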