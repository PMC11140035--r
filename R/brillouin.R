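## Brillouin spectrometer calibration, Lorentzian shift fitting, OCT
## segmentation and surface-wise shift summaries.

#' Reference-liquid Brillouin shifts at 660 nm
#'
#' Default shifts for the calibration liquids, computed from standard
#' acoustic-velocity and refractive-index tables via
#' `nu = 2 * n * V / lambda` at a 660 nm source. These are configuration
#' defaults, not measurements: override them with the values appropriate
#' to your instrument and temperature.
#'
#' @return named numeric vector (GHz) for water, acetone and methanol.
#' @export
brillouinReferenceShifts <- function() {
  c(water = 5.96, acetone = 4.83, methanol = 4.42)
}

## refine a peak position by fitting a Lorentzian + offset around pixel p0
refinePeakPixel <- function(intensity, p0, halfWindow = 15L) {
  n <- length(intensity)
  i <- max(1L, p0 - halfWindow):min(n, p0 + halfWindow)
  df <- data.frame(x = i, y = intensity[i])
  fit <- try(minpack.lm::nlsLM(
    y ~ b + A * (g / 2)^2 / ((x - c0)^2 + (g / 2)^2), data = df,
    start = list(b = min(df$y), A = max(df$y) - min(df$y),
                 g = halfWindow / 2, c0 = p0),
    lower = c(0, 0, 0.5, min(i)), upper = c(Inf, Inf, 4 * halfWindow, max(i)),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(p0)
  coef(fit)[["c0"]]
}

## locate the Stokes / anti-Stokes peak pair (two dominant local maxima)
locatePeakPair <- function(intensity, exclusion = 20L) {
  p1 <- which.max(intensity)
  masked <- intensity
  masked[max(1L, p1 - exclusion):min(length(intensity), p1 + exclusion)] <- -Inf
  p2 <- which.max(masked)
  sort(c(refinePeakPixel(intensity, p1), refinePeakPixel(intensity, p2)))
}

#' Calibrate the spectrometer pixel axis against reference liquids
#'
#' Each reference liquid contributes its Stokes and anti-Stokes peak
#' pixel positions, which are regressed against `-shift` and `+shift`
#' (GHz) to give the affine pixel-to-GHz map. At least two liquids with
#' distinct shifts are required; identical shifts leave the slope
#' unidentifiable and are rejected.
#'
#' @param refSpectra named list of [BrillouinSpectrum-class] objects, one
#'   per reference liquid.
#' @param refShifts named numeric vector of known shifts (GHz) with
#'   matching names.
#' @return a [CalibrationModel-class].
#' @examples
#' shifts <- brillouinReferenceShifts()
#' specs <- lapply(shifts, simulateBrillouinSpectrum, noiseSd = 0)
#' cal <- calibrateSpectrometer(specs, shifts)
#' @export
calibrateSpectrometer <- function(refSpectra, refShifts) {
  stopifnot(is.list(refSpectra), length(refSpectra) >= 2L,
            all(names(refSpectra) %in% names(refShifts)))
  if (length(unique(round(refShifts[names(refSpectra)], 6))) < 2L)
    stop("degenerate calibration: reference liquids must have distinct ",
         "Brillouin shifts")
  rows <- lapply(names(refSpectra), function(liquid) {
    s <- refSpectra[[liquid]]
    stopifnot(is(s, "BrillouinSpectrum"))
    pk <- locatePeakPair(s@intensity)
    data.frame(liquid = liquid, shift = refShifts[[liquid]],
               pixMinus = pk[1L], pixPlus = pk[2L])
  })
  refs <- do.call(rbind, rows)
  x <- c(refs$pixMinus, refs$pixPlus)
  y <- c(-refs$shift, refs$shift)
  fit <- stats::lm(y ~ x)
  res <- stats::resid(fit)
  new("CalibrationModel", slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      residualRms = sqrt(mean(res^2)), references = refs)
}

#' Fit the Brillouin frequency shift of a spectrum
#'
#' Least-squares fit of a symmetric Stokes / anti-Stokes Lorentzian pair
#' (shared linewidth and amplitude) on the calibrated GHz axis. Spectra
#' without a peak rising at least `minPeakSnr` noise SDs above the
#' baseline are declared invalid rather than fitted.
#'
#' @param s a [BrillouinSpectrum-class].
#' @param calib a [CalibrationModel-class].
#' @param minPeakSnr peak-detection threshold in baseline-noise SDs.
#' @return list with `nu` (GHz), `linewidth` (FWHM, GHz), `quality`
#'   (fit R-squared) and `valid`; `nu` is `NA` when invalid.
#' @export
fitBrillouinShift <- function(s, calib, minPeakSnr = 5) {
  stopifnot(is(s, "BrillouinSpectrum"), is(calib, "CalibrationModel"))
  intensity <- s@intensity
  nu <- calib@slope * seq_along(intensity) + calib@intercept
  base <- median(intensity)
  noise <- stats::mad(intensity)
  if (max(intensity) < base + minPeakSnr * max(noise, 1e-12))
    return(list(nu = NA_real_, linewidth = NA_real_, quality = 0,
                valid = FALSE))
  nu0 <- abs(nu[which.max(intensity)])
  df <- data.frame(x = nu, y = intensity)
  fit <- try(minpack.lm::nlsLM(
    y ~ b + A * ((g / 2)^2 / ((x - s0)^2 + (g / 2)^2) +
                 (g / 2)^2 / ((x + s0)^2 + (g / 2)^2)),
    data = df,
    start = list(b = base, A = max(intensity) - base, g = 0.3, s0 = nu0),
    lower = c(0, 0, 0.01, 0.05), upper = c(Inf, Inf, 5, max(abs(nu))),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(nu = NA_real_, linewidth = NA_real_, quality = 0,
                valid = FALSE))
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((intensity - mean(intensity))^2)
  cf <- coef(fit)
  list(nu = unname(cf[["s0"]]), linewidth = unname(cf[["g"]]),
       quality = r2, valid = TRUE)
}

#' Segment the organoid in an OCT intensity volume
#'
#' Speckle is suppressed with a separable 3x3x3 box blur (skipped for
#' binary input, which has none), the volume is thresholded with Otsu's
#' method, the largest 6-connected component is kept, internal cavities
#' are filled, and a boundary shell of configurable thickness is
#' extracted by erosion. When no component reaches `minSize` voxels the
#' result is an empty ("no object") mask.
#'
#' @param oct an [OCTVolume-class].
#' @param boundaryThickness boundary shell thickness (voxels).
#' @param minSize minimal component size (voxels) to call an object.
#' @param smoothIterations box-blur passes before thresholding.
#' @param minContrast minimal foreground / background mean-intensity
#'   ratio at the Otsu threshold; below it the volume has no
#'   object/background contrast (background only) and no object is
#'   called.
#' @return a [SegmentationMask-class].
#' @export
segmentOrganoid <- function(oct, boundaryThickness = 3L, minSize = 27L,
                            smoothIterations = 1L, minContrast = 2) {
  stopifnot(is(oct, "OCTVolume"))
  x <- oct@intensity
  binaryInput <- length(unique(as.vector(x))) <= 2L
  if (!binaryInput && smoothIterations > 0L)
    x <- boxBlur3(x, smoothIterations)
  ot <- otsuThreshold(as.vector(x))
  mask <- x > ot$threshold
  contrast <- if (any(mask) && any(!mask))
    mean(x[mask]) / mean(x[!mask]) else 0
  ## volumes without object/background contrast carry no object
  if (contrast < minContrast || !any(mask) || all(mask)) mask[] <- FALSE
  mask <- largestComponent(mask)
  if (sum(mask) < minSize) {
    empty <- array(FALSE, dim(mask))
    return(new("SegmentationMask", mask = empty, boundary = empty,
               voxelSize = oct@voxelSize))
  }
  mask <- fillHoles(mask)
  boundary <- mask & !erodeMask(mask, boundaryThickness)
  new("SegmentationMask", mask = mask, boundary = boundary,
      voxelSize = oct@voxelSize)
}

#' Simulate and fit Brillouin shifts at sampled mask points
#'
#' Convenience closed loop for phantom studies: samples points from the
#' segmentation (boundary shell or whole mask), looks up the ground-truth
#' shift of the phantom compartment containing each point, simulates a
#' spectrum there and fits it through the calibration.
#'
#' @param phantom an [OrganoidPhantom-class].
#' @param mask a [SegmentationMask-class] on the OCT grid.
#' @param calib a [CalibrationModel-class].
#' @param where sample from the `"boundary"` shell or the whole
#'   `"mask"`.
#' @param nPoints maximal number of sampled points.
#' @param noiseSd read-noise SD passed to the spectral simulator.
#' @param linewidth Lorentzian FWHM (GHz).
#' @param seed RNG seed.
#' @return a [ShiftMap-class].
#' @export
simulateShiftMap <- function(phantom, mask, calib,
                             where = c("boundary", "mask"),
                             nPoints = 100L, noiseSd = 0, linewidth = 0.3,
                             seed = 1L) {
  stopifnot(is(phantom, "OrganoidPhantom"), is(mask, "SegmentationMask"),
            is(calib, "CalibrationModel"))
  where <- match.arg(where)
  src <- if (where == "boundary") mask@boundary else mask@mask
  if (!any(src))
    stop("mask has no points to sample in region '", where, "'")
  idx <- which(src, arr.ind = TRUE)
  set.seed(seed)
  if (nrow(idx) > nPoints)
    idx <- idx[sample.int(nrow(idx), nPoints), , drop = FALSE]
  d <- dim(src)
  ## voxel centres (mm) relative to the volume centre = phantom centre
  pos <- sweep(idx, 2L, (d + 1) / 2, "-") * mask@voxelSize
  rho <- sqrt(rowSums(pos^2))
  trueShift <- ifelse(rho <= phantom@coreRadius, phantom@shiftCore,
                      phantom@shiftShell)
  nu <- lw <- q <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    sp <- simulateBrillouinSpectrum(trueShift[i], linewidth = linewidth,
                                    noiseSd = noiseSd, seed = seed + i)
    fit <- fitBrillouinShift(sp, calib)
    nu[i] <- fit$nu; lw[i] <- fit$linewidth; q[i] <- fit$quality
  }
  new("ShiftMap", coords = unname(as.matrix(idx)), nu = nu,
      linewidth = lw, quality = q)
}

#' Surface-wise mean Brillouin shift
#'
#' Mean and SD of the valid fitted shifts whose sample points fall on the
#' segmentation's boundary shell (or, optionally, anywhere in the mask).
#'
#' @param shifts a [ShiftMap-class].
#' @param mask a [SegmentationMask-class]; required.
#' @param where restrict to the `"boundary"` shell (surface-wise, the
#'   default) or the whole `"mask"`.
#' @return data.frame with `meanShift`, `sdShift`, `n` (valid points
#'   used) and `nInvalid`.
#' @export
surfaceMeanShift <- function(shifts, mask, where = c("boundary", "mask")) {
  stopifnot(is(shifts, "ShiftMap"))
  if (missing(mask) || !is(mask, "SegmentationMask"))
    stop("a segmentation mask is required to define the surface")
  where <- match.arg(where)
  region <- if (where == "boundary") mask@boundary else mask@mask
  inRegion <- region[shifts@coords]
  nu <- shifts@nu[inRegion]
  valid <- is.finite(nu)
  if (!any(valid))
    stop("no valid shift samples fall on the requested region")
  data.frame(meanShift = mean(nu[valid]),
             sdShift = if (sum(valid) > 1L) sd(nu[valid]) else NA_real_,
             n = sum(valid), nInvalid = sum(!valid) + sum(!inRegion))
}
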