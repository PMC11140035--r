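## Organoid volumetry (sphericity assumption) and region-wise speed
## summaries over OCT-derived masks.

#' Spherical organoid morphometry from diameters or a segmentation
#'
#' The organoid is assumed spherical: the radius is half the mean of the
#' horizontal and vertical diameters and the volume is
#' `V = (4/3) * pi * r^3`. Diameters can be supplied directly or measured
#' from a [SegmentationMask-class] as the mask extents along the
#' horizontal (x) and vertical (z) axes through the mask centroid.
#'
#' @param dHorizontal,dVertical diameters (mm); or pass a mask instead.
#' @param mask a [SegmentationMask-class] to measure diameters from.
#' @return a [Morphometry-class].
#' @examples
#' m <- organoidMorphometry(1.0, 1.0)
#' organoidVolumeMm3(m)        # (4/3)*pi*0.5^3 = 0.5236 mm^3
#' @export
organoidMorphometry <- function(dHorizontal = NULL, dVertical = NULL,
                                mask = NULL) {
  if (!is.null(mask)) {
    stopifnot(is(mask, "SegmentationMask"))
    if (!hasObject(mask))
      stop("mask contains no object; no morphometry possible")
    idx <- which(mask@mask, arr.ind = TRUE)
    cen <- round(colMeans(idx))
    ## extents through the centroid, with a one-voxel tolerance slab
    horiz <- idx[abs(idx[, 2L] - cen[2L]) <= 1L &
                 abs(idx[, 3L] - cen[3L]) <= 1L, 1L]
    vert <- idx[abs(idx[, 1L] - cen[1L]) <= 1L &
                abs(idx[, 2L] - cen[2L]) <= 1L, 3L]
    dHorizontal <- (diff(range(horiz)) + 1L) * mask@voxelSize
    dVertical <- (diff(range(vert)) + 1L) * mask@voxelSize
  }
  if (is.null(dHorizontal) || is.null(dVertical) ||
      !is.finite(dHorizontal) || !is.finite(dVertical) ||
      dHorizontal <= 0 || dVertical <= 0)
    stop("diameters must be positive and finite")
  dMean <- (dHorizontal + dVertical) / 2
  r <- dMean / 2
  new("Morphometry", dHorizontal = dHorizontal, dVertical = dVertical,
      dMean = dMean, r = r, volume = 4 / 3 * pi * r^3)
}

#' Region-wise summary of a shear-wave speed map
#'
#' Splits the masked organoid windows into a surface region (the outer
#' `shellFraction` of the radial extent, measured from the mask centroid)
#' and a core region, and reports mean, median, SD and window counts of
#' the valid speeds in each.
#'
#' @param sm a [SpeedMap-class].
#' @param mask logical matrix on the speed-map grid selecting organoid
#'   windows; `NULL` selects windows within `phantom`'s shell radius.
#' @param shellFraction fraction of the radial extent treated as surface.
#' @param phantom optional [OrganoidPhantom-class] used to build the mask
#'   when none is given.
#' @return data.frame with one row per region (`surface`, `core`):
#'   `mean`, `median`, `sd`, `n` (valid windows), `nTotal`.
#' @export
regionSpeedSummary <- function(sm, mask = NULL, shellFraction = 0.2,
                               phantom = NULL) {
  stopifnot(is(sm, "SpeedMap"))
  cx <- matrix(sm@centersX, nrow = nrow(sm@vs), ncol = ncol(sm@vs))
  cy <- matrix(sm@centersY, nrow = nrow(sm@vs), ncol = ncol(sm@vs),
               byrow = TRUE)
  if (is.null(mask)) {
    if (is.null(phantom))
      stop("supply either a window mask or a phantom to derive one")
    rho <- sqrt((cx - phantom@center[1L])^2 + (cy - phantom@center[2L])^2)
    mask <- rho <= phantom@shellRadius
  }
  stopifnot(is.logical(mask), all(dim(mask) == dim(sm@vs)))
  if (!any(mask))
    stop("mask selects no speed-map windows: regions 'surface' and ",
         "'core' are both empty")
  cenX <- mean(cx[mask]); cenY <- mean(cy[mask])
  rho <- sqrt((cx - cenX)^2 + (cy - cenY)^2)
  rMax <- max(rho[mask])
  surface <- mask & rho >= (1 - shellFraction) * rMax
  core <- mask & !surface
  summarise <- function(sel, label) {
    v <- sm@vs[sel]
    v <- v[is.finite(v)]
    if (!length(v))
      warning("region '", label, "' contains no valid windows")
    data.frame(region = label,
               mean = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) median(v) else NA_real_,
               sd = if (length(v) > 1L) sd(v) else NA_real_,
               n = length(v), nTotal = sum(sel))
  }
  rbind(summarise(surface, "surface"), summarise(core, "core"))
}
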