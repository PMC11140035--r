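#' @rdname AcquisitionConfig-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("deltaT", function(object) standardGeneric("deltaT"))

#' @rdname AcquisitionConfig-class
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))

#' @rdname WavenumberMap-class
#' @param object an object of the documented class.
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname WavenumberMap-class
#' @export
setGeneric("fitQuality", function(object) standardGeneric("fitQuality"))

#' @rdname SpeedMap-class
#' @param object an object of the documented class.
#' @export
setGeneric("speedValues", function(object) standardGeneric("speedValues"))

#' @rdname SegmentationMask-class
#' @param object an object of the documented class.
#' @export
setGeneric("hasObject", function(object) standardGeneric("hasObject"))

#' @rdname Morphometry-class
#' @param object an object of the documented class.
#' @export
setGeneric("organoidVolumeMm3", function(object)
  standardGeneric("organoidVolumeMm3"))
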