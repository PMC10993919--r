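#' Accessors for polarization-imaging containers
#'
#' @param x a [PolarizationStack-class], [NormalizedStack-class],
#'   [OrientationMaps-class] or [SegmentationMask-class] object.
#' @return \code{polImages}: the rows x cols x 4 intensity array;
#'   \code{polAngles}: the polarization angles in degrees;
#'   \code{validMask}/\code{maskRaster}: logical matrices; \code{ofMap} and
#'   \code{azimuthMap}: numeric matrices.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("polImages", function(x) standardGeneric("polImages"))

#' @rdname accessors
#' @export
setGeneric("polAngles", function(x) standardGeneric("polAngles"))

#' @rdname accessors
#' @export
setGeneric("fieldId", function(x) standardGeneric("fieldId"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("ofMap", function(x) standardGeneric("ofMap"))

#' @rdname accessors
#' @export
setGeneric("azimuthMap", function(x) standardGeneric("azimuthMap"))

#' @rdname accessors
#' @export
setGeneric("maskRaster", function(x) standardGeneric("maskRaster"))

#' @rdname accessors
#' @export
setMethod("polImages", "PolarizationStack", function(x) x@images)

#' @rdname accessors
#' @export
setMethod("polAngles", "PolarizationStack", function(x) x@polAngles)

#' @rdname accessors
#' @export
setMethod("fieldId", "PolarizationStack", function(x) x@fieldId)

#' @rdname accessors
#' @export
setMethod("fieldId", "OrientationMaps", function(x) x@fieldId)

#' @rdname accessors
#' @export
setMethod("validMask", "NormalizedStack", function(x) x@validMask)

#' @rdname accessors
#' @export
setMethod("validMask", "OrientationMaps", function(x) x@validMask)

#' @rdname accessors
#' @export
setMethod("ofMap", "OrientationMaps", function(x) x@ofMap)

#' @rdname accessors
#' @export
setMethod("azimuthMap", "OrientationMaps", function(x) x@azimuthMap)

#' @rdname accessors
#' @export
setMethod("maskRaster", "SegmentationMask", function(x) x@mask)

setMethod("show", "PolarizationStack", function(object) {
  d <- dim(object@images)
  cat(sprintf("%s: %d x %d pixels, polarizations %s deg\n",
              class(object), d[1L], d[2L],
              paste(object@polAngles, collapse = "/")))
  if (nzchar(object@fieldId))
    cat("  field:", object@fieldId, "\n")
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@images), max(object@images)))
})

setMethod("show", "OrientationMaps", function(object) {
  d <- dim(object@ofMap)
  nv <- sum(object@validMask)
  cat(sprintf("OrientationMaps: %d x %d pixels, %d valid (%.1f%%)\n",
              d[1L], d[2L], nv, 100 * nv / prod(d)))
  if (nv) {
    cat(sprintf("  OF range (valid): [%.3f, %.3f]\n",
                min(object@ofMap[object@validMask]),
                max(object@ofMap[object@validMask])))
  }
})

setMethod("show", "SegmentationMask", function(object) {
  cat(sprintf(
    "SegmentationMask: %d x %d, %d foreground px, Otsu threshold %.4g (top-hat radius %g)\n",
    nrow(object@mask), ncol(object@mask), sum(object@mask),
    object@thresholdValue, object@tophatRadius))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d x %d px, %d puncta, background %g, vignette %g, PSF sigma %g px, seed %d\n",
    object@imageSize[1L], object@imageSize[2L], nrow(object@puncta),
    object@backgroundLevel, object@vignetteDepth, object@psfSigma,
    object@rngSeed))
})
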