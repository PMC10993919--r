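#' @import methods
NULL

# Extract polarization channel k as a matrix (drop = TRUE would collapse
# single-row or single-column images to vectors).
.chan <- function(a, k) {
  m <- a[, , k, drop = FALSE]
  dim(m) <- dim(a)[1:2]
  m
}

# Shared dimension check for the four-image containers: images is a
# rows x cols x 4 numeric array, one slice per excitation polarization.
.checkFourImages <- function(images, requireFinite = TRUE,
                             requireNonNegative = TRUE) {
  msg <- character(0)
  if (!is.array(images) || length(dim(images)) != 3L)
    return("'images' must be a rows x cols x 4 array")
  if (dim(images)[3L] != 4L)
    msg <- c(msg, "exactly 4 polarization images are required")
  if (requireFinite && !all(is.finite(images)))
    msg <- c(msg, "all intensities must be finite")
  if (requireNonNegative && any(images < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be >= 0")
  msg
}

#' PolarizationStack: a four-polarization excitation stack
#'
#' Container for one imaging field: four co-registered intensity images
#' acquired at linear excitation polarizations of 0, 45, 90 and 135 degrees
#' measured from the positive x-axis (image columns increase along +x, rows
#' increase downward; angles are counterclockwise in the x/up-y frame).
#'
#' @slot images numeric array, rows x cols x 4, one slice per polarization
#'   in the fixed storage order 0, 45, 90, 135 degrees; finite, non-negative
#'   detector units.
#' @slot polAngles numeric(4), always \code{c(0, 45, 90, 135)}.
#' @slot pixelSize physical pixel size in micrometres (NA when unknown);
#'   metadata only, never used in computation.
#' @slot fieldId free-text field identifier.
#'
#' @seealso [readPolarizationStack()], [flatFieldCorrect()]
#' @export
setClass("PolarizationStack",
  representation(
    images = "array",
    polAngles = "numeric",
    pixelSize = "numeric",
    fieldId = "character"
  ),
  prototype(
    polAngles = c(0, 45, 90, 135),
    pixelSize = NA_real_,
    fieldId = ""
  )
)

setValidity("PolarizationStack", function(object) {
  msg <- .checkFourImages(object@images)
  if (!identical(as.numeric(object@polAngles), c(0, 45, 90, 135)))
    msg <- c(msg, "polAngles must be exactly c(0, 45, 90, 135)")
  if (length(object@fieldId) != 1L)
    msg <- c(msg, "fieldId must be a single string")
  if (length(msg)) msg else TRUE
})

#' FlatFieldStack: normalized flat-field reference
#'
#' Per-polarization mean of one or more stacks acquired on a uniformly
#' autofluorescent slide, normalized so the global maximum over all four
#' images is 1. Every element must be strictly positive (greater than 1e-6
#' of the maximum) so that division is always defined.
#'
#' @slot sourceCount number of raw slide stacks averaged (study value 3).
#' @export
setClass("FlatFieldStack",
  contains = "PolarizationStack",
  representation(sourceCount = "integer"),
  prototype(sourceCount = 1L)
)

setValidity("FlatFieldStack", function(object) {
  msg <- character(0)
  mx <- max(object@images)
  if (abs(mx - 1) > 1e-12)
    msg <- c(msg, "flat-field stack must be normalized to a maximum of 1")
  if (any(object@images <= 1e-6 * mx))
    msg <- c(msg, "flat-field elements must exceed 1e-6 of the maximum")
  if (length(msg)) msg else TRUE
})

#' CorrectedStack: flat-field corrected stack
#'
#' Element-wise quotient of a raw stack by a [FlatFieldStack-class],
#' polarization-matched. Values are in corrected detector units and may
#' exceed the raw range.
#'
#' @slot provenance named character(2): the field id of the raw stack and an
#'   identifier for the flat field used.
#' @export
setClass("CorrectedStack",
  contains = "PolarizationStack",
  representation(provenance = "character"),
  prototype(provenance = c(field = "", flat = ""))
)

#' NormalizedStack: pixel-wise max-normalized stack
#'
#' At every pixel the four corrected intensities are divided by their
#' maximum across polarizations, so the per-pixel maximum is exactly 1 at
#' valid pixels. Pixels whose four-channel maximum was 0 are flagged invalid
#' and carry 0 in all channels.
#'
#' @slot validMask logical matrix, FALSE where the four-channel maximum was 0.
#' @export
setClass("NormalizedStack",
  contains = "PolarizationStack",
  representation(validMask = "matrix")
)

setValidity("NormalizedStack", function(object) {
  msg <- character(0)
  d <- dim(object@images)
  if (!is.logical(object@validMask) ||
      !identical(dim(object@validMask), d[1:2]))
    msg <- c(msg, "validMask must be a logical matrix matching image size")
  if (length(msg)) msg else TRUE
})

#' OrientationMaps: per-pixel Order Factor and azimuth
#'
#' The per-pixel readout of excitation-resolved polarization imaging. The
#' Order Factor OF = sqrt(A^2 + B^2) with A = I0 - I90 and B = I45 - I135
#' on normalized intensities; the azimuth alpha = arctan2(B, A) / 2 is an
#' axial (180-degree ambiguous) angle reported in degrees on (-90, +90].
#'
#' @slot ofMap numeric matrix of per-pixel OF values (>= 0; not clipped
#'   above, see the package vignette).
#' @slot azimuthMap numeric matrix of azimuths in degrees on (-90, +90];
#'   NA where undefined (invalid pixel or OF = 0).
#' @slot validMask logical matrix: TRUE where both OF and azimuth are
#'   defined.
#' @export
setClass("OrientationMaps",
  representation(
    ofMap = "matrix",
    azimuthMap = "matrix",
    validMask = "matrix",
    fieldId = "character"
  ),
  prototype(fieldId = "")
)

setValidity("OrientationMaps", function(object) {
  msg <- character(0)
  d <- dim(object@ofMap)
  if (!identical(dim(object@azimuthMap), d) ||
      !identical(dim(object@validMask), d))
    msg <- c(msg, "ofMap, azimuthMap and validMask must share dimensions")
  if (any(object@ofMap[object@validMask] < 0))
    msg <- c(msg, "OF must be >= 0 at valid pixels")
  az <- object@azimuthMap[object@validMask]
  if (any(is.na(az)) || any(az <= -90 | az > 90))
    msg <- c(msg, "valid azimuths must lie in (-90, 90] degrees")
  if (length(msg)) msg else TRUE
})

#' SegmentationMask: binary analysis mask
#'
#' Binarization of the average-intensity image: white top-hat with a
#' disk-shaped structuring element, then a global Otsu threshold on the
#' top-hat image.
#'
#' @slot mask logical matrix (TRUE = foreground).
#' @slot thresholdValue the Otsu threshold applied to the top-hat image.
#' @slot tophatRadius structuring-element radius in pixels (default 3).
#' @export
setClass("SegmentationMask",
  representation(
    mask = "matrix",
    thresholdValue = "numeric",
    tophatRadius = "numeric"
  )
)

#' SceneSpec: ground-truth description of a synthetic polarization scene
#'
#' Forward-model specification for simulated polarized-excitation imaging of
#' punctate junctions. Each punctum is a disk of fluorophore dipoles whose
#' in-plane orientations follow a wrapped normal distribution with a mean
#' azimuth and circular spread; the expected signal at excitation angle
#' theta is amplitude * (1 + c2 * cos 2(theta - mu)) / 2 where c2 =
#' exp(-2 sigma^2) is the wrapped-normal second circular moment.
#'
#' @slot imageSize integer(2): rows, cols.
#' @slot puncta data.frame with columns \code{row}, \code{col} (centres, may
#'   be fractional), \code{diameter} (px), \code{amplitude} (expected photons
#'   per pixel at unit angular response), \code{muDeg} (mean dipole azimuth,
#'   degrees), \code{sigmaDeg} (circular spread, degrees).
#' @slot backgroundLevel expected background photons per pixel per channel.
#' @slot vignetteDepth relative attenuation of the multiplicative flat-field
#'   at the image corner (0 = uniform illumination).
#' @slot psfSigma Gaussian PSF sigma in pixels (0 disables blurring).
#' @slot poissonNoise logical: apply photon shot noise.
#' @slot readNoiseSd Gaussian read-noise sigma in photon-equivalents.
#' @slot rngSeed integer seed recorded in the output; rendering is
#'   deterministic given the spec.
#' @seealso [renderScene()]
#' @export
setClass("SceneSpec",
  representation(
    imageSize = "integer",
    puncta = "data.frame",
    backgroundLevel = "numeric",
    vignetteDepth = "numeric",
    psfSigma = "numeric",
    poissonNoise = "logical",
    readNoiseSd = "numeric",
    rngSeed = "integer"
  ),
  prototype(
    imageSize = c(256L, 256L),
    backgroundLevel = 50,
    vignetteDepth = 0.2,
    psfSigma = 1.2,
    poissonNoise = TRUE,
    readNoiseSd = 2,
    rngSeed = 1L
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character(0)
  p <- object@puncta
  need <- c("row", "col", "diameter", "amplitude", "muDeg", "sigmaDeg")
  if (!all(need %in% names(p)))
    return(paste("puncta must have columns:", paste(need, collapse = ", ")))
  if (nrow(p)) {
    if (any(p$amplitude <= 0)) msg <- c(msg, "amplitudes must be > 0")
    if (any(p$sigmaDeg < 0)) msg <- c(msg, "sigmaDeg must be >= 0")
    if (any(p$row < 1 | p$row > object@imageSize[1L] |
            p$col < 1 | p$col > object@imageSize[2L]))
      msg <- c(msg, "puncta centres must be inside the image")
  }
  if (object@backgroundLevel < 0) msg <- c(msg, "background must be >= 0")
  if (object@vignetteDepth < 0 || object@vignetteDepth >= 1)
    msg <- c(msg, "vignetteDepth must be in [0, 1)")
  if (length(msg)) msg else TRUE
})
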