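#' Construct a PolarizationStack
#'
#' @param images either a rows x cols x 4 numeric array or a list of four
#'   matrices with identical dimensions, in the polarization order 0, 45,
#'   90, 135 degrees.
#' @param pixelSize physical pixel size in micrometres (metadata only).
#' @param fieldId free-text identifier for the imaging field.
#' @return a validated [PolarizationStack-class].
#' @examples
#' s <- PolarizationStack(array(1, c(8, 8, 4)), fieldId = "demo")
#' polAngles(s)
#' @export
PolarizationStack <- function(images, pixelSize = NA_real_, fieldId = "") {
  if (is.list(images)) {
    if (length(images) != 4L)
      stop("expected 4 polarization images, got ", length(images))
    dims <- unique(lapply(images, dim))
    if (length(dims) != 1L)
      stop("polarization images have inconsistent dimensions")
    images <- array(unlist(images, use.names = FALSE),
                    dim = c(dims[[1L]], 4L))
  }
  new("PolarizationStack", images = images, polAngles = c(0, 45, 90, 135),
      pixelSize = pixelSize, fieldId = fieldId)
}

# tiff stores pages as matrices (or rows x cols x channels); coerce to a
# grayscale matrix, failing loudly for colour data.
.pageToMatrix <- function(p) {
  if (is.matrix(p)) return(p)
  if (length(dim(p)) == 3L && dim(p)[3L] == 1L) return(p[, , 1L])
  stop("only single-channel grayscale TIFF pages are supported")
}

#' Read polarization stacks from a multi-page TIFF
#'
#' Pages are grouped into fields of four, mapped to excitation polarizations
#' 0, 45, 90, 135 degrees. With \code{layout = "sequential"} pages 1-4 form
#' field 1, pages 5-8 field 2, and so on; with \code{layout = "interleaved"}
#' page i of field f is page (i - 1) * nFields + f (all first-polarization
#' pages, then all second, ...).
#'
#' Integer TIFFs are read back as raw detector counts (16-bit values on the
#' 0..65535 scale); 32-bit float TIFFs are read as stored.
#'
#' @param path path to a multi-page grayscale TIFF with a multiple of 4
#'   pages.
#' @param layout page-order convention, \code{"sequential"} or
#'   \code{"interleaved"}.
#' @param pixelSize,fieldId metadata forwarded to the stacks; with several
#'   fields, ids are suffixed \code{_1}, \code{_2}, ...
#' @return a [PolarizationStack-class], or a list of them when the file
#'   holds more than one field.
#' @seealso [writePolarizationStack()]
#' @export
readPolarizationStack <- function(path, layout = c("sequential",
                                                   "interleaved"),
                                  pixelSize = NA_real_, fieldId = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  if (n < 4L || n %% 4L != 0L)
    stop("expected 4 pages per field; file has ", n, " pages")
  pages <- lapply(pages, .pageToMatrix)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) stop("inconsistent page dimensions in ", path)
  nFields <- n %/% 4L
  if (is.null(fieldId))
    fieldId <- tools::file_path_sans_ext(basename(path))
  stacks <- lapply(seq_len(nFields), function(f) {
    idx <- switch(layout,
      sequential = (f - 1L) * 4L + 1:4,
      interleaved = (1:4 - 1L) * nFields + f
    )
    id <- if (nFields > 1L) paste0(fieldId, "_", f) else fieldId
    PolarizationStack(lapply(pages[idx], function(m) m * 1.0),
                      pixelSize = pixelSize, fieldId = id)
  })
  if (nFields == 1L) stacks[[1L]] else stacks
}

#' Write a polarization stack as a multi-page TIFF
#'
#' Pages are written in the storage order 0, 45, 90, 135 degrees. 16-bit
#' output expects raw counts in 0..65535 (values are rounded); 32-bit output
#' stores floating point as-is and is the right choice for corrected or
#' derived rasters.
#'
#' @param x a [PolarizationStack-class] (or subclass).
#' @param path output path.
#' @param bitsPerSample 16 (integer counts) or 32 (float).
#' @return \code{path}, invisibly.
#' @export
writePolarizationStack <- function(x, path, bitsPerSample = 16L) {
  stopifnot(is(x, "PolarizationStack"))
  imgs <- lapply(1:4, function(k) .chan(x@images, k))
  if (bitsPerSample == 16L) {
    imgs <- lapply(imgs, function(m) {
      if (any(m < 0 | m > 65535))
        stop("16-bit output requires values in 0..65535")
      round(m) / 65535
    })
  } else if (bitsPerSample != 32L) {
    stop("bitsPerSample must be 16 or 32")
  }
  tiff::writeTIFF(imgs, path, bits.per.sample = as.integer(bitsPerSample),
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Write a single raster as a 32-bit float TIFF
#'
#' @param m numeric matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRaster32 <- function(m, path) {
  tiff::writeTIFF(m, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Build a normalized flat-field reference
#'
#' Averages one or more four-polarization stacks acquired on a uniformly
#' autofluorescent slide along each excitation polarization, then divides
#' the whole four-image stack by its single global maximum.
#'
#' @param rawFlatStacks a [PolarizationStack-class] or list of them, all
#'   with identical dimensions.
#' @return a [FlatFieldStack-class] whose global maximum is exactly 1.
#' @export
buildFlatField <- function(rawFlatStacks) {
  if (is(rawFlatStacks, "PolarizationStack"))
    rawFlatStacks <- list(rawFlatStacks)
  if (!length(rawFlatStacks)) stop("at least one flat stack is required")
  dims <- unique(lapply(rawFlatStacks, function(s) dim(s@images)))
  if (length(dims) != 1L) stop("flat stacks have mismatched dimensions")
  acc <- Reduce(`+`, lapply(rawFlatStacks, function(s) s@images))
  acc <- acc / length(rawFlatStacks)
  mx <- max(acc)
  if (mx <= 0) stop("cannot normalize an all-zero flat-field stack")
  new("FlatFieldStack", images = acc / mx, polAngles = c(0, 45, 90, 135),
      pixelSize = rawFlatStacks[[1L]]@pixelSize, fieldId = "flat",
      sourceCount = length(rawFlatStacks))
}

#' Flat-field correct a raw stack
#'
#' Divides each element of the raw emission stack by the corresponding
#' element of the flat-field stack, polarization by polarization.
#'
#' @param raw a [PolarizationStack-class].
#' @param flat a [FlatFieldStack-class] with matching dimensions.
#' @return a [CorrectedStack-class].
#' @export
flatFieldCorrect <- function(raw, flat) {
  stopifnot(is(raw, "PolarizationStack"), is(flat, "FlatFieldStack"))
  if (!identical(dim(raw@images), dim(flat@images)))
    stop("raw and flat-field dimensions differ")
  if (any(flat@images <= 0))
    stop("flat-field contains nonpositive elements; refusing to divide")
  out <- raw@images / flat@images
  new("CorrectedStack", images = out, polAngles = c(0, 45, 90, 135),
      pixelSize = raw@pixelSize, fieldId = raw@fieldId,
      provenance = c(field = raw@fieldId, flat = flat@fieldId))
}

#' Pixel-wise max normalization
#'
#' At each pixel, divides the four corrected intensities by their maximum
#' across excitation polarizations, so the largest of the four equals 1.
#' Pixels whose four-channel maximum is 0 carry 0 in every channel and are
#' flagged invalid.
#'
#' @param corrected a [CorrectedStack-class] (any
#'   [PolarizationStack-class] is accepted).
#' @return a [NormalizedStack-class].
#' @export
normalizeStack <- function(corrected) {
  stopifnot(is(corrected, "PolarizationStack"))
  imgs <- corrected@images
  mx <- pmax(.chan(imgs, 1L), .chan(imgs, 2L), .chan(imgs, 3L),
             .chan(imgs, 4L))
  valid <- mx > 0
  div <- ifelse(valid, mx, 1)
  out <- imgs / as.vector(div) # recycles over the 3rd dimension
  if (any(!valid)) {
    for (k in 1:4) {
      sl <- .chan(out, k)
      sl[!valid] <- 0
      out[, , k] <- sl
    }
  }
  new("NormalizedStack", images = out, polAngles = c(0, 45, 90, 135),
      pixelSize = corrected@pixelSize, fieldId = corrected@fieldId,
      validMask = valid)
}

#' Average-intensity image
#'
#' Per-pixel arithmetic mean of the four flat-field corrected polarization
#' images; this is the raster that segmentation and signal-to-background
#' measurements operate on.
#'
#' @param corrected a [PolarizationStack-class] (typically a
#'   [CorrectedStack-class]).
#' @return a numeric matrix.
#' @export
averageIntensity <- function(corrected) {
  stopifnot(is(corrected, "PolarizationStack"))
  (.chan(corrected@images, 1L) + .chan(corrected@images, 2L) +
     .chan(corrected@images, 3L) + .chan(corrected@images, 4L)) / 4
}
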