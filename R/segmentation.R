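#' Otsu threshold with fixed binning policy
#'
#' Global threshold maximizing the between-class variance of the image
#' histogram. The histogram uses \code{nbins} equal-width bins spanning the
#' image min..max; candidate cuts fall on bin boundaries and ties in the
#' between-class variance are broken toward the lower threshold. Class
#' statistics use bin midpoints.
#'
#' @param x numeric matrix or vector of finite values.
#' @param nbins number of histogram bins (default 256).
#' @return the threshold value (pixels strictly above it are foreground);
#'   \code{NA} with a warning for a constant input.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  v <- as.vector(x)
  stopifnot(all(is.finite(v)))
  rng <- range(v)
  if (rng[1L] == rng[2L]) {
    warning("constant image: no Otsu threshold exists")
    return(NA_real_)
  }
  width <- (rng[2L] - rng[1L]) / nbins
  idx <- pmin(nbins, 1L + floor((v - rng[1L]) / width))
  counts <- tabulate(idx, nbins)
  mids <- rng[1L] + (seq_len(nbins) - 0.5) * width
  w <- cumsum(counts)
  s <- cumsum(counts * mids)
  total <- w[nbins]
  totalSum <- s[nbins]
  k <- seq_len(nbins - 1L)
  w0 <- w[k]
  w1 <- total - w0
  ok <- w0 > 0 & w1 > 0
  mu0 <- s[k] / w0
  mu1 <- (totalSum - s[k]) / w1
  bcv <- ifelse(ok, w0 * w1 * (mu0 - mu1)^2, -Inf)
  kBest <- which.max(bcv) # which.max takes the first (lowest) maximizer
  rng[1L] + kBest * width
}

#' Build the segmentation mask
#'
#' Applies a white top-hat transform (disk-shaped structuring element) to
#' the average-intensity image to remove smooth background, then binarizes
#' the top-hat image at its Otsu threshold.
#'
#' @param avg average-intensity raster (finite, non-negative).
#' @param tophatRadius structuring-element radius in pixels (default 3).
#' @return a [SegmentationMask-class]; for a constant image, an empty mask
#'   with a warning.
#' @export
buildMask <- function(avg, tophatRadius = 3) {
  stopifnot(is.matrix(avg), all(is.finite(avg)), all(avg >= 0))
  brush <- EBImage::makeBrush(2L * as.integer(tophatRadius) + 1L, "disc")
  th <- EBImage::imageData(EBImage::whiteTopHat(avg, brush))
  dim(th) <- dim(avg)
  if (max(th) == min(th)) {
    warning("no foreground: top-hat image is constant; mask is empty")
    return(new("SegmentationMask", mask = matrix(FALSE, nrow(avg), ncol(avg)),
               thresholdValue = NA_real_, tophatRadius = tophatRadius))
  }
  thr <- otsuThreshold(th)
  new("SegmentationMask", mask = th > thr, thresholdValue = thr,
      tophatRadius = tophatRadius)
}

#' Label connected components (4-connectivity)
#'
#' Segments the mask into maximal 4-connected components. Labels are
#' assigned deterministically in row-major order of each component's first
#' pixel (scanning rows top to bottom, columns left to right).
#'
#' @param mask a [SegmentationMask-class] or a logical matrix.
#' @return an integer matrix of labels, 0 for background.
#' @export
labelObjects <- function(mask) {
  if (is(mask, "SegmentationMask")) mask <- mask@mask
  stopifnot(is.matrix(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1L))
  dim(lab) <- dim(mask)
  n <- max(lab)
  if (n == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  # relabel by row-major first pixel
  idx <- which(lab > 0, arr.ind = TRUE)
  rowMajor <- (idx[, 1L] - 1L) * ncol(mask) + idx[, 2L]
  firstPix <- tapply(rowMajor, lab[lab > 0], min)
  remap <- integer(n)
  remap[as.integer(names(firstPix))[order(firstPix)]] <- seq_len(n)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

.dilKernel <- function(metric) {
  switch(metric,
    cityblock = matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3L, 3L),
    chebyshev = matrix(1, 3L, 3L),
    stop("unknown dilation metric: ", metric)
  )
}

.dilateN <- function(m, n, kern) {
  for (i in seq_len(n)) m <- EBImage::imageData(EBImage::dilate(m * 1, kern)) > 0
  m
}

# Buffer and background-ring geometry around one object, on the full image.
# Buffer: within 3 dilations of the object, outside it. Ring: within the
# further 2 dilations, outside object and buffer. Ring pixels inside any
# OTHER object's 3-dilation zone are excluded from the background.
.objectZones <- function(objMask, allMask, metric = "cityblock") {
  kern <- .dilKernel(metric)
  d3 <- .dilateN(objMask, 3L, kern)
  d5 <- .dilateN(d3, 2L, kern)
  others <- allMask & !objMask
  othersD3 <- if (any(others)) .dilateN(others, 3L, kern) else others
  list(buffer = d3 & !objMask, ring = d5 & !d3 & !othersD3)
}

#' Local signal-to-background of one object
#'
#' Signal is the mean average-intensity over the object's pixels. A
#' 3-pixel-wide buffer zone around the object is excluded; the background
#' is the mean over the 2-pixel-wide ring around the buffer. Ring pixels
#' falling inside other objects or their buffers are excluded from the
#' background, and the ring is clipped at the image edge. Zone widths are
#' successive morphological dilations; the metric defaults to city-block
#' (4-connected cross), matching the component connectivity.
#'
#' @param labels integer label matrix from [labelObjects()].
#' @param objectId the label to measure.
#' @param avg average-intensity raster.
#' @param dilationMetric \code{"cityblock"} or \code{"chebyshev"}.
#' @return a list with \code{sbRatio} (Inf if the background mean is 0, NA
#'   if the ring is empty), \code{signalMean}, \code{backgroundMean}, and
#'   the logical \code{buffer} and \code{ring} rasters.
#' @export
signalToBackground <- function(labels, objectId, avg,
                               dilationMetric = c("cityblock", "chebyshev")) {
  dilationMetric <- match.arg(dilationMetric)
  stopifnot(identical(dim(labels), dim(avg)))
  objMask <- labels == objectId
  if (!any(objMask)) stop("no pixels with label ", objectId)
  z <- .objectZones(objMask, labels > 0, dilationMetric)
  signalMean <- mean(avg[objMask])
  nRing <- sum(z$ring)
  backgroundMean <- if (nRing) mean(avg[z$ring]) else NA_real_
  sb <- if (nRing == 0) NA_real_
        else if (backgroundMean == 0) Inf
        else signalMean / backgroundMean
  list(sbRatio = sb, signalMean = signalMean,
       backgroundMean = backgroundMean, buffer = z$buffer, ring = z$ring)
}

#' Object-level order metrics
#'
#' For every labeled object computes the object OF (mean pixel OF over
#' member pixels with defined orientation), the azimuthal disorder (axial
#' circular standard deviation of member azimuths, [axialCircularSD()]),
#' the local signal-to-background ratio ([signalToBackground()]), the
#' centroid and the pixel count, and flags which objects pass the filters:
#' sbRatio >= minSb (strict: S/B exactly at the threshold is retained), at
#' least 2 member pixels with defined azimuth, and a non-empty background
#' ring.
#'
#' Pixels invalid in the orientation maps (including OF = 0 pixels, whose
#' azimuth is undefined) are excluded from both the object OF and the
#' disorder statistic.
#'
#' @param labels integer label matrix from [labelObjects()].
#' @param maps an [OrientationMaps-class].
#' @param avg average-intensity raster.
#' @param minSb signal-to-background retention threshold (default 3).
#' @param dilationMetric zone metric, see [signalToBackground()].
#' @return a data.frame with one row per object: \code{objectId},
#'   \code{fieldId}, \code{nPixels}, \code{centroidRow}, \code{centroidCol},
#'   \code{meanOF}, \code{azimuthCSD} (degrees), \code{nAzimuth},
#'   \code{sbRatio}, \code{retained}.
#' @export
objectStats <- function(labels, maps, avg, minSb = 3,
                        dilationMetric = c("cityblock", "chebyshev")) {
  dilationMetric <- match.arg(dilationMetric)
  stopifnot(is(maps, "OrientationMaps"),
            identical(dim(labels), dim(maps@ofMap)),
            identical(dim(labels), dim(avg)))
  ids <- sort(unique(labels[labels > 0]))
  nr <- nrow(labels); nc <- ncol(labels)
  kern <- .dilKernel(dilationMetric)
  allMask <- labels > 0
  # other-object exclusion zone, computed once: union of all 3-dilations
  globalD3 <- if (any(allMask)) .dilateN(allMask, 3L, kern) else allMask
  rows <- lapply(ids, function(id) {
    pix <- which(labels == id, arr.ind = TRUE)
    # crop with a 6-px margin so 5 dilations stay inside the crop unless
    # clipped by the true image edge
    r0 <- max(1L, min(pix[, 1L]) - 6L); r1 <- min(nr, max(pix[, 1L]) + 6L)
    c0 <- max(1L, min(pix[, 2L]) - 6L); c1 <- min(nc, max(pix[, 2L]) + 6L)
    objC <- labels[r0:r1, c0:c1, drop = FALSE] == id
    d3 <- .dilateN(objC, 3L, kern)
    d5 <- .dilateN(d3, 2L, kern)
    ring <- d5 & !d3 & !globalD3[r0:r1, c0:c1, drop = FALSE]
    avgC <- avg[r0:r1, c0:c1, drop = FALSE]
    signalMean <- mean(avgC[objC])
    nRing <- sum(ring)
    bgMean <- if (nRing) mean(avgC[ring]) else NA_real_
    sb <- if (nRing == 0) NA_real_
          else if (bgMean == 0) Inf else signalMean / bgMean
    valid <- maps@validMask[pix]
    ofVals <- maps@ofMap[pix][valid]
    azVals <- maps@azimuthMap[pix][valid]
    csd <- suppressWarnings(axialCircularSD(azVals))
    data.frame(
      objectId = id,
      nPixels = nrow(pix),
      centroidRow = mean(pix[, 1L]),
      centroidCol = mean(pix[, 2L]),
      meanOF = if (length(ofVals)) mean(ofVals) else NA_real_,
      azimuthCSD = csd,
      nAzimuth = sum(!is.na(azVals)),
      sbRatio = sb
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(objectId = integer(0), nPixels = integer(0),
                      centroidRow = numeric(0), centroidCol = numeric(0),
                      meanOF = numeric(0), azimuthCSD = numeric(0),
                      nAzimuth = integer(0), sbRatio = numeric(0))
  }
  out$fieldId <- rep(maps@fieldId, nrow(out))
  out$retained <- !is.na(out$sbRatio) & out$sbRatio >= minSb &
    !is.na(out$meanOF) & !is.na(out$azimuthCSD) & out$nAzimuth >= 2L
  out[, c("objectId", "fieldId", "nPixels", "centroidRow", "centroidCol",
          "meanOF", "azimuthCSD", "nAzimuth", "sbRatio", "retained")]
}

#' Filter objects by signal-to-background
#'
#' Retains objects whose S/B is at least \code{minSb} (the exclusion rule
#' is strict: S/B < minSb is dropped, S/B = minSb is kept) and whose metric
#' fields are all defined. Exclusion counts are reported in a message.
#'
#' @param objects the data.frame from [objectStats()].
#' @param minSb retention threshold (default 3).
#' @return the retained subset of \code{objects}.
#' @export
filterObjects <- function(objects, minSb = 3) {
  if (!nrow(objects)) return(objects)
  defined <- !is.na(objects$sbRatio) & !is.na(objects$meanOF) &
    !is.na(objects$azimuthCSD)
  keep <- defined & objects$sbRatio >= minSb
  nDropSb <- sum(defined & objects$sbRatio < minSb)
  nDropUndef <- sum(!defined)
  message(sprintf("filterObjects: %d retained, %d below S/B %g, %d undefined",
                  sum(keep), nDropSb, minSb, nDropUndef))
  objects[keep, , drop = FALSE]
}
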