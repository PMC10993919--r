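#' Per-pixel Order Factor and azimuth
#'
#' Computes, at every pixel of a normalized stack, the channel differences
#' A = I0 - I90 and B = I45 - I135, the Order Factor
#' OF = sqrt(A^2 + B^2), and the azimuth alpha = arctan2(B, A) / 2. The
#' azimuth is an axial quantity with a 180-degree ambiguity, reported in
#' degrees on (-90, +90] measured counterclockwise from the positive
#' x-axis.
#'
#' Because the normalization divides by the per-pixel four-channel maximum,
#' the OF of a perfectly aligned population depends on its orientation
#' (1 at axis-aligned angles, up to about 1.17 at 22.5 degrees); values are
#' reported as computed, never clipped.
#'
#' Pixels that were invalid in the input, and pixels where OF = 0 (where
#' the azimuth is mathematically undefined), carry OF = 0 / azimuth NA and
#' are excluded from the validity mask so that downstream circular
#' statistics never ingest fabricated angles.
#'
#' @param normalized a [NormalizedStack-class].
#' @return an [OrientationMaps-class].
#' @examples
#' imgs <- array(0, c(1, 1, 4))
#' imgs[1, 1, ] <- c(1, 0.5, 0, 0.5) # dipoles aligned with the x-axis
#' ns <- new("NormalizedStack", images = imgs,
#'           polAngles = c(0, 45, 90, 135), pixelSize = NA_real_,
#'           fieldId = "", validMask = matrix(TRUE, 1, 1))
#' m <- computeOrientationMaps(ns)
#' ofMap(m)       # 1
#' azimuthMap(m)  # 0 degrees
#' @export
computeOrientationMaps <- function(normalized) {
  stopifnot(is(normalized, "NormalizedStack"))
  imgs <- normalized@images
  A <- .chan(imgs, 1L) - .chan(imgs, 3L)
  B <- .chan(imgs, 2L) - .chan(imgs, 4L)
  of <- sqrt(A * A + B * B)
  az <- atan2(B, A) / 2 * 180 / pi # atan2 in (-pi, pi] => az in (-90, 90]
  valid <- normalized@validMask & of > 0
  of[!normalized@validMask] <- 0
  az[!valid] <- NA_real_
  new("OrientationMaps", ofMap = of, azimuthMap = az, validMask = valid,
      fieldId = normalized@fieldId)
}

#' Azimuth line overlay
#'
#' Builds one line segment per masked valid pixel, centred on the pixel,
#' oriented along the pixel azimuth, with length proportional to the pixel
#' OF — the standard visualization of orientation maps. Pixels with OF = 0
#' (undefined azimuth) emit no segment.
#'
#' Coordinates are in pixel units with x = column and y = row (y increases
#' downward); because azimuths are counterclockwise in the x/up-y frame,
#' the segment direction is (cos alpha, -sin alpha) in (x, y).
#'
#' @param maps an [OrientationMaps-class].
#' @param mask logical matrix selecting pixels (defaults to all valid).
#' @param scale OF-to-length factor in pixels per unit OF.
#' @return a data.frame with columns \code{row}, \code{col}, \code{x0},
#'   \code{y0}, \code{x1}, \code{y1}, \code{of}, \code{azimuthDeg}.
#' @seealso [plotAzimuthOverlay()]
#' @export
azimuthOverlay <- function(maps, mask = NULL, scale = 2) {
  stopifnot(is(maps, "OrientationMaps"))
  if (is.null(mask)) mask <- maps@validMask
  stopifnot(identical(dim(mask), dim(maps@ofMap)))
  sel <- which(mask & maps@validMask, arr.ind = TRUE)
  if (!nrow(sel)) {
    return(data.frame(row = integer(0), col = integer(0), x0 = numeric(0),
                      y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
                      of = numeric(0), azimuthDeg = numeric(0)))
  }
  of <- maps@ofMap[sel]
  az <- maps@azimuthMap[sel] * pi / 180
  half <- scale * of / 2
  dx <- cos(az) * half
  dy <- -sin(az) * half # image y runs downward
  data.frame(
    row = sel[, 1L], col = sel[, 2L],
    x0 = sel[, 2L] - dx, y0 = sel[, 1L] - dy,
    x1 = sel[, 2L] + dx, y1 = sel[, 1L] + dy,
    of = of, azimuthDeg = maps@azimuthMap[sel]
  )
}

#' Plot an azimuth overlay
#'
#' Renders the segments from [azimuthOverlay()] over the OF map using base
#' graphics (image y-axis pointing down, as in the raster).
#'
#' @param maps an [OrientationMaps-class].
#' @param mask,scale passed to [azimuthOverlay()].
#' @param col segment colour.
#' @param ... further arguments to [graphics::image()].
#' @return the overlay data.frame, invisibly.
#' @export
plotAzimuthOverlay <- function(maps, mask = NULL, scale = 2,
                               col = "white", ...) {
  ov <- azimuthOverlay(maps, mask, scale)
  m <- maps@ofMap
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m)[, nrow(m):1, drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "x (px)", ylab = "y (px)", useRaster = TRUE, ...)
  if (nrow(ov)) {
    n <- nrow(m)
    graphics::segments(ov$x0, n + 1 - ov$y0, ov$x1, n + 1 - ov$y1,
                       col = col)
  }
  invisible(ov)
}
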