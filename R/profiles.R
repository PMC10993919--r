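#' Bilinear sampling of a raster at fractional (row, col) positions
#'
#' @param m numeric matrix.
#' @param r,c numeric vectors of row/column coordinates (1-based; pixel
#'   centres at integers).
#' @return sampled values; NA outside the interpolation domain.
#' @keywords internal
.bilinear <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  out <- rep(NA_real_, length(r))
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  # points exactly on the last row/col edge
  edge <- r >= 1 & c >= 1 & r <= nr & c <= nc & !ok
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok])
    i10 <- cbind(r0[ok] + 1, c0[ok])
    i01 <- cbind(r0[ok], c0[ok] + 1)
    i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- (1 - fr[ok]) * (1 - fc[ok]) * m[i00] +
      fr[ok] * (1 - fc[ok]) * m[i10] +
      (1 - fr[ok]) * fc[ok] * m[i01] +
      fr[ok] * fc[ok] * m[i11]
  }
  if (any(edge)) {
    out[edge] <- m[cbind(pmin(pmax(round(r[edge]), 1), nr),
                         pmin(pmax(round(c[edge]), 1), nc))]
  }
  out
}

#' OF line scan along a border
#'
#' Samples the OF map along a band of parallel lines: the two anchor
#' points define the scan direction, and \code{nLines} lines offset along
#' the normal direction at \code{spacing}-pixel lateral steps (centred on
#' the anchor line) are each sampled at 1-pixel steps with bilinear
#' interpolation. Samples are kept only where the binary mask covers all
#' four interpolation neighbours; the profile is the per-position mean over
#' contributing lines.
#'
#' @param ofMap numeric OF raster.
#' @param mask logical matrix; samples outside it are discarded.
#' @param anchors 2 x 2 numeric matrix, rows = the two (row, col) anchor
#'   points.
#' @param nLines number of parallel lines (default 18).
#' @param spacing lateral spacing between lines in pixels (default 1).
#' @param step sampling step along the scan in pixels (default 1).
#' @return a data.frame with \code{position} (px from the first anchor),
#'   \code{meanOF} (NA where no line contributes) and \code{nContributing};
#'   a warning is raised if every sample is masked out.
#' @export
lineScan <- function(ofMap, mask, anchors, nLines = 18L, spacing = 1,
                     step = 1) {
  stopifnot(is.matrix(ofMap), identical(dim(mask), dim(ofMap)),
            is.matrix(anchors), all(dim(anchors) == c(2L, 2L)))
  p0 <- anchors[1L, ]; p1 <- anchors[2L, ]
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len == 0) stop("anchor points must be distinct")
  u <- d / len                 # along-scan unit vector (row, col)
  nvec <- c(-u[2L], u[1L])     # in-image normal
  positions <- seq(0, len, by = step)
  offsets <- (seq_len(nLines) - (nLines + 1) / 2) * spacing
  # conservative mask: all four bilinear neighbours must be inside the mask
  maskNum <- mask * 1
  acc <- matrix(NA_real_, length(positions), nLines)
  for (j in seq_len(nLines)) {
    pr <- p0[1L] + positions * u[1L] + offsets[j] * nvec[1L]
    pc <- p0[2L] + positions * u[2L] + offsets[j] * nvec[2L]
    mval <- .bilinear(maskNum, pr, pc)
    v <- .bilinear(ofMap, pr, pc)
    v[is.na(mval) | mval < 1] <- NA_real_
    acc[, j] <- v
  }
  nContributing <- rowSums(!is.na(acc))
  meanOF <- ifelse(nContributing > 0, rowMeans(acc, na.rm = TRUE),
                   NA_real_)
  if (all(nContributing == 0))
    warning("line scan: every sample fell outside the mask")
  data.frame(position = positions, meanOF = meanOF,
             nContributing = nContributing)
}

#' Pair border-flanking objects for the leading-edge comparison
#'
#' For borders between cells at a wound edge, the object closest to the
#' leading edge forms group A and the farthest forms group B. For borders
#' in confluent regions (no leading edge), objects are randomly split into
#' two groups A' and B' (seeded, reproducible) and each group is summarized
#' by its mean OF.
#'
#' @param objects data.frame with columns \code{centroidRow},
#'   \code{centroidCol}, \code{meanOF} and \code{borderId}.
#' @param leadingEdge either NULL (confluent mode) or a 2 x 2 matrix of two
#'   (row, col) points defining the leading-edge line.
#' @param seed integer seed for the confluent-mode random assignment.
#' @return a data.frame with one row per border: \code{borderId},
#'   \code{ofA}, \code{ofB}, \code{nA}, \code{nB}, \code{mode}. Borders
#'   with fewer than 2 objects are skipped with a message.
#' @export
pairBorderObjects <- function(objects, leadingEdge = NULL, seed = 1L) {
  stopifnot(all(c("centroidRow", "centroidCol", "meanOF", "borderId") %in%
                names(objects)))
  confluent <- is.null(leadingEdge)
  if (!confluent)
    stopifnot(is.matrix(leadingEdge), all(dim(leadingEdge) == c(2L, 2L)))
  rng <- NULL
  if (confluent) {
    # private RNG stream so callers' RNG state is untouched
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  res <- lapply(split(objects, objects$borderId), function(b) {
    if (nrow(b) < 2L) {
      message("border ", b$borderId[1L], " has < 2 objects; skipped")
      return(NULL)
    }
    if (confluent) {
      grp <- sample(rep(c("A", "B"), length.out = nrow(b)))
      data.frame(borderId = b$borderId[1L],
                 ofA = mean(b$meanOF[grp == "A"]),
                 ofB = mean(b$meanOF[grp == "B"]),
                 nA = sum(grp == "A"), nB = sum(grp == "B"),
                 mode = "confluent")
    } else {
      dist <- .pointLineDistance(b$centroidRow, b$centroidCol, leadingEdge)
      data.frame(borderId = b$borderId[1L],
                 ofA = b$meanOF[which.min(dist)],
                 ofB = b$meanOF[which.max(dist)],
                 nA = 1L, nB = 1L, mode = "leading-edge")
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(borderId = character(0), ofA = numeric(0),
                      ofB = numeric(0), nA = integer(0), nB = integer(0),
                      mode = character(0))
  rownames(out) <- NULL
  out
}

.pointLineDistance <- function(r, c, line) {
  p0 <- line[1L, ]; p1 <- line[2L, ]
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len == 0) stop("leading-edge points must be distinct")
  abs((r - p0[1L]) * d[2L] - (c - p0[2L]) * d[1L]) / len
}
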