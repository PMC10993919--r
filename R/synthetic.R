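#' Wrapped-normal second circular moment
#'
#' For dipole azimuths distributed as a wrapped normal with spread sigma,
#' the expectation of cos 2(phi - mu) is exp(-2 sigma^2) (sigma in
#' radians). This factor sets the polarization modulation depth of the
#' ensemble's cos-squared excitation response.
#'
#' @param sigmaDeg circular spread in degrees.
#' @return the second-moment resultant length c2 in [0, 1].
#' @export
wrappedNormalC2 <- function(sigmaDeg) {
  s <- sigmaDeg * pi / 180
  exp(-2 * s^2)
}

#' Expected four-channel response of a dipole ensemble
#'
#' Expected (unit-amplitude) signal under linear excitation at the four
#' polarizations: I(theta) = (1 + c2 * cos 2(theta - mu)) / 2, the mean of
#' cos^2(theta - phi) over a wrapped-normal dipole population with mean
#' azimuth mu and spread sigma.
#'
#' @param muDeg mean dipole azimuth in degrees.
#' @param sigmaDeg circular spread in degrees.
#' @param anglesDeg excitation polarization angles (default 0/45/90/135).
#' @return numeric vector of expected responses, one per angle.
#' @export
channelResponse <- function(muDeg, sigmaDeg,
                            anglesDeg = c(0, 45, 90, 135)) {
  c2 <- wrappedNormalC2(sigmaDeg)
  (1 + c2 * cos(2 * (anglesDeg - muDeg) * pi / 180)) / 2
}

#' Noiseless Order Factor and azimuth implied by the forward model
#'
#' Pushes the analytic four-channel response of a wrapped-normal dipole
#' ensemble through the same pixel-wise max normalization and OF/azimuth
#' equations the pipeline applies, yielding the ground-truth values a
#' noiseless measurement would return.
#'
#' @param muDeg mean dipole azimuth in degrees.
#' @param sigmaDeg circular spread in degrees.
#' @return a list with \code{of} and \code{azimuthDeg} (on (-90, 90]; NA
#'   when OF = 0).
#' @export
analyticOrientation <- function(muDeg, sigmaDeg) {
  resp <- channelResponse(muDeg, sigmaDeg)
  n <- resp / max(resp)
  A <- n[1L] - n[3L]
  B <- n[2L] - n[4L]
  of <- sqrt(A^2 + B^2)
  az <- if (of > 0) atan2(B, A) / 2 * 180 / pi else NA_real_
  list(of = of, azimuthDeg = az)
}

#' Radial vignetting field
#'
#' Smooth multiplicative illumination field: 1 at the image centre,
#' falling quadratically to 1 - depth at the most distant corner.
#'
#' @param imageSize integer(2): rows, cols.
#' @param depth relative attenuation at the corner, in [0, 1).
#' @return numeric matrix in (1 - depth, 1].
#' @export
vignetteField <- function(imageSize, depth) {
  nr <- imageSize[1L]; nc <- imageSize[2L]
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  r2 <- outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, `+`)
  1 - depth * r2 / max(r2)
}

#' Construct a SceneSpec
#'
#' @param puncta data.frame with columns \code{row}, \code{col},
#'   \code{diameter}, \code{amplitude}, \code{muDeg}, \code{sigmaDeg} (one
#'   row per punctum; may be empty).
#' @param imageSize integer(2): rows, cols.
#' @param backgroundLevel expected background photons per pixel per
#'   channel.
#' @param vignetteDepth corner attenuation of the flat field (0 = none).
#' @param psfSigma Gaussian PSF sigma in pixels (0 = no blur).
#' @param poissonNoise apply photon shot noise.
#' @param readNoiseSd Gaussian read noise sigma (photon-equivalents).
#' @param rngSeed integer seed; rendering is deterministic given the spec.
#' @return a validated [SceneSpec-class].
#' @export
sceneSpec <- function(puncta = emptyPuncta(), imageSize = c(256L, 256L),
                      backgroundLevel = 50, vignetteDepth = 0.2,
                      psfSigma = 1.2, poissonNoise = TRUE, readNoiseSd = 2,
                      rngSeed = 1L) {
  new("SceneSpec", imageSize = as.integer(imageSize),
      puncta = as.data.frame(puncta), backgroundLevel = backgroundLevel,
      vignetteDepth = vignetteDepth, psfSigma = psfSigma,
      poissonNoise = poissonNoise, readNoiseSd = readNoiseSd,
      rngSeed = as.integer(rngSeed))
}

#' @rdname sceneSpec
#' @export
emptyPuncta <- function() {
  data.frame(row = numeric(0), col = numeric(0), diameter = numeric(0),
             amplitude = numeric(0), muDeg = numeric(0),
             sigmaDeg = numeric(0))
}

# run code with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Render a synthetic polarization scene
#'
#' Forward-simulates a four-polarization excitation stack from a
#' [SceneSpec-class]: each punctum is a disk whose expected signal at
#' excitation angle theta is amplitude * (1 + c2 cos 2(theta - mu)) / 2
#' with c2 the wrapped-normal second moment of its dipole population; a
#' diffuse unpolarized background is added, the stack is multiplied by the
#' radial vignetting field, blurred with a Gaussian PSF, and finally
#' Poisson shot noise and Gaussian read noise are applied. Rendering is
#' deterministic given the spec (the seed is part of the spec) and leaves
#' the caller's RNG state untouched.
#'
#' @param spec a [SceneSpec-class].
#' @return a list with \code{stack} (the raw [PolarizationStack-class]),
#'   \code{flat} (the exact [FlatFieldStack-class] used, for round-trip
#'   correction), and \code{truth}: the puncta table augmented with the
#'   noiseless analytic \code{ofTrue}/\code{azimuthTrue}, plus
#'   \code{labelRaster} (integer punctum ids) and \code{vignette}.
#' @seealso [renderAssemblySeries()], [renderScratchScene()]
#' @export
renderScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  nr <- spec@imageSize[1L]; nc <- spec@imageSize[2L]
  p <- spec@puncta
  expected <- array(spec@backgroundLevel, dim = c(nr, nc, 4L))
  labelRaster <- matrix(0L, nr, nc)
  if (nrow(p)) {
    for (i in seq_len(nrow(p))) {
      rad <- p$diameter[i] / 2
      rr <- max(1L, floor(p$row[i] - rad)):min(nr, ceiling(p$row[i] + rad))
      cc <- max(1L, floor(p$col[i] - rad)):min(nc, ceiling(p$col[i] + rad))
      d2 <- outer((rr - p$row[i])^2, (cc - p$col[i])^2, `+`)
      disk <- d2 <= rad^2
      if (!any(disk)) next
      resp <- p$amplitude[i] * channelResponse(p$muDeg[i], p$sigmaDeg[i])
      for (k in 1:4) {
        sl <- expected[rr, cc, k]
        sl[disk] <- sl[disk] + resp[k]
        expected[rr, cc, k] <- sl
      }
      lab <- labelRaster[rr, cc]
      lab[disk] <- i
      labelRaster[rr, cc] <- lab
    }
  }
  vig <- vignetteField(spec@imageSize, spec@vignetteDepth)
  for (k in 1:4) expected[, , k] <- expected[, , k] * vig
  if (spec@psfSigma > 0) {
    for (k in 1:4) {
      bl <- EBImage::gblur(expected[, , k], sigma = spec@psfSigma)
      expected[, , k] <- EBImage::imageData(bl)
    }
  }
  imgs <- .withSeed(spec@rngSeed, {
    out <- expected
    if (spec@poissonNoise) {
      out[] <- stats::rpois(length(out), lambda = pmax(out, 0))
    }
    if (spec@readNoiseSd > 0) {
      out <- out + stats::rnorm(length(out), sd = spec@readNoiseSd)
    }
    pmax(out, 0)
  })
  truth <- p
  if (nrow(p)) {
    ao <- mapply(function(mu, sg) unlist(analyticOrientation(mu, sg)),
                 p$muDeg, p$sigmaDeg)
    truth$ofTrue <- ao["of", ]
    truth$azimuthTrue <- ao["azimuthDeg", ]
    truth$punctumId <- seq_len(nrow(p))
  } else {
    truth$ofTrue <- numeric(0)
    truth$azimuthTrue <- numeric(0)
    truth$punctumId <- integer(0)
  }
  flatImgs <- array(rep(vig, 4L), dim = c(nr, nc, 4L))
  flat <- new("FlatFieldStack", images = flatImgs / max(flatImgs),
              polAngles = c(0, 45, 90, 135), pixelSize = NA_real_,
              fieldId = "synthetic-flat", sourceCount = 1L)
  list(
    stack = PolarizationStack(imgs, fieldId = sprintf("sim%06d", spec@rngSeed)),
    flat = flat,
    truth = list(puncta = truth, labelRaster = labelRaster, vignette = vig)
  )
}

#' Simulate flat-field acquisition on an autofluorescent slide
#'
#' Renders raw slide stacks (uniform autofluorescence times the vignetting
#' field, with shot and read noise) for feeding [buildFlatField()], as in
#' the acquisition protocol where several slide stacks are averaged and
#' normalized.
#'
#' @param imageSize integer(2).
#' @param level expected slide photons per pixel per channel.
#' @param vignetteDepth corner attenuation.
#' @param n number of slide stacks.
#' @param rngSeed integer seed.
#' @return a list of \code{n} [PolarizationStack-class] objects.
#' @export
renderFlatSlideStacks <- function(imageSize = c(256L, 256L), level = 2000,
                                  vignetteDepth = 0.2, n = 3L,
                                  rngSeed = 1L) {
  vig <- vignetteField(as.integer(imageSize), vignetteDepth)
  .withSeed(rngSeed, lapply(seq_len(n), function(i) {
    imgs <- array(0, dim = c(dim(vig), 4L))
    for (k in 1:4) {
      lam <- level * vig
      imgs[, , k] <- stats::rpois(length(lam), lam) +
        pmax(stats::rnorm(length(lam), sd = 2), -level)
    }
    imgs <- pmax(imgs, 0)
    PolarizationStack(imgs, fieldId = sprintf("flat%02d", i))
  }))
}

# rejection-sample punctum centres with a minimum pairwise separation
.placePuncta <- function(n, imageSize, minSep = 12, margin = 10) {
  nr <- imageSize[1L]; nc <- imageSize[2L]
  pts <- matrix(NA_real_, n, 2L)
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < 20000L) {
    tries <- tries + 1L
    cand <- c(stats::runif(1, margin, nr - margin),
              stats::runif(1, margin, nc - margin))
    if (placed == 0L ||
        min((pts[seq_len(placed), 1L] - cand[1L])^2 +
            (pts[seq_len(placed), 2L] - cand[2L])^2) >= minSep^2) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  if (placed < n)
    stop("could not place ", n, " puncta at separation ", minSep)
  pts
}

#' Render an assembly time series
#'
#' Simulates the maturation readout: one or more fields per condition
#' label, each containing randomly placed puncta whose dipole circular
#' spread is drawn from the label's schedule entry (a single value, or a
#' mean with jitter). A gradual-maturation preset corresponds to a spread
#' schedule decreasing across labels; a constant preset keeps it fixed.
#'
#' @param schedule data.frame with columns \code{label} and
#'   \code{sigmaDeg} (per-label mean spread), optionally
#'   \code{sigmaJitter} (SD of per-punctum spread around the mean,
#'   truncated at 0); at least 2 rows.
#' @param nFieldsPerLabel fields rendered per label.
#' @param punctaPerField puncta per field.
#' @param imageSize,backgroundLevel,vignetteDepth,psfSigma,poissonNoise,readNoiseSd
#'   scene parameters, see [sceneSpec()].
#' @param amplitude expected punctum photons per pixel.
#' @param diameter punctum diameter in pixels.
#' @param rngSeed integer master seed; per-field seeds are derived from it.
#' @return a list with \code{fields} (each: \code{stack}, \code{flat},
#'   \code{truth}, \code{condition}, \code{fieldId}) and \code{manifest}
#'   (data.frame field_id, condition).
#' @export
renderAssemblySeries <- function(schedule, nFieldsPerLabel = 3L,
                                 punctaPerField = 40L,
                                 imageSize = c(256L, 256L),
                                 amplitude = 5000, diameter = 5,
                                 backgroundLevel = 50, vignetteDepth = 0.2,
                                 psfSigma = 1.2, poissonNoise = TRUE,
                                 readNoiseSd = 2, rngSeed = 1L) {
  schedule <- as.data.frame(schedule)
  stopifnot(all(c("label", "sigmaDeg") %in% names(schedule)),
            nrow(schedule) >= 1L)
  if (is.null(schedule$sigmaJitter)) schedule$sigmaJitter <- 0
  fields <- list()
  manifest <- NULL
  fieldNum <- 0L
  for (i in seq_len(nrow(schedule))) {
    for (f in seq_len(nFieldsPerLabel)) {
      fieldNum <- fieldNum + 1L
      seed <- (rngSeed * 1000L + fieldNum) %% .Machine$integer.max
      pk <- .withSeed(seed, {
        pts <- .placePuncta(punctaPerField, as.integer(imageSize))
        sg <- pmax(0, stats::rnorm(punctaPerField, schedule$sigmaDeg[i],
                                   schedule$sigmaJitter[i]))
        data.frame(row = pts[, 1L], col = pts[, 2L], diameter = diameter,
                   amplitude = amplitude,
                   muDeg = stats::runif(punctaPerField, -90, 90),
                   sigmaDeg = sg)
      })
      spec <- sceneSpec(pk, imageSize = imageSize,
                        backgroundLevel = backgroundLevel,
                        vignetteDepth = vignetteDepth, psfSigma = psfSigma,
                        poissonNoise = poissonNoise,
                        readNoiseSd = readNoiseSd, rngSeed = seed)
      sc <- renderScene(spec)
      id <- sprintf("%s_f%02d", schedule$label[i], f)
      sc$stack@fieldId <- id
      fields[[id]] <- list(stack = sc$stack, flat = sc$flat,
                           truth = sc$truth,
                           condition = schedule$label[i], fieldId = id)
      manifest <- rbind(manifest,
                        data.frame(field_id = id,
                                   condition = schedule$label[i]))
    }
  }
  list(fields = fields, manifest = manifest)
}

#' Render a scratch-wound scene
#'
#' Simulates cell borders receding from a straight leading edge (a
#' vertical line near the left image edge). Each border is a horizontal
#' row carrying one punctum close to the edge and one far from it; the
#' dipole spread of each punctum is \code{sigmaFun(distance)} where
#' distance is measured from the leading edge in pixels, so a decreasing
#' \code{sigmaFun} produces the maturity gradient and a constant one the
#' confluent control.
#'
#' @param sigmaFun function distance (px) -> circular spread (deg).
#' @param nBorders number of borders (rows).
#' @param distances numeric(2): near and far punctum distances from the
#'   edge in pixels.
#' @param edgeCol column of the leading edge.
#' @param borderSpacing vertical spacing between borders in pixels.
#' @param amplitude,diameter,backgroundLevel,vignetteDepth,psfSigma,poissonNoise,readNoiseSd
#'   scene parameters.
#' @param muJitterSd SD (deg) of per-punctum mean azimuth about the border
#'   normal (dipoles tend to align with the border normal, here the
#'   vertical image axis).
#' @param rngSeed integer seed.
#' @return a list with \code{stack}, \code{flat}, \code{truth} (as in
#'   [renderScene()], with \code{borderId} and \code{edgeGroup} = "A"
#'   near / "B" far added to the puncta table), \code{borders}
#'   (data.frame borderId, row), and \code{leadingEdge} (2 x 2 anchor
#'   matrix of the edge line).
#' @export
renderScratchScene <- function(sigmaFun, nBorders = 15L,
                               distances = c(30, 130), edgeCol = 16,
                               borderSpacing = 16L, amplitude = 5000,
                               diameter = 5, backgroundLevel = 50,
                               vignetteDepth = 0, psfSigma = 1.2,
                               poissonNoise = TRUE, readNoiseSd = 2,
                               muJitterSd = 10, rngSeed = 1L) {
  nr <- as.integer(nBorders * borderSpacing + 2L * borderSpacing)
  nc <- as.integer(edgeCol + max(distances) + 60L)
  rowsAt <- borderSpacing * seq_len(nBorders) + borderSpacing %/% 2L
  if (nBorders == 0L) {
    pk <- cbind(emptyPuncta(),
                data.frame(borderId = character(0),
                           edgeGroup = character(0)))
  } else pk <- .withSeed(rngSeed, {
    do.call(rbind, lapply(seq_len(nBorders), function(b) {
      data.frame(
        row = rowsAt[b],
        col = edgeCol + distances,
        diameter = diameter,
        amplitude = amplitude,
        # border normal is vertical (90 deg from +x), with jitter
        muDeg = 90 - abs(stats::rnorm(2L, 0, muJitterSd)),
        sigmaDeg = vapply(distances, sigmaFun, numeric(1)),
        borderId = sprintf("b%02d", b),
        edgeGroup = c("A", "B")
      )
    }))
  })
  spec <- sceneSpec(pk[, c("row", "col", "diameter", "amplitude", "muDeg",
                           "sigmaDeg")],
                    imageSize = c(nr, nc),
                    backgroundLevel = backgroundLevel,
                    vignetteDepth = vignetteDepth, psfSigma = psfSigma,
                    poissonNoise = poissonNoise, readNoiseSd = readNoiseSd,
                    rngSeed = rngSeed)
  sc <- renderScene(spec)
  sc$truth$puncta$borderId <- pk$borderId
  sc$truth$puncta$edgeGroup <- pk$edgeGroup
  list(stack = sc$stack, flat = sc$flat, truth = sc$truth,
       borders = data.frame(borderId = sprintf("b%02d", seq_len(nBorders)),
                            row = rowsAt),
       leadingEdge = matrix(c(1, edgeCol, nr, edgeCol), 2L, 2L,
                            byrow = TRUE))
}
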