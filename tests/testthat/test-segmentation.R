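test_that("constant images yield an empty mask with a warning", {
  expect_warning(m <- buildMask(matrix(7, 20, 20)), "no foreground")
  expect_false(any(maskRaster(m)))
})

test_that("a bright square on zero background is masked exactly", {
  img <- matrix(0, 16, 16)
  img[7:9, 7:9] <- 100
  m <- buildMask(img, tophatRadius = 3)
  # the 3x3 square cannot contain the radius-3 disk, so the top-hat
  # equals the original; Otsu on the two-valued histogram separates 0/100
  expect_identical(maskRaster(m), img > 0)
  expect_true(m@thresholdValue > 0 && m@thresholdValue < 100)
})

test_that("Otsu threshold equals exhaustive between-class-variance maximization", {
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        globalenv()))
  set.seed(21)
  # bimodal image: background ~50 with a mild gradient, foreground ~200
  img <- matrix(50, 40, 40) + outer(seq(0, 5, length.out = 40),
                                    seq(0, 5, length.out = 40), "+")
  img[10:14, 8:12] <- 200 + rnorm(25, sd = 3)
  img[25:29, 30:34] <- 200 + rnorm(25, sd = 3)
  thr <- otsuThreshold(img)
  expect_equal(thr, otsuExhaustive(img), tolerance = 1e-12)
  expect_gt(thr, 60)
  expect_lt(thr, 200)
  # random image: the vectorized search agrees with the exhaustive loop
  rndImg <- matrix(runif(900, 0, 10), 30, 30)
  expect_equal(otsuThreshold(rndImg), otsuExhaustive(rndImg),
               tolerance = 1e-12)
  expect_warning(otsuThreshold(matrix(3, 5, 5)), "constant")
})

test_that("labeling uses 4-connectivity with deterministic label order", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE # diagonal touch: 2 objects
  lab <- labelObjects(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[2, 2], 1L) # row-major first pixel gets label 1
  expect_equal(lab[3, 3], 2L)

  plus <- matrix(FALSE, 7, 7)
  plus[4, 3:5] <- TRUE; plus[3:5, 4] <- TRUE
  labP <- labelObjects(plus)
  expect_equal(max(labP), 1L)
  expect_equal(sum(labP == 1L), 5L)

  expect_equal(max(labelObjects(matrix(FALSE, 4, 4))), 0L)
})

test_that("component labeling matches a flood-fill oracle on random masks", {
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        globalenv()))
  for (seed in 1:3) {
    set.seed(seed + 300)
    m <- matrix(runif(400) < 0.4, 20, 20)
    lab <- labelObjects(m)
    oracle <- floodFillLabels(m)
    expect_equal(max(lab), max(oracle))
    # identical partition: labels agree up to renaming
    expect_equal(length(unique(paste(lab[m], oracle[m]))), max(oracle))
  }
})

test_that("object OF is the mean over member pixels with defined orientation", {
  ns <- uniformAlignedNormalized(10, 10)
  maps <- computeOrientationMaps(ns)
  # hand-build OF values on two member pixels
  maps@ofMap[2, 2] <- 0.2
  maps@ofMap[2, 3] <- 0.4
  labels <- matrix(0L, 10, 10)
  labels[2, 2:3] <- 1L
  avg <- matrix(1, 10, 10)
  st <- objectStats(labels, maps, avg)
  expect_equal(st$meanOF, 0.3)
  expect_equal(st$nPixels, 2L)
  expect_equal(st$centroidRow, 2)
  expect_equal(st$centroidCol, 2.5)

  # uniform OF field: every object inherits the field value
  maps2 <- computeOrientationMaps(ns)
  labels2 <- matrix(0L, 10, 10)
  labels2[2, 2:4] <- 1L; labels2[7:8, 7] <- 2L
  st2 <- objectStats(labels2, maps2, avg)
  expect_equal(st2$meanOF, c(1, 1))
})

test_that("invalid pixels are excluded; objects need 2 defined azimuths", {
  imgs <- array(0, c(8, 8, 4))
  imgs[, , 1] <- 1; imgs[, , 2] <- 0.5; imgs[, , 4] <- 0.5
  imgs[3, 4, ] <- 1 # isotropic pixel: OF 0, azimuth undefined
  maps <- computeOrientationMaps(asNormalized(imgs))
  labels <- matrix(0L, 8, 8)
  labels[3, 3:5] <- 1L
  st <- objectStats(labels, maps, matrix(1, 8, 8))
  expect_equal(st$nAzimuth, 2L)
  expect_equal(st$meanOF, 1) # the OF-0 pixel does not drag the mean down
  # single defined azimuth: disorder undefined, object not retained
  labels2 <- matrix(0L, 8, 8)
  labels2[3, 4:5] <- 2L
  st2 <- objectStats(labels2, maps, matrix(1, 8, 8))
  expect_true(is.na(st2$azimuthCSD))
  expect_false(st2$retained)
})

test_that("buffer and ring geometry match a city-block distance oracle", {
  labels <- matrix(0L, 21, 21)
  labels[10, 10] <- 1L
  avg <- matrix(1, 21, 21)
  sb <- signalToBackground(labels, 1L, avg, dilationMetric = "cityblock")
  d1 <- abs(row(labels) - 10) + abs(col(labels) - 10)
  expect_identical(sb$buffer, d1 >= 1 & d1 <= 3)
  expect_identical(sb$ring, d1 >= 4 & d1 <= 5)

  sbC <- signalToBackground(labels, 1L, avg, dilationMetric = "chebyshev")
  dI <- pmax(abs(row(labels) - 10), abs(col(labels) - 10))
  expect_identical(sbC$buffer, dI >= 1 & dI <= 3)
  expect_identical(sbC$ring, dI >= 4 & dI <= 5)
})

test_that("ring pixels near other objects are excluded from background", {
  labels <- matrix(0L, 30, 30)
  labels[15, 10] <- 1L
  labels[15, 15] <- 2L # neighbor 5 px away: its buffer overlaps the ring
  avg <- matrix(10, 30, 30)
  avg[15, 15] <- 1000
  sb <- signalToBackground(labels, 1L, avg)
  expect_false(any(sb$ring & labels == 2L))
  # neighbor's 3-dilation zone is excluded, so the bright neighbor never
  # contaminates the background mean
  expect_equal(sb$backgroundMean, 10)
})

test_that("the S/B exclusion boundary is exact and strict", {
  mkScene <- function(objVal) {
    labels <- matrix(0L, 30, 30)
    labels[14:16, 14:16] <- 1L
    avg <- matrix(10, 30, 30)
    avg[labels == 1L] <- objVal
    ns <- uniformAlignedNormalized(30, 30)
    maps <- computeOrientationMaps(ns)
    objectStats(labels, maps, avg)
  }
  atBoundary <- mkScene(30)    # S/B = 3.0 exactly
  below <- mkScene(29.9)       # S/B = 2.99
  expect_equal(atBoundary$sbRatio, 3)
  expect_true(atBoundary$retained)
  expect_false(below$retained)
  expect_equal(suppressMessages(nrow(filterObjects(below))), 0L)
  expect_equal(suppressMessages(nrow(filterObjects(atBoundary))), 1L)
  # crossing the boundary flips retention and nothing else
  expect_equal(atBoundary[c("nPixels", "centroidRow", "centroidCol",
                            "meanOF", "azimuthCSD")],
               below[c("nPixels", "centroidRow", "centroidCol",
                       "meanOF", "azimuthCSD")])
})

test_that("filterObjects applies the strict S/B rule to a mixed table", {
  tb <- data.frame(objectId = 1:3, sbRatio = c(2.5, 3.0, 8.1),
                   meanOF = 0.3, azimuthCSD = 5)
  kept <- suppressMessages(filterObjects(tb))
  expect_equal(kept$objectId, c(2L, 3L))
  empty <- tb[0, ]
  expect_equal(nrow(suppressMessages(filterObjects(empty))), 0L)
})

test_that("segmentation recovers bright puncta and rejects dim ones", {
  # 10 bright puncta (S/B ~ 10+) and 5 dim ones (S/B ~ 1.5)
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        globalenv()))
  set.seed(77)
  pts <- expand.grid(row = c(20, 50, 80, 110, 140), col = c(40, 100, 160))
  bright <- data.frame(row = pts$row[1:10], col = pts$col[1:10],
                       diameter = 5, amplitude = 2000, muDeg = 30,
                       sigmaDeg = 10)
  dim5 <- data.frame(row = pts$row[11:15], col = pts$col[11:15],
                     diameter = 5, amplitude = 50, muDeg = 30,
                     sigmaDeg = 10)
  spec <- sceneSpec(rbind(bright, dim5), imageSize = c(160L, 200L),
                    backgroundLevel = 50, vignetteDepth = 0,
                    psfSigma = 1.0, rngSeed = 13L)
  sc <- renderScene(spec)
  res <- suppressMessages(analyzeField(sc$stack, minSb = 3))
  matched <- matchObjects(sc$truth$puncta, res$retained, maxDist = 4)
  expect_equal(sum(!is.na(matched$objectId[1:10])), 10L)
  expect_equal(sum(!is.na(matched$objectId[11:15])), 0L)
})

test_that("object metrics are invariant to labeling permutations", {
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        globalenv()))
  set.seed(5)
  ns <- normalizeStack(randomStack(40L, 40L, seed = 15L))
  maps <- computeOrientationMaps(ns)
  avg <- matrix(runif(1600, 5, 10), 40, 40)
  labels <- matrix(0L, 40, 40)
  labels[5:8, 5:8] <- 1L; labels[20:22, 25:28] <- 2L; labels[33, 10:14] <- 3L
  st <- objectStats(labels, maps, avg)
  # permute ids: 1->3, 2->1, 3->2
  perm <- labels
  perm[labels == 1L] <- 3L; perm[labels == 2L] <- 1L; perm[labels == 3L] <- 2L
  stP <- objectStats(perm, maps, avg)
  for (id in 1:3) {
    newId <- c(3L, 1L, 2L)[id]
    expect_equal(st$meanOF[st$objectId == id],
                 stP$meanOF[stP$objectId == newId])
    expect_equal(st$azimuthCSD[st$objectId == id],
                 stP$azimuthCSD[stP$objectId == newId])
    expect_equal(st$sbRatio[st$objectId == id],
                 stP$sbRatio[stP$objectId == newId])
  }
})
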