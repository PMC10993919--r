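# shared fixtures and independent oracles, built in code at test time

# evaluate expr under a fixed seed, restoring the caller's RNG state
.withSeedHelper <- function(seed, expr) {
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        globalenv()))
  set.seed(seed)
  force(expr)
}

# a random four-polarization stack with positive intensities
randomStack <- function(nr = 32L, nc = 32L, seed = 1L, maxVal = 100) {
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        globalenv()))
  set.seed(seed)
  PolarizationStack(array(runif(nr * nc * 4L, 0, maxVal),
                          dim = c(nr, nc, 4L)),
                    fieldId = sprintf("rand%03d", seed))
}

# wrap a plain array as a NormalizedStack without going through the
# pipeline (channels must already be max-normalized per pixel)
asNormalized <- function(imgs) {
  mx <- apply(imgs, c(1, 2), max) # keeps matrix shape for 1-row images
  new("NormalizedStack", images = imgs, polAngles = c(0, 45, 90, 135),
      pixelSize = NA_real_, fieldId = "", validMask = mx > 0)
}

# uniform normalized stack: dipoles aligned with the x-axis at every pixel
uniformAlignedNormalized <- function(nr, nc) {
  imgs <- array(0, c(nr, nc, 4L))
  imgs[, , 1L] <- 1
  imgs[, , 2L] <- 0.5
  imgs[, , 4L] <- 0.5
  asNormalized(imgs)
}

# independent flood-fill labeling oracle (4-connectivity), breadth-first
floodFillLabels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] && lab[r, c] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r, c))
      lab[r, c] <- cur
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          q <- p + d
          if (q[1L] >= 1L && q[1L] <= nr && q[2L] >= 1L && q[2L] <= nc &&
              mask[q[1L], q[2L]] && lab[q[1L], q[2L]] == 0L) {
            lab[q[1L], q[2L]] <- cur
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  lab
}

# exhaustive Otsu oracle: loop over every bin-boundary cut, computing the
# between-class variance from the binned histogram step by step
otsuExhaustive <- function(x, nbins = 256L) {
  v <- as.vector(x)
  rng <- range(v)
  width <- (rng[2L] - rng[1L]) / nbins
  idx <- pmin(nbins, 1L + floor((v - rng[1L]) / width))
  counts <- tabulate(idx, nbins)
  mids <- rng[1L] + (seq_len(nbins) - 0.5) * width
  best <- -Inf; bestK <- NA_integer_
  for (k in seq_len(nbins - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1L):nbins] * mids[(k + 1L):nbins]) / n1
    bcv <- n0 * n1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; bestK <- k }
  }
  rng[1L] + bestK * width
}

# scalar-loop orientation oracle: per-pixel equations, no vectorization
orientationLoopOracle <- function(normalized) {
  imgs <- normalized@images
  valid <- normalized@validMask
  nr <- dim(imgs)[1L]; nc <- dim(imgs)[2L]
  of <- matrix(0, nr, nc)
  az <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!valid[r, c]) next
    A <- imgs[r, c, 1L] - imgs[r, c, 3L]
    B <- imgs[r, c, 2L] - imgs[r, c, 4L]
    o <- sqrt(A * A + B * B)
    of[r, c] <- o
    if (o > 0) az[r, c] <- atan2(B, A) / 2 * 180 / pi
  }
  list(of = of, az = az)
}

# scalar-loop axial circular SD oracle over doubled angles
circularSDLoopOracle <- function(azimuthDeg) {
  a <- azimuthDeg[!is.na(azimuthDeg)]
  sr <- 0; si <- 0
  for (x in a) {
    sr <- sr + cos(2 * x * pi / 180)
    si <- si + sin(2 * x * pi / 180)
  }
  R <- sqrt((sr / length(a))^2 + (si / length(a))^2)
  sqrt(-2 * log(min(R, 1))) / 2 * 180 / pi
}

# sample axial angles from a wrapped normal, reported on (-90, 90]
rWrappedAxial <- function(n, muDeg, sigmaDeg) {
  a <- rnorm(n, muDeg, sigmaDeg) %% 180
  ifelse(a > 90, a - 180, a)
}
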