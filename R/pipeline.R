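#' Run the full per-field analysis
#'
#' Convenience wrapper chaining the pipeline stages on one field:
#' flat-field correction (optional), pixel-wise max normalization,
#' orientation maps, average-intensity image, top-hat/Otsu mask,
#' 4-connected labeling and object-level metrics with the S/B filter.
#'
#' @param raw a [PolarizationStack-class].
#' @param flat a [FlatFieldStack-class], or NULL to skip correction.
#' @param minSb signal-to-background retention threshold (default 3).
#' @param tophatRadius structuring-element radius for the mask (default 3).
#' @return a list with \code{corrected}, \code{normalized}, \code{maps},
#'   \code{avg}, \code{mask}, \code{labels}, \code{objects} (all objects,
#'   with the \code{retained} flag) and \code{retained} (the filtered
#'   table).
#' @export
analyzeField <- function(raw, flat = NULL, minSb = 3, tophatRadius = 3) {
  corrected <- if (is.null(flat)) {
    new("CorrectedStack", images = raw@images,
        polAngles = c(0, 45, 90, 135), pixelSize = raw@pixelSize,
        fieldId = raw@fieldId, provenance = c(field = raw@fieldId,
                                              flat = "none"))
  } else {
    flatFieldCorrect(raw, flat)
  }
  normalized <- normalizeStack(corrected)
  maps <- computeOrientationMaps(normalized)
  avg <- averageIntensity(corrected)
  mask <- buildMask(avg, tophatRadius = tophatRadius)
  labels <- labelObjects(mask)
  objects <- objectStats(labels, maps, avg, minSb = minSb)
  retained <- objects[objects$retained, , drop = FALSE]
  list(corrected = corrected, normalized = normalized, maps = maps,
       avg = avg, mask = mask, labels = labels, objects = objects,
       retained = retained)
}

#' Analyze a simulated dataset into a grouped object table
#'
#' Runs [analyzeField()] on every field of a dataset from
#' [renderAssemblySeries()] and stacks the retained objects into one table
#' labeled by condition — the input expected by [compareTimepoints()].
#'
#' @param dataset list with \code{fields} as returned by
#'   [renderAssemblySeries()].
#' @param useFlat correct each field with its simulation flat field.
#' @param minSb S/B retention threshold.
#' @return a data.frame of retained objects with a \code{condition}
#'   column.
#' @export
analyzeDataset <- function(dataset, useFlat = TRUE, minSb = 3) {
  tabs <- lapply(dataset$fields, function(fd) {
    res <- analyzeField(fd$stack, flat = if (useFlat) fd$flat else NULL,
                        minSb = minSb)
    tb <- res$retained
    if (nrow(tb)) tb$condition <- fd$condition
    tb
  })
  tabs <- tabs[vapply(tabs, nrow, integer(1)) > 0]
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Match recovered objects to ground-truth puncta
#'
#' Greedy nearest-centroid matching between the simulator's puncta and the
#' segmentation's objects, used to score punctum recovery on synthetic
#' scenes.
#'
#' @param truthPuncta ground-truth puncta table (columns \code{row},
#'   \code{col}, \code{punctumId}).
#' @param objects object table from [objectStats()].
#' @param maxDist maximum centre-to-centroid distance in pixels.
#' @return \code{truthPuncta} with an \code{objectId} column (NA where no
#'   object matched).
#' @export
matchObjects <- function(truthPuncta, objects, maxDist = 5) {
  truthPuncta$objectId <- NA_integer_
  if (!nrow(objects) || !nrow(truthPuncta)) return(truthPuncta)
  free <- rep(TRUE, nrow(objects))
  for (i in seq_len(nrow(truthPuncta))) {
    d <- sqrt((objects$centroidRow - truthPuncta$row[i])^2 +
              (objects$centroidCol - truthPuncta$col[i])^2)
    d[!free] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= maxDist) {
      truthPuncta$objectId[i] <- objects$objectId[j]
      free[j] <- FALSE
    }
  }
  truthPuncta
}

#' Assign objects to the nearest simulated border
#'
#' Labels each object with the border whose row is closest to the object
#' centroid, for feeding [pairBorderObjects()] on scratch-wound scenes.
#'
#' @param objects object table from [objectStats()].
#' @param borders data.frame with \code{borderId} and \code{row}.
#' @param maxDist maximum |centroid row - border row| in pixels.
#' @return \code{objects} with a \code{borderId} column; unassigned
#'   objects are dropped.
#' @export
assignObjectsToBorders <- function(objects, borders, maxDist = 6) {
  if (!nrow(objects)) {
    objects$borderId <- character(0)
    return(objects)
  }
  idx <- vapply(objects$centroidRow, function(r) {
    j <- which.min(abs(borders$row - r))
    if (abs(borders$row[j] - r) <= maxDist) j else NA_integer_
  }, integer(1))
  objects$borderId <- borders$borderId[idx]
  objects[!is.na(objects$borderId), , drop = FALSE]
}
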