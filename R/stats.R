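#' Neighbor-and-control comparison set
#'
#' The study design compares each timepoint only to its neighbouring
#' timepoints and to the control group; p-value adjustment is then applied
#' over exactly this restricted set, not over all pairs.
#'
#' @param levels character vector of group labels in temporal order,
#'   excluding the control.
#' @param control label of the control group (omit with NULL).
#' @return a 2-column character matrix of comparisons.
#' @export
neighborControlComparisons <- function(levels, control = "no-pulse") {
  cmp <- NULL
  if (length(levels) >= 2L)
    cmp <- cbind(levels[-length(levels)], levels[-1L])
  if (!is.null(control))
    cmp <- rbind(cmp, cbind(levels, control))
  cmp <- unique(cmp)
  cmp[cmp[, 1L] != cmp[, 2L], , drop = FALSE]
}

# Dunn's post hoc z statistics on the pooled midranks, with the standard
# tie correction; p adjusted by Bonferroni over the comparisons made.
.dunn <- function(values, groups, comparisons) {
  N <- length(values)
  rk <- rank(values) # midranks
  meanRank <- tapply(rk, groups, mean)
  n <- tapply(rk, groups, length)
  ties <- table(rk)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tieCorr
  m <- nrow(comparisons)
  z <- p <- numeric(m)
  for (i in seq_len(m)) {
    g1 <- comparisons[i, 1L]; g2 <- comparisons[i, 2L]
    se <- sqrt(sigma2 * (1 / n[[g1]] + 1 / n[[g2]]))
    z[i] <- (meanRank[[g1]] - meanRank[[g2]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(group1 = comparisons[, 1L], group2 = comparisons[, 2L],
             z = z, p = p, pAdjusted = pmin(1, p * m))
}

#' Compare an object metric across timepoints
#'
#' Omnibus Kruskal-Wallis test on the chosen object metric across
#' condition groups, followed by Dunn's pairwise comparisons restricted to
#' the neighbor-and-control set, with Bonferroni adjustment over the
#' comparisons actually made. Group medians and interquartile ranges are
#' reported alongside.
#'
#' @param objects data.frame of retained objects with a \code{condition}
#'   column and the metric column.
#' @param metric column to compare, \code{"meanOF"} or \code{"azimuthCSD"}.
#' @param levels condition labels in temporal order (excluding the
#'   control); defaults to the order of first appearance.
#' @param control control condition label, or NULL for no control group.
#' @return a list with \code{H}, \code{df}, \code{p} (omnibus),
#'   \code{pairwise} (Dunn table), and \code{summary} (median, IQR, n per
#'   group).
#' @export
compareTimepoints <- function(objects, metric = c("meanOF", "azimuthCSD"),
                              levels = NULL, control = "no-pulse") {
  metric <- match.arg(metric)
  stopifnot("condition" %in% names(objects), metric %in% names(objects))
  x <- objects[[metric]]
  g <- as.character(objects$condition)
  keep <- !is.na(x) & is.finite(x)
  x <- x[keep]; g <- g[keep]
  counts <- table(g)
  if (any(counts < 2L))
    stop("group(s) with < 2 observations: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  if (is.null(levels)) levels <- setdiff(unique(g), control)
  present <- unique(g)
  if (!all(levels %in% present))
    stop("empty group(s): ", paste(setdiff(levels, present), collapse = ", "))
  if (!is.null(control) && !(control %in% present))
    stop("empty group(s): ", control)
  kw <- stats::kruskal.test(x, factor(g))
  cmp <- neighborControlComparisons(levels, control)
  pair <- .dunn(x, g, cmp)
  summ <- do.call(rbind, lapply(split(x, g), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(median = q[2L], q25 = q[1L], q75 = q[3L], n = length(v))
  }))
  summ$condition <- rownames(summ)
  rownames(summ) <- NULL
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = pair,
       summary = summ[, c("condition", "median", "q25", "q75", "n")])
}

#' Compare fragment counts across timepoints
#'
#' Ordinary one-way ANOVA on fragmentation counts (technical replicates
#' pooled across experiments), followed by Sidak-adjusted pairwise
#' comparisons over the neighbor-and-control set. Pairwise t statistics
#' use the pooled residual variance from the ANOVA.
#'
#' @param counts data.frame with columns \code{timepoint} and
#'   \code{nFragments}.
#' @param levels timepoint labels in temporal order (excluding the
#'   control); defaults to first appearance.
#' @param control control label, or NULL.
#' @return a list with \code{F}, \code{df}, \code{p}, \code{pairwise}
#'   (with Sidak-adjusted p), and \code{summary} (mean, sd, n). For
#'   degenerate input with zero residual variance, \code{F} is NA and
#'   \code{degenerate} is TRUE.
#' @export
compareFragmentCounts <- function(counts, levels = NULL,
                                  control = "no-pulse") {
  stopifnot(all(c("timepoint", "nFragments") %in% names(counts)))
  x <- counts$nFragments
  g <- as.character(counts$timepoint)
  stopifnot(is.numeric(x), all(is.finite(x)))
  nPer <- table(g)
  if (any(nPer < 2L))
    stop("group(s) with a single observation: ",
         paste(names(nPer)[nPer < 2L], collapse = ", "))
  if (is.null(levels)) levels <- setdiff(unique(g), control)
  summ <- do.call(rbind, lapply(split(x, g), function(v) {
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))
  }))
  summ$timepoint <- rownames(summ)
  rownames(summ) <- NULL
  withinConst <- all(vapply(split(x, g),
                            function(v) max(v) == min(v), logical(1)))
  if (withinConst) {
    warning("zero residual variance: ANOVA F is undefined")
    return(list(F = NA_real_,
                df = c(length(unique(g)) - 1L, length(x) - length(unique(g))),
                p = NA_real_, pairwise = NULL, degenerate = TRUE,
                summary = summ[, c("timepoint", "mean", "sd", "n")]))
  }
  fit <- stats::aov(x ~ factor(g))
  an <- stats::anova(fit)
  mse <- an[["Mean Sq"]][2L]
  dfRes <- an$Df[2L]
  cmp <- neighborControlComparisons(levels, control)
  m <- nrow(cmp)
  means <- tapply(x, g, mean)
  ns <- tapply(x, g, length)
  tv <- pv <- numeric(m)
  for (i in seq_len(m)) {
    g1 <- cmp[i, 1L]; g2 <- cmp[i, 2L]
    se <- sqrt(mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
    tv[i] <- (means[[g1]] - means[[g2]]) / se
    pv[i] <- 2 * stats::pt(-abs(tv[i]), dfRes)
  }
  pair <- data.frame(group1 = cmp[, 1L], group2 = cmp[, 2L], t = tv,
                     p = pv, pAdjusted = 1 - (1 - pv)^m)
  list(F = an$F[1L], df = c(an$Df[1L], dfRes), p = an$`Pr(>F)`[1L],
       pairwise = pair, degenerate = FALSE,
       summary = summ[, c("timepoint", "mean", "sd", "n")])
}

#' Paired comparison of border-flanking objects
#'
#' Two-sided paired t-test of the OF of objects nearest versus farthest
#' from the leading edge (or of the random A'/B' groups in confluent
#' regions). Incomplete pairs are excluded with a message; zero-variance
#' differences are flagged as degenerate rather than reported as an
#' infinite t.
#'
#' @param pairs data.frame with columns \code{ofA} and \code{ofB} (one row
#'   per border), e.g. from [pairBorderObjects()].
#' @return a list with \code{t}, \code{df}, \code{p}, \code{meanDiff}
#'   (B - A), \code{sdDiff}, \code{n}, \code{degenerate}.
#' @export
pairedBorderTest <- function(pairs) {
  stopifnot(all(c("ofA", "ofB") %in% names(pairs)))
  ok <- !is.na(pairs$ofA) & !is.na(pairs$ofB)
  if (any(!ok))
    message(sum(!ok), " incomplete pair(s) excluded")
  a <- pairs$ofA[ok]; b <- pairs$ofB[ok]
  if (length(a) < 2L) stop("need at least 2 complete pairs")
  d <- b - a
  if (stats::sd(d) == 0) {
    warning("all paired differences are identical; t is undefined")
    return(list(t = if (all(d == 0)) 0 else NA_real_,
                df = length(d) - 1L,
                p = if (all(d == 0)) 1 else NA_real_,
                meanDiff = mean(d), sdDiff = 0, n = length(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(b, a, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanDiff = mean(d), sdDiff = stats::sd(d),
       n = length(d), degenerate = FALSE)
}
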