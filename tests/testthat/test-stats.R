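test_that("the comparison set covers neighbors and the control only", {
  cmp <- neighborControlComparisons(c("2h", "4h", "6h", "8h"), "no-pulse")
  pairsStr <- apply(cmp, 1, paste, collapse = "|")
  expect_setequal(pairsStr,
                  c("2h|4h", "4h|6h", "6h|8h", "2h|no-pulse",
                    "4h|no-pulse", "6h|no-pulse", "8h|no-pulse"))
  expect_equal(nrow(neighborControlComparisons(c("a", "b"), NULL)), 1L)
})

test_that("Kruskal-Wallis H matches the hand-computed rank statistic", {
  # groups {1,2,3}, {101,102,103}, {201,202,203}: all ranks distinct,
  # rank sums 6/15/24 => H = 12/(9*10) * (36+225+576)/3 - 3*10 = 7.2
  tb <- data.frame(condition = rep(c("g1", "g2", "g3"), each = 3),
                   meanOF = c(1, 2, 3, 101, 102, 103, 201, 202, 203))
  res <- compareTimepoints(tb, "meanOF", levels = c("g1", "g2", "g3"),
                           control = NULL)
  expect_equal(res$H, 7.2, tolerance = 1e-10)
  # identical groups: H = 0, p = 1
  same <- data.frame(condition = rep(c("a", "b"), each = 3),
                     meanOF = c(1, 2, 3, 1, 2, 3))
  res0 <- compareTimepoints(same, "meanOF", levels = c("a", "b"),
                            control = NULL)
  expect_equal(res0$H, 0)
  expect_equal(res0$p, 1)
})

test_that("Dunn z matches a direct mean-rank computation with tie correction", {
  x <- c(1, 2, 2, 4, 5, 7, 7, 7, 10, 12, 15, 18)
  g <- rep(c("A", "B", "C"), each = 4)
  tb <- data.frame(condition = g, meanOF = x)
  res <- compareTimepoints(tb, "meanOF", levels = c("A", "B", "C"),
                           control = NULL)
  # oracle: explicit midranks and the standard tie correction
  rk <- rank(x)
  mr <- tapply(rk, g, mean)
  ties <- table(rk)
  sigma2 <- 12 * 13 / 12 - sum(ties^3 - ties) / (12 * 11)
  zAB <- (mr[["A"]] - mr[["B"]]) / sqrt(sigma2 * (1 / 4 + 1 / 4))
  row <- res$pairwise[res$pairwise$group1 == "A" &
                      res$pairwise$group2 == "B", ]
  expect_equal(row$z, zAB, tolerance = 1e-12)
  expect_equal(row$pAdjusted, min(1, row$p * nrow(res$pairwise)))
})

test_that("Dunn adjustment never shrinks p, and restricting never inflates it", {
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        globalenv()))
  set.seed(6)
  tb <- data.frame(
    condition = rep(c("2h", "4h", "6h", "8h", "no-pulse"), each = 8),
    meanOF = rnorm(40, rep(c(0.22, 0.26, 0.30, 0.31, 0.32), each = 8),
                   0.06))
  res <- compareTimepoints(tb, "meanOF", levels = c("2h", "4h", "6h", "8h"))
  expect_true(all(res$pairwise$pAdjusted >= res$pairwise$p))
  # all-pairs adjustment uses a larger multiplier (10 vs 7), so for any
  # retained comparison the restricted-set adjusted p cannot exceed it
  mAll <- choose(5, 2)
  expect_true(all(res$pairwise$pAdjusted <=
                    pmin(1, res$pairwise$p * mAll) + 1e-12))
})

test_that("empty or undersized groups are rejected by name", {
  tb <- data.frame(condition = c("a", "a", "b"), meanOF = c(1, 2, 3))
  expect_error(compareTimepoints(tb, "meanOF", levels = c("a", "b"),
                                 control = NULL), "< 2 observations")
  tb2 <- data.frame(condition = rep(c("a", "b"), each = 3),
                    meanOF = rnorm(6))
  expect_error(compareTimepoints(tb2, "meanOF", levels = c("a", "b", "c"),
                                 control = NULL), "c")
})

test_that("one-way ANOVA F matches the hand computation", {
  # {1,2,3} vs {4,5,6}: SSB = 13.5 (df 1), SSW = 4 (df 4) => F = 13.5
  counts <- data.frame(timepoint = rep(c("a", "b"), each = 3),
                       nFragments = c(1, 2, 3, 4, 5, 6))
  res <- compareFragmentCounts(counts, levels = c("a", "b"),
                               control = NULL)
  expect_equal(res$F, 13.5, tolerance = 1e-10)
  expect_equal(res$pairwise$pAdjusted,
               1 - (1 - res$pairwise$p)^nrow(res$pairwise))

  flat <- data.frame(timepoint = rep(c("a", "b"), each = 3),
                     nFragments = rep(5, 6))
  expect_warning(r0 <- compareFragmentCounts(flat, levels = c("a", "b"),
                                             control = NULL),
                 "zero residual variance")
  expect_true(r0$degenerate)
  single <- data.frame(timepoint = c("a", "a", "b"),
                       nFragments = c(1, 2, 3))
  expect_error(compareFragmentCounts(single, control = NULL),
               "single observation")
})

test_that("counts drawn at the published scale give a powered omnibus ANOVA", {
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        globalenv()))
  set.seed(140)
  groupMeans <- c("2h" = 88.1, "4h" = 57.7, "6h" = 41.1, "8h" = 25.8,
                  "no-pulse" = 8.8)
  groupSds <- c(24.5, 17.6, 31.8, 14.1, 6.6)
  sig <- 0L
  for (r in 1:200) {
    counts <- data.frame(
      timepoint = rep(names(groupMeans), each = 9L),
      nFragments = pmax(0, rnorm(45, rep(groupMeans, each = 9L),
                                 rep(groupSds, each = 9L))))
    res <- compareFragmentCounts(counts, levels = c("2h", "4h", "6h", "8h"))
    if (res$p < 0.05) sig <- sig + 1L
  }
  expect_gte(sig / 200, 0.95)
})

test_that("paired t-test matches hand computation and handles degeneracy", {
  # diffs 0.2/0.3/0.1/0.2: mean 0.2, sd sqrt(0.02/3), t = 0.2/(sd/2)
  pairs <- data.frame(ofA = c(0.1, 0.2, 0.3, 0.25),
                      ofB = c(0.3, 0.5, 0.4, 0.45))
  res <- pairedBorderTest(pairs)
  sdHand <- sqrt(sum((c(0.2, 0.3, 0.1, 0.2) - 0.2)^2) / 3)
  tHand <- 0.2 / (sdHand / sqrt(4))
  expect_equal(res$t, tHand, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(tHand), 3), tolerance = 1e-12)

  zeros <- data.frame(ofA = c(1, 2, 3), ofB = c(1, 2, 3))
  expect_warning(rz <- pairedBorderTest(zeros), "identical")
  expect_equal(rz$t, 0)
  expect_equal(rz$p, 1)

  shift <- data.frame(ofA = c(1, 2, 3), ofB = c(2, 3, 4))
  expect_warning(rs <- pairedBorderTest(shift), "identical")
  expect_true(rs$degenerate)
  expect_true(is.na(rs$t))
})

test_that("paired test is antisymmetric in the group columns", {
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        globalenv()))
  set.seed(31)
  pairs <- data.frame(ofA = runif(10, 0.2, 0.4), ofB = runif(10, 0.2, 0.5))
  a <- pairedBorderTest(pairs)
  b <- pairedBorderTest(data.frame(ofA = pairs$ofB, ofB = pairs$ofA))
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("omnibus test holds its nominal size under the null", {
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        globalenv()))
  set.seed(2024)
  reps <- 500
  rej <- 0L
  for (i in seq_len(reps)) {
    tb <- data.frame(condition = rep(c("a", "b", "c"), each = 25),
                     meanOF = rnorm(75))
    p <- compareTimepoints(tb, "meanOF", levels = c("a", "b", "c"),
                           control = NULL)$p
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / reps, 0.02)
  expect_lt(rej / reps, 0.08)
})
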