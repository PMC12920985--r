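# Property-style checks over seeded random mask pairs.

randomPairs2d3d <- function(n2, n3, seedBase = 0L) {
  pairs <- list()
  for (i in seq_len(n2)) {
    set.seed(seedBase + i)
    dens <- runif(2, 0.05, 0.5)
    pairs[[length(pairs) + 1L]] <- list(
      x = randomMask(c(16, 16), dens[1], seedBase + 10000L + i),
      y = randomMask(c(16, 16), dens[2], seedBase + 20000L + i))
  }
  for (i in seq_len(n3)) {
    set.seed(seedBase + 500L + i)
    dens <- runif(2, 0.05, 0.5)
    pairs[[length(pairs) + 1L]] <- list(
      x = randomMask(c(8, 8, 8), dens[1], seedBase + 30000L + i),
      y = randomMask(c(8, 8, 8), dens[2], seedBase + 40000L + i))
  }
  pairs
}

test_that("the fast and set-form WDC agree to 1e-12 on 100 random pairs", {
  cfg <- MetricConfig()
  pairs <- randomPairs2d3d(50L, 50L)
  for (p in pairs) {
    fast <- metricValue(wdc(p$x, p$y, cfg))
    setf <- metricValue(wdcSetForm(p$x, p$y, cfg))
    expect_lt(abs(fast - setf), 1e-12)
  }
})

test_that("all metrics are symmetric, in [0,1], and 1 on identity", {
  cfg <- MetricConfig()
  pairs <- randomPairs2d3d(10L, 5L, seedBase = 600L)
  for (p in pairs) {
    for (f in list(dsc, wdc, ldc, hybridWdc)) {
      v <- metricValue(f(p$x, p$y, cfg))
      expect_identical(v, metricValue(f(p$y, p$x, cfg)))
      expect_gte(v, 0); expect_lte(v, 1)
    }
    if (positiveCount(p$x) > 0L)
      expect_equal(unname(allMetrics(p$x, p$x, cfg)), rep(1, 4))
  }
})

test_that("with zero environments WDC collapses to DSC and LDC to its closed form", {
  cfg0 <- MetricConfig(nEnv = 0)
  pairs <- randomPairs2d3d(10L, 5L, seedBase = 700L)
  for (p in pairs) {
    d <- metricValue(dsc(p$x, p$y, cfg0))
    expect_identical(metricValue(wdc(p$x, p$y, cfg0)), d)
    expect_identical(metricValue(wdcSetForm(p$x, p$y, cfg0)), d)
    gx <- maskGrid(p$x); gy <- maskGrid(p$y)
    closed <- 2 * sum(gx & gy) /
      (sum(gx) + sum(gy) + sum(gx & !gy) + sum(gy & !gx))
    expect_equal(metricValue(ldc(p$x, p$y, cfg0)), closed, tolerance = 1e-15)
  }
})

test_that("LDC never exceeds DSC", {
  cfg <- MetricConfig()
  pairs <- randomPairs2d3d(15L, 10L, seedBase = 800L)
  for (p in pairs) {
    expect_lte(metricValue(ldc(p$x, p$y, cfg)),
               metricValue(dsc(p$x, p$y, cfg)) + 1e-15)
  }
})

test_that("equal-count errors near the reference outrank errors far from it", {
  # X: 3x3 block. B and C keep the same 8 true positives and add one
  # false positive each: B's inside X_1, C's beyond X_3.
  shape <- c(30, 30)
  x <- blockMask(shape, 10:12, 10:12)
  base <- maskGrid(x); base[12, 12] <- FALSE     # drop one corner: 8 TPs
  gb <- base; gb[11, 13] <- TRUE                 # adjacent FP, in X_1
  gc <- base; gc[25, 25] <- TRUE                 # FP far outside X_3
  b <- BinaryMask(gb); cc <- BinaryMask(gc)
  expect_identical(positiveCount(b), positiveCount(cc))
  expect_identical(metricValue(dsc(x, b)), metricValue(dsc(x, cc)))
  expect_gt(metricValue(wdc(x, b)), metricValue(wdc(x, cc)))
  expect_gt(metricValue(ldc(x, b)), metricValue(ldc(x, cc)))
})

test_that("a false positive inside the reference environment raises a low WDC", {
  shape <- c(40, 40)
  x <- blockMask(shape, 5:7, 5:7)
  y <- blockMask(shape, 5:7, 30:32)    # far away: WDC = 0
  g2 <- maskGrid(y); g2[6, 9] <- TRUE  # new point inside X_2, far from Y
  y2 <- BinaryMask(g2)
  expect_gt(metricValue(wdc(x, y2)), metricValue(wdc(x, y)))
})

test_that("translating both masks together leaves every metric unchanged", {
  cfg <- MetricConfig()
  x <- blockMask(c(30, 30), 10:13, 11:12)
  g <- array(FALSE, c(30, 30)); g[9:12, 12:14] <- TRUE
  y <- BinaryMask(g)
  before <- allMetrics(x, y, cfg)
  # shift by (+5, +4) via explicit re-embedding of the coordinates
  reEmbed <- function(m, dr, dc) {
    g0 <- maskGrid(m)
    out <- array(FALSE, dim(g0))
    idx <- which(g0, arr.ind = TRUE)
    out[cbind(idx[, 1] + dr, idx[, 2] + dc)] <- TRUE
    BinaryMask(out)
  }
  after <- allMetrics(reEmbed(x, 5L, 4L), reEmbed(y, 5L, 4L), cfg)
  expect_identical(before, after)
})
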