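test_that("two 3x3 squares overlapping in 2 pixels give DSC 2*2/18", {
  a <- blockMask(c(10, 10), 2:4, 2:4)
  b <- blockMask(c(10, 10), 4:6, 3:5)
  expect_identical(sum(maskGrid(a) & maskGrid(b)), 2L)
  r <- dsc(a, b)
  expect_equal(metricValue(r), 4 / 18)
  expect_identical(degenerateFlag(r), "none")
})

test_that("all four metrics are 1 on identical nonempty masks", {
  m <- blockMask(c(12, 12), 4:7, 5:8)
  expect_equal(unname(allMetrics(m, m)), rep(1, 4))
})

test_that("DSC matches a literal set-counting oracle on random pairs", {
  for (seed in 1:50) {
    x <- randomMask(c(16, 16), runif(1, 0.05, 0.5), seed)
    y <- randomMask(c(16, 16), runif(1, 0.05, 0.5), seed + 1000L)
    expect_equal(metricValue(dsc(x, y)), oracleDsc(x, y), tolerance = 1e-15)
  }
})

test_that("adjacent single pixels give WDC 14.8/22.8 and DSC 0", {
  a <- blockMask(c(15, 15), 8, 7)
  b <- blockMask(c(15, 15), 8, 8)
  cfg <- MetricConfig()
  expect_equal(metricValue(wdc(a, b, cfg)), 14.8 / 22.8, tolerance = 1e-12)
  expect_equal(metricValue(wdc(a, b, cfg)), oracleWdc(a, b, cfg),
               tolerance = 1e-12)
  expect_equal(metricValue(dsc(a, b)), 0)
  expect_equal(metricValue(hybridWdc(a, b, cfg)), 0)
})

test_that("pixels farther apart than 2n steps have WDC exactly 0", {
  a <- blockMask(c(20, 20), 5, 5)
  b <- blockMask(c(20, 20), 5, 13)   # L1 distance 8 > 2*3
  expect_identical(metricValue(wdc(a, b)), 0)
})

test_that("WDC matches the brute-force weight-map oracle on random pairs", {
  cfg <- MetricConfig()
  for (seed in 1:10) {
    x <- randomMask(c(12, 12), 0.1, seed + 300L)
    y <- randomMask(c(12, 12), 0.1, seed + 400L)
    expect_equal(metricValue(wdc(x, y, cfg)), oracleWdc(x, y, cfg),
                 tolerance = 1e-12)
  }
})

test_that("LDC penalises a distant false positive as derived by counting", {
  x <- blockMask(c(20, 20), 5:7, 5:7)
  g <- maskGrid(x); g[15, 15] <- TRUE
  y <- BinaryMask(g)
  # 2*9 / (9 + 10 + |X \ Y*| + |Y \ X*|) = 18 / (19 + 0 + 1)
  expect_equal(metricValue(ldc(x, y)), 0.9)
  expect_equal(metricValue(dsc(x, y)), 18 / 19)
})

test_that("LDC equals DSC when each mask sits inside the other's environment", {
  x <- blockMask(c(16, 16), 5:8, 5:8)
  y <- blockMask(c(16, 16), 5:9, 5:8)   # one-row over-segmentation
  expect_equal(metricValue(ldc(x, y)), metricValue(dsc(x, y)))
})

test_that("the hybrid coefficient passes WDC through whenever overlap exists", {
  x <- blockMask(c(14, 14), 4:6, 4:6)
  y <- blockMask(c(14, 14), 5:7, 4:6)
  expect_equal(metricValue(hybridWdc(x, y)), metricValue(wdc(x, y)))
})

test_that("empty-mask semantics: both empty is 1, one empty is 0, flagged", {
  e <- BinaryMask(array(FALSE, c(8, 8)))
  m <- blockMask(c(8, 8), 3:4, 3:4)
  for (f in list(dsc, wdc, wdcSetForm, ldc, hybridWdc)) {
    both <- f(e, e)
    expect_equal(metricValue(both), 1)
    expect_identical(degenerateFlag(both), "both_empty")
    one <- f(e, m)
    expect_equal(metricValue(one), 0)
    expect_identical(degenerateFlag(one), "one_empty")
  }
})

test_that("shape mismatches are reported with both shapes named", {
  a <- blockMask(c(8, 8), 2, 2)
  b <- blockMask(c(8, 9), 2, 2)
  expect_error(dsc(a, b), "8x8.*8x9")
  expect_error(wdc(a, b), "8x8.*8x9")
  expect_error(ldc(a, b), "8x8.*8x9")
})

test_that("an LDC environment index beyond n is rejected", {
  expect_error(MetricConfig(ldcEnvIndex = 5), "ldcEnvIndex")
})
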