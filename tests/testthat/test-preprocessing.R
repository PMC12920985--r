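test_that("constant masks resize to constant masks", {
  ones <- BinaryMask(array(TRUE, c(64, 64)))
  out <- resizeMask(ones, c(16, 16))
  expect_identical(dim(out), c(16L, 16L))
  expect_true(all(maskGrid(out)))
  zeros <- BinaryMask(array(FALSE, c(64, 64)))
  expect_identical(positiveCount(resizeMask(zeros, c(16, 16))), 0L)
})

test_that("integer downscale equals the block-average oracle", {
  set.seed(11)
  g <- array(runif(48 * 48) < 0.3, c(48, 48))
  out <- maskGrid(resizeMask(BinaryMask(g), c(12, 12), threshold = 0.25))
  oracle <- array(FALSE, c(12, 12))
  for (i in 1:12) for (j in 1:12) {
    blk <- g[((i - 1) * 4 + 1):(i * 4), ((j - 1) * 4 + 1):(j * 4)]
    oracle[i, j] <- mean(blk) > 0.25
  }
  expect_identical(out, oracle)
})

test_that("a centred block survives 4x downscaling at threshold 0.25", {
  g <- array(FALSE, c(64, 64))
  g[31:34, 31:34] <- TRUE            # straddles four coarse pixels equally
  out <- maskGrid(resizeMask(BinaryMask(g), c(16, 16), threshold = 0.2))
  # each of the four straddled coarse pixels has coverage 2x2/16 = 0.25
  expected <- array(FALSE, c(16, 16)); expected[8:9, 8:9] <- TRUE
  expect_identical(out, expected)
  # at the default strict threshold 0.25 the same blocks are excluded
  out25 <- resizeMask(BinaryMask(g), c(16, 16), threshold = 0.25)
  expect_identical(positiveCount(out25), 0L)
})

test_that("resizing to the input shape is the identity", {
  m <- randomMask(c(20, 20), 0.3, 5L)
  expect_identical(maskGrid(resizeMask(m, c(20, 20))), maskGrid(m))
})

test_that("bilinear path handles non-integer scale factors", {
  g <- array(FALSE, c(30, 30)); g[10:20, 10:20] <- TRUE
  out <- resizeMask(BinaryMask(g), c(20, 20))
  expect_identical(dim(out), c(20L, 20L))
  expect_gt(positiveCount(out), 0L)
})

test_that("resize rejects bad targets and thresholds", {
  m <- randomMask(c(10, 10), 0.3, 1L)
  expect_error(resizeMask(m, c(0, 10)), "positive")
  expect_error(resizeMask(m, c(5, 5), threshold = 0), "threshold")
  expect_error(resizeMask(m, c(5, 5), threshold = 1), "threshold")
})

test_that("the minimum-positive filter excludes below the cutoff only", {
  five <- blockMask(c(10, 10), 2:6, 3)          # 5 positives
  six <- blockMask(c(10, 10), 2:7, 3)           # 6 positives
  res <- minPositiveFilter(list(five, six), minCount = 6)
  expect_identical(res$excluded, 1L)
  expect_length(res$retained, 1L)
  expect_identical(maskGrid(res$retained[[1L]]), maskGrid(six))

  all_in <- minPositiveFilter(list(five, six), minCount = 0)
  expect_length(all_in$retained, 2L)
  expect_length(all_in$excluded, 0L)
})

test_that("filtering matches a direct counting oracle on random masks", {
  masks <- lapply(1:10, function(s) randomMask(c(6, 6), 0.1, s + 60L))
  res <- minPositiveFilter(masks, minCount = 3)
  keepOracle <- vapply(masks, function(m) sum(maskGrid(m)) >= 3, logical(1))
  expect_identical(length(res$retained), sum(keepOracle))
  expect_identical(res$excluded, which(!keepOracle))
})

test_that("stacking slices conserves counts and round-trips", {
  slices <- lapply(1:3, function(s) randomMask(c(12, 12), 0.2, s + 80L))
  vol <- stackSlices(slices)
  expect_identical(dim(vol), c(3L, 12L, 12L))
  expect_identical(positiveCount(vol),
                   sum(vapply(slices, positiveCount, integer(1))))
  back <- sliceMask(vol)
  for (i in 1:3)
    expect_identical(maskGrid(back[[i]]), maskGrid(slices[[i]]))

  single <- stackSlices(slices[1])
  expect_identical(dim(single), c(1L, 12L, 12L))
  expect_error(stackSlices(list(slices[[1]], randomMask(c(5, 5), 0.2, 1L))),
               "inconsistent")
})
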