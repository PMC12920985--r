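test_that("perfectly monotone sequences give rho of +1 and -1", {
  scores <- c(0, 1, 2, 3, 4, 0, 2)
  up <- spearmanCorrelation(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.12, 0.31),
                            c(0, 1, 2, 3, 4, 0.5, 2.5))
  expect_equal(testStatistic(up), 1)
  expect_equal(pValue(up), 0)
  down <- spearmanCorrelation(5:1, 1:5)
  expect_equal(testStatistic(down), -1)
})

test_that("rho matches the rank-then-Pearson oracle to 1e-12", {
  set.seed(21)
  values <- round(runif(20), 2)           # rounding forces some ties
  scores <- sample(0:4, 20, replace = TRUE)
  r <- spearmanCorrelation(values, scores)
  expect_lt(abs(testStatistic(r) - oracleSpearman(values, scores)), 1e-12)
  # and against the independent base-R route
  expect_lt(abs(testStatistic(r) -
                cor(values, scores, method = "spearman")), 1e-12)
})

test_that("rho is invariant under strictly increasing transforms", {
  set.seed(33)
  v <- runif(15); s <- sample(0:4, 15, replace = TRUE)
  r0 <- testStatistic(spearmanCorrelation(v, s))
  expect_equal(testStatistic(spearmanCorrelation(exp(3 * v), s)), r0)
  expect_equal(testStatistic(spearmanCorrelation(v, s * 10 + 1)), r0)
})

test_that("constant sequences are rejected as undefined correlation", {
  expect_error(spearmanCorrelation(rep(0.5, 5), 1:5), "constant")
  expect_error(spearmanCorrelation(1:5, rep(2, 5)), "constant")
  expect_error(spearmanCorrelation(1:2, 1:2), "length")
})

test_that("the exact permutation p-value is valid at tiny n", {
  r <- spearmanCorrelation(c(0.1, 0.4, 0.2, 0.9, 0.7),
                           c(0, 1, 1, 3, 2), method = "exact")
  expect_gt(pValue(r), 0)
  expect_lte(pValue(r), 1)
  expect_error(spearmanCorrelation(runif(9), runif(9), method = "exact"),
               "n <= 8")
})

test_that("identical samples give F = 1 with two-sided p = 1", {
  a <- c(0.2, 0.5, 0.9, 0.4)
  r <- fTestVariances(a, a)
  expect_equal(testStatistic(r), 1)
  expect_equal(pValue(r), 1)
  expect_false(attr(r, "significant"))
})

test_that("F-test p-values match a numerical F-CDF oracle to 1e-9", {
  set.seed(77)
  a <- rnorm(25, sd = 2)
  b <- rnorm(25, sd = 1)
  r <- fTestVariances(a, b)
  f <- var(a) / var(b)
  expect_lt(abs(testStatistic(r) - f), 1e-12)
  oracle <- 2 * min(pf(f, 24, 24), 1 - pf(f, 24, 24))
  expect_lt(abs(pValue(r) - min(oracle, 1)), 1e-9)
})

test_that("the F test is symmetric in its two-sided p-value", {
  set.seed(78)
  a <- rnorm(12, sd = 3); b <- rnorm(9)
  expect_equal(pValue(fTestVariances(a, b)), pValue(fTestVariances(b, a)))
})

test_that("two zero-variance samples cannot be F-tested", {
  expect_error(fTestVariances(rep(0, 5), rep(0, 4)), "zero variance")
  expect_error(fTestVariances(1, c(1, 2)), "at least 2")
})

test_that("Benjamini-Hochberg adjustment reproduces the hand computation", {
  expect_equal(fdrCorrect(0.04), 0.04)
  expect_equal(fdrCorrect(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- sort(runif(20))
  q <- fdrCorrect(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q) >= -1e-15))    # monotone in the sorted order
  expect_true(all(q <= 1))
  expect_error(fdrCorrect(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("class summaries use sample sd and flag singletons", {
  metrics <- data.frame(DSC = c(0, 0, 0, 0.5, 0.7, 0.9, 0.4))
  scores <- c(0, 0, 0, 3, 3, 3, 4)
  expect_warning(s <- classSummaries(metrics, scores), "omitted")
  zero <- s[s$score == 0, ]
  expect_equal(c(zero$min, zero$mean, zero$max, zero$sd), c(0, 0, 0, 0))
  three <- s[s$score == 3, ]
  expect_equal(three$mean, mean(c(0.5, 0.7, 0.9)))
  expect_equal(three$sd, sd(c(0.5, 0.7, 0.9)))
  expect_true(is.na(s[s$score == 4, "sd"]))
})

test_that("summaries match direct formulas on a seeded class", {
  set.seed(90)
  v <- runif(50)
  s <- suppressWarnings(classSummaries(data.frame(m = v), rep(2, 50)))
  expect_equal(s$min, min(v)); expect_equal(s$max, max(v))
  expect_equal(s$mean, sum(v) / 50)
  expect_equal(s$sd, sqrt(sum((v - mean(v))^2) / 49))
})

test_that("the variance-test table corrects over the whole family", {
  set.seed(91)
  metrics <- data.frame(DSC = runif(40), WDC = runif(40) * 0.5,
                        LDC = runif(40))
  scores <- rep(c(3, 4), each = 20)
  tab <- varianceTestTable(metrics, scores)
  expect_identical(nrow(tab), 6L)          # 2 classes x 3 pairings
  expect_true(all(tab$pValueFdr >= tab$pValue - 1e-15))
  expect_equal(tab$pValueFdr, fdrCorrect(tab$pValue))
})
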