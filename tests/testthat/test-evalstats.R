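# Evaluation arithmetic: confusion tables, rates, occupancy fit, tests.

test_that("the benchmark confusion matrix reproduces every printed margin", {
  cm <- confusionFromTables(benchmarkDiagonal, benchmarkOffDiagonal)
  m <- cmCounts(cm)
  expect_identical(sum(m), 7920L)
  expect_equal(unname(rowSums(m)), c(6458, 1225, 209, 28))
  expect_equal(unname(colSums(m)), c(6467, 1203, 225, 25))
  r <- categoryRates(cm)
  expect_equal(round(r$overall, 5), 0.98321)
  expect_equal(round(unname(r$sensitivity), 5),
               c(0.99412, 0.93878, 0.92344, 0.85714))
  expect_equal(round(unname(r$ppv), 5),
               c(0.99273, 0.95594, 0.85778, 0.96))
  d <- discordanceMatrix(cm)
  expect_identical(d$total, 133L)
  expect_equal(unname(d$rowTotals), c(38, 75, 16, 4))
  expect_equal(unname(d$colTotals), c(47, 53, 32, 1))
  # the packaged reference equals the assembled matrix
  expect_identical(cmCounts(referenceConfusionMatrix()), m)
})

test_that("rates weight-average to the overall concordance", {
  set.seed(4)
  for (i in 1:20) {
    truth <- sample(CATEGORY_LEVELS, 200, replace = TRUE,
                    prob = c(0.7, 0.2, 0.07, 0.03))
    pred <- ifelse(runif(200) < 0.8, truth,
                   sample(CATEGORY_LEVELS, 200, replace = TRUE))
    cm <- confusionMatrix(truth, pred)
    r <- categoryRates(cm)
    m <- cmCounts(cm)
    expect_equal(sum(r$sensitivity * rowSums(m), na.rm = TRUE) / sum(m),
                 r$overall)
    expect_equal(sum(r$ppv * colSums(m), na.rm = TRUE) / sum(m), r$overall)
    # discordance totals equal n minus trace, by brute force
    d <- discordanceMatrix(cm)
    expect_equal(d$total, sum(m[row(m) != col(m)]))
  }
  # zero marginals are flagged as undefined, not silently zero
  cm0 <- confusionMatrix(rep("0", 5), rep("0", 5))
  r0 <- categoryRates(cm0)
  expect_equal(unname(r0$sensitivity[1]), 1)
  expect_true(all(is.na(r0$sensitivity[2:4])))
  expect_error(categoryRates(confusionFromTables(rep(0, 4),
                                                 matrix(0, 4, 4))),
               "all-zero")
})

test_that("the censored-Poisson fit recovers lambda", {
  # boundary: all wells empty
  f0 <- fitPoissonOccupancy(100, 0, 0, 0)
  expect_identical(lambdaHat(f0), 0)
  # parameter recovery at the benchmark loading
  set.seed(5)
  cnt <- rpois(1e5, 0.2)
  f <- fitPoissonOccupancy(sum(cnt == 0), sum(cnt == 1), sum(cnt == 2),
                           sum(cnt > 2))
  expect_lt(abs(lambdaHat(f) - 0.2), 0.01)
  # the gradient of the log-likelihood vanishes at the optimum
  ll <- function(l) nanowell:::.occLogLik(l, sum(cnt == 0), sum(cnt == 1),
                                          sum(cnt == 2), sum(cnt > 2))
  eps <- 1e-5
  grad <- (ll(lambdaHat(f) + eps) - ll(lambdaHat(f) - eps)) / (2 * eps)
  expect_lt(abs(grad) / sum(cnt >= 0), 1e-3)
  # invariance to scaling all counts
  f2 <- fitPoissonOccupancy(7 * sum(cnt == 0), 7 * sum(cnt == 1),
                            7 * sum(cnt == 2), 7 * sum(cnt > 2))
  expect_equal(lambdaHat(f2), lambdaHat(f), tolerance = 1e-6)
})

test_that("expected Poisson proportions are a valid distribution", {
  expect_equal(unname(expectedPoissonProportions(0)), c(1, 0, 0, 0))
  p <- expectedPoissonProportions(0.202247)
  expect_equal(unname(p[1]), exp(-0.202247), tolerance = 1e-12)
  expect_equal(sum(p), 1)
  expect_equal(unname(p[4]), 0.001186, tolerance = 1e-3)
  for (lam in c(0.01, 0.5, 2, 10)) {
    q <- expectedPoissonProportions(lam)
    expect_true(all(q >= 0))
    expect_equal(sum(q), 1)
  }
})

test_that("generator data with cluster excess show surplus multi-cell wells", {
  # mirrors the benchmark observation: observed 2 / >2 proportions exceed
  # the fitted Poisson expectation when cells cluster
  set.seed(6)
  cnt <- sampleCellCount(occupancyModel(lambda = 0.2, clusterExcess = 0.3),
                         5e4)
  n <- c(sum(cnt == 0), sum(cnt == 1), sum(cnt == 2), sum(cnt > 2))
  f <- fitPoissonOccupancy(n[1], n[2], n[3], n[4])
  expected <- expectedPoissonProportions(lambdaHat(f))
  observed <- n / sum(n)
  expect_gt(observed[3] + observed[4], expected[3] + expected[4])
  expect_lt(observed[2], expected[2])
})

test_that("chi-square comparison matches its closed form", {
  # identical columns: no association at all
  flat <- compareConcordanceChi2(matrix(c(50, 50, 50, 50), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$pValue, 1)
  # closed-form oracle n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  set.seed(7)
  for (i in 1:50) {
    tb <- matrix(rpois(4, 30) + 1, 2)
    a <- tb[1, 1]; b <- tb[1, 2]; c <- tb[2, 1]; d <- tb[2, 2]
    stat <- sum(tb) * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    got <- compareConcordanceChi2(tb)
    expect_equal(got$statistic, stat, tolerance = 1e-12)
    expect_equal(got$pValue, pchisq(stat, 1, lower.tail = FALSE))
  }
  expect_error(compareConcordanceChi2(matrix(c(0, 0, 5, 5), 2)),
               "marginal")
})

test_that("the majority-vote comparison reproduces the printed bound", {
  tb <- referenceMajorityVoteTable()
  expect_equal(unname(tb[, 1]), c(87, 46))
  expect_equal(round(87 / 133, 2), 0.65)
  expect_equal(round(36 / 133, 2), 0.27)
  res <- compareConcordanceChi2(tb)
  expect_lt(res$pValue, 0.0001)
  # the corrected variant agrees on the conclusion
  expect_lt(compareConcordanceChi2(tb, correct = TRUE)$pValue, 0.0001)
})

test_that("confidence separation is a rank test on log outputs", {
  # exchangeable groups: no separation
  set.seed(8)
  g <- runif(30, 0.3, 1)
  same <- confidenceSeparationTest(g, g)
  expect_gt(same$pValue, 0.5)
  # full separation at n1 = n2 = 4: exact two-sided p = 2 / choose(8, 4)
  hi <- c(0.9, 0.92, 0.95, 0.97)
  lo <- c(0.3, 0.35, 0.4, 0.45)
  sep <- confidenceSeparationTest(hi, lo)
  expect_equal(sep$U, 16)
  expect_equal(sep$pValue, 2 / choose(8, 4), tolerance = 1e-12)
  # invariance: log is monotone, U is unchanged versus the raw scale
  raw <- suppressWarnings(wilcox.test(hi, lo))
  expect_equal(sep$U, unname(raw$statistic))
  expect_error(confidenceSeparationTest(numeric(0), lo), "non-empty")
})
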