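# Confidence-threshold triage: the ambiguous set, derived thresholds,
# concordance under the two policies.

test_that("ambiguous wells are exactly those with h below the threshold", {
  h <- c(a = 0.9, b = 0.6, c = 0.4)
  r <- flagAmbiguous(h, t = 0.5)
  expect_identical(ambiguousWells(r), "c")
  expect_identical(sort(retainedWells(r)), c("a", "b"))
  expect_equal(r@realizedProportion, 1 / 3)

  # a 4-class softmax maximum is >= 0.25, so t = 0.25 flags nothing
  set.seed(1)
  hh <- runif(50, 0.25, 1)
  expect_length(ambiguousWells(flagAmbiguous(hh, 0.25)), 0L)
  # at t = 1 every well below certainty is ambiguous
  expect_length(ambiguousWells(flagAmbiguous(hh, 1.0)), 50L)
  expect_error(flagAmbiguous(hh, 1.2))
  # strict inequality: ties at t are retained
  r2 <- flagAmbiguous(c(x = 0.5, y = 0.4), t = 0.5)
  expect_identical(ambiguousWells(r2), "y")
})

test_that("threshold derivation hits the target proportion from below", {
  h <- c(0.3, 0.5, 0.7, 0.9)
  th <- thresholdForProportion(h, 0.25)
  expect_equal(th$threshold, 0.5)
  expect_equal(th$realizedProportion, 0.25)
  # p = 0: threshold at the minimum, nothing flagged
  th0 <- thresholdForProportion(h, 0)
  expect_equal(th0$threshold, 0.3)
  expect_equal(th0$realizedProportion, 0)
  # duplicated h values may undershoot, never overshoot
  set.seed(2)
  for (i in 1:200) {
    hh <- sample(seq(0.3, 1, by = 0.1), sample(3:12, 1), replace = TRUE)
    p <- runif(1, 0, 0.9)
    th <- thresholdForProportion(hh, p)
    expect_lte(th$realizedProportion, p)
    expect_equal(th$realizedProportion, mean(hh < th$threshold))
    # maximality: no larger observed threshold stays within the target
    larger <- unique(hh[hh > th$threshold])
    if (length(larger))
      expect_true(all(vapply(larger, function(t2) mean(hh < t2),
                             numeric(1)) > p))
  }
})

test_that("triage concordance follows the two policies", {
  # toy set: 10 wells, 9 concordant, the only error has the lowest h
  h <- c(0.35, seq(0.6, 0.92, length.out = 9))
  pred <- makePredictions(h, c(FALSE, rep(TRUE, 9)))
  truth <- rep("0", 10)
  raw <- concordanceWithTriage(pred, truth, t = 0.3, "resolve_by_human")
  expect_equal(raw@concordance, 0.9)     # t below min h: raw accuracy
  res <- concordanceWithTriage(pred, truth, t = 0.4, "resolve_by_human")
  exc <- concordanceWithTriage(pred, truth, t = 0.4, "exclude")
  expect_equal(res@concordance, 1.0)     # 10/10 after human resolution
  expect_equal(exc@concordance, 1.0)     # 9/9 after exclusion
  # all ambiguous under the resolve policy: everything human-resolved
  all_r <- concordanceWithTriage(pred, truth, t = 1.0, "resolve_by_human")
  expect_equal(all_r@concordance, 1.0)
  expect_error(concordanceWithTriage(pred, truth[-1], 0.5),
               "differ in length")
})

test_that("resolve-policy concordance is monotone in the threshold", {
  # brute-force oracle on random small instances
  set.seed(3)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    h <- round(runif(n, 0.25, 1), 2)
    conc <- runif(n) < 0.8
    pred <- makePredictions(h, conc)
    truth <- rep("0", n)
    grid <- sort(unique(c(h, 0.26, 1.0)))
    rates <- vapply(grid, function(t)
      concordanceWithTriage(pred, truth, t, "resolve_by_human")@concordance,
      numeric(1))
    # independent oracle: direct counting from the definition
    oracle <- vapply(grid, function(t)
      (sum(conc & h >= t) + sum(h < t)) / n, numeric(1))
    expect_equal(rates, oracle)
    expect_true(all(diff(rates) >= -1e-12))
  }
})

test_that("concordance curves behave at their boundaries", {
  h <- c(0.35, seq(0.6, 0.92, length.out = 9))
  pred <- makePredictions(h, c(FALSE, rep(TRUE, 9)))
  truth <- rep("0", 10)
  # single grid point 0: both policies equal raw accuracy
  c0 <- concordanceCurve(pred, truth, proportions = 0)
  expect_equal(c0$concordance, c(0.9, 0.9))
  # perfectly calibrated and correct: flat at 1
  perfect <- makePredictions(rep(1, 8), rep(TRUE, 8))
  cp <- concordanceCurve(perfect, rep("0", 8), c(0, 0.1, 0.5))
  expect_true(all(cp$concordance == 1))
  # errors concentrated at low h: resolve curve increases
  cc <- concordanceCurve(pred, truth, c(0, 0.1, 0.3))
  resolve <- cc[cc$policy == "resolve_by_human", ]
  expect_true(all(diff(resolve$concordance) >= 0))
  expect_gt(max(resolve$concordance), resolve$concordance[1])
})
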