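# Network initialization, forward/backward correctness, the stratified
# mini-batch sampler, and the training loop contracts.

test_that("He initialization has the prescribed moments and is reproducible", {
  spec <- tableSpec(64L)
  p <- initParams(spec, seed = 5)
  # conv2: fan-in 5*5*32 = 800, so variance 2/800 over its 25,600 weights
  w2 <- p[[2]]$W
  expect_identical(length(w2), 25600L)
  expect_lt(abs(var(as.vector(w2)) - 2 / 800) / (2 / 800), 0.10)
  # mean within 3 standard errors of 0
  expect_lt(abs(mean(w2)), 3 * sqrt(2 / 800 / 25600))
  # biases start at zero
  expect_true(all(vapply(p, function(q) all(q$b == 0), logical(1))))
  # determinism
  expect_identical(p, initParams(spec, seed = 5))
  expect_false(identical(p[[1]]$W, initParams(spec, seed = 6)[[1]]$W))
})

test_that("the forward pass produces valid softmax posteriors", {
  set.seed(8)
  net <- buildNetwork(tableSpec(64L), seed = 2)
  imgs <- lapply(1:5, function(i) matrix(runif(64 * 64, 0, 255), 64))
  pred <- predictWells(net, imgs)
  probs <- as.matrix(pred[, c("p0", "p1", "p2", "pgt2")])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-5))
  expect_true(all(pred$highest_output >= 0.25))
  expect_identical(as.character(pred$predicted),
                   CATEGORY_LEVELS[max.col(probs, ties.method = "first")])
  # a minimal one-layer spec also yields normalized posteriors
  mini <- buildNetwork(nanowell:::.minimalSpec(64L), seed = 1)
  pm <- predictWells(mini, imgs)
  expect_true(all(abs(rowSums(as.matrix(pm[, 2:5])) - 1) < 1e-5))
})

test_that("prediction is deterministic and batch equals per-image", {
  set.seed(9)
  net <- buildNetwork(tableSpec(64L), seed = 3)
  imgs <- lapply(1:7, function(i) matrix(runif(64 * 64, 0, 255), 64))
  a <- predictWells(net, imgs)
  b <- predictWells(net, imgs)              # dropout must be inactive
  expect_identical(a, b)
  single <- do.call(rbind, lapply(imgs, function(im)
    predictWells(net, list(im))))
  expect_equal(as.matrix(a[, 2:5]), as.matrix(single[, 2:5]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(predictWells(net, list(matrix(0, 32, 32))), "incompatible")
})

test_that("analytic gradients match central finite differences", {
  spec <- tableSpec(64L, dropoutRate = 0)
  net <- buildNetwork(spec, seed = 3)
  plan <- nanowell:::.cppPlan(spec)
  set.seed(9)
  B <- 2L
  x <- array(runif(64 * 64 * B), dim = c(64L, 64L, B))
  y <- c(1L, 3L)
  lossAt <- function(params) {
    p <- nanowell:::.cnnForward(plan, params, x)$probs
    mean(-log(p[cbind(seq_len(B), y)]))
  }
  lr <- 1e-3
  step <- nanowell:::.cnnTrainStep(plan, net@params, x, y, lr, 0, 1)
  set.seed(42)
  for (li in seq_along(net@params)) {
    gW <- (net@params[[li]]$W - step$params[[li]]$W) / lr
    for (t in 1:3) {
      i <- sample(length(gW), 1)
      eps <- 1e-5
      up <- net@params; up[[li]]$W[i] <- up[[li]]$W[i] + eps
      dn <- net@params; dn[[li]]$W[i] <- dn[[li]]$W[i] - eps
      fd <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      denom <- max(abs(fd), abs(gW[i]), 1e-6)
      expect_lt(abs(fd - gW[i]) / denom, 1e-4)
    }
  }
})

test_that("the stratified sampler honours its composition", {
  set.seed(10)
  imgs <- lapply(1:300, function(i) matrix(runif(16), 4))
  labs <- countToCategory(c(rep(0, 200), rep(1, 60), rep(2, 25),
                            rep(3, 15)))
  b <- sampleMinibatch(imgs, labs)
  expect_identical(length(b$images), 119L)
  expect_equal(as.vector(table(b$labels)), c(77L, 21L, 10L, 11L))
  # minimal composition
  b4 <- sampleMinibatch(imgs, labs, composition = c(1L, 1L, 1L, 1L))
  expect_identical(length(b4$images), 4L)
  # scarce category: with replacement, still the full composition
  labs2 <- countToCategory(c(rep(0, 200), rep(1, 70), rep(2, 28),
                             rep(3, 2)))
  b2 <- sampleMinibatch(imgs, labs2)
  expect_equal(sum(b2$labels == "gt2"), 11L)
  # absent category is an error naming the category
  labs3 <- countToCategory(c(rep(0, 230), rep(1, 50), rep(2, 20)))
  expect_error(sampleMinibatch(imgs, labs3), "gt2")
})

test_that("within a category every pool member is drawn uniformly", {
  # 10 distinct members, 2 requested per batch, 1000 batches
  imgs <- lapply(1:40, function(i) matrix(i, 2, 2))
  labs <- countToCategory(c(rep(0, 10), rep(1, 10), rep(2, 10),
                            rep(3, 10)))
  set.seed(11)
  draws <- integer(10)
  for (i in 1:1000) {
    b <- sampleMinibatch(imgs, labs, composition = c(2L, 1L, 1L, 1L),
                         transformProb = 0)
    ids <- vapply(b$images[b$labels == "0"], function(m) m[1, 1],
                  numeric(1))
    draws[ids] <- draws[ids] + 1L
  }
  # 2000 draws over 10 members: expectation 200, binomial SE ~ 13.4
  se <- sqrt(2000 * 0.1 * 0.9)
  expect_true(all(abs(draws - 200) < 3 * se))
})

test_that("training runs its schedule, records traces and is reproducible", {
  set.seed(12)
  mini <- nanowell:::.minimalSpec(64L)
  geom <- smallGeometry()
  occ <- occupancyModel(lambda = 0.8, clusterExcess = 0.3)
  tr <- generatePlate(120L, geom, occ, cleanArtifacts(), seed = 61,
                      plateId = "tr")
  va <- generatePlate(60L, geom, occ, cleanArtifacts(), seed = 62,
                      plateId = "va")
  data <- c(tr, va)
  part <- subsetPartition(train = "tr", validation = "va", test = character())
  cfg <- trainingConfig(minibatchComposition = c(4L, 2L, 1L, 1L),
                        stageSchedule = list(
                          list(iterations = 30L, subsets = "tr")),
                        learningRate = 0.005, evalEvery = 10L)
  net <- buildNetwork(mini, seed = 1)
  fit1 <- trainNetwork(net, data, part, cfg, seed = 77)
  fit2 <- trainNetwork(net, data, part, cfg, seed = 77)
  expect_identical(fit1$trace, fit2$trace)
  expect_identical(fit1$network@params, fit2$network@params)
  expect_identical(nrow(fit1$trace), 30L)
  expect_identical(nrow(fit1$validation), 3L)
  expect_true(all(fit1$trace$loss >= 0))
  expect_true(all(fit1$validation$accuracy >= 0 &
                    fit1$validation$accuracy <= 1))

  # a zero-iteration schedule returns the initialization untouched
  cfg0 <- trainingConfig(minibatchComposition = c(4L, 2L, 1L, 1L),
                         stageSchedule = list(
                           list(iterations = 0L, subsets = "tr")))
  fit0 <- trainNetwork(net, data, part, cfg0, seed = 77)
  expect_identical(fit0$network@params, net@params)
})

test_that("a non-finite loss aborts with a learning-rate diagnostic", {
  mini <- nanowell:::.minimalSpec(64L)
  net <- buildNetwork(mini, seed = 1)
  plan <- nanowell:::.cppPlan(mini)
  set.seed(14)
  x <- array(runif(64 * 64 * 2), dim = c(64L, 64L, 2L))
  y <- c(1L, 2L)
  bad <- net@params
  bad[[1]]$W[1] <- NaN            # a blown-up parameter poisons the loss
  expect_error(nanowell:::.cnnTrainStep(plan, bad, x, y, 0.01, 0, 1),
               "learning rate")
})

test_that("dropout perturbs training but never prediction", {
  spec <- tableSpec(64L, dropoutRate = 0.5)
  net <- buildNetwork(spec, seed = 4)
  plan <- nanowell:::.cppPlan(spec)
  set.seed(13)
  x <- array(runif(64 * 64 * 4), dim = c(64L, 64L, 4L))
  y <- c(1L, 2L, 3L, 4L)
  s1 <- nanowell:::.cnnTrainStep(plan, net@params, x, y, 0.01, 0.5, 101)
  s2 <- nanowell:::.cnnTrainStep(plan, net@params, x, y, 0.01, 0.5, 202)
  # different dropout masks give different fc updates
  expect_false(identical(s1$params[[9]]$W, s2$params[[9]]$W))
  # same seed reproduces the step exactly
  s3 <- nanowell:::.cnnTrainStep(plan, net@params, x, y, 0.01, 0.5, 101)
  expect_identical(s1$params, s3$params)
})
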