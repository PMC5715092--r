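# Building, initializing, training and applying the counting network.
# The heavy numerics live in src/cnn.cpp; this file owns parameter
# initialization, the stratified mini-batch sampler, the staged training
# schedule with early stopping, and prediction.

#' Initialize network parameters
#'
#' Every weight is drawn i.i.d. from a normal distribution with mean 0 and
#' variance `2 / fanIn` (He initialization), where `fanIn` is the number of
#' nodes of the previous layer feeding one unit; biases start at zero.
#' Reproducible given the seed.
#'
#' @param spec a [NetworkSpec-class].
#' @param seed RNG seed.
#' @return list with one `list(W, b)` per learnable layer, in network
#'   order. `W` is stored as an (out x fanIn) matrix.
#' @export
initParams <- function(spec, seed = 1L) {
  stopifnot(is(spec, "NetworkSpec"))
  validObject(spec)
  set.seed(seed)
  params <- list()
  for (l in spec@layers) {
    if (!length(l@weightShape)) next
    nOut <- l@outChannels
    fanIn <- l@fanIn
    W <- matrix(rnorm(nOut * fanIn, mean = 0, sd = sqrt(2 / fanIn)),
                nrow = nOut, ncol = fanIn)
    params[[length(params) + 1L]] <- list(W = W, b = numeric(nOut))
  }
  params
}

#' Build a counting network from its spec
#'
#' Instantiates a [CellCountNet-class]: the differentiable map from a batch
#' of well images to 4-category posterior probabilities, with freshly
#' He-initialized parameters. Layer compatibility is checked when the spec
#' is compiled; a mismatch between consecutive layers is an error naming
#' both layers.
#'
#' @param spec a [NetworkSpec-class] (see [tableSpec()]).
#' @param seed RNG seed for initialization.
#' @return a [CellCountNet-class].
#' @examples
#' net <- buildNetwork(tableSpec(64), seed = 1)
#' @export
buildNetwork <- function(spec, seed = 1L) {
  .cppPlan(spec)            # validates layer-to-layer shape compatibility
  new("CellCountNet", spec = spec, params = initParams(spec, seed))
}

#' Realized layer shapes of a forward pass
#'
#' Runs one image through the network and reports the actual output shape
#' of every layer, for verification against the declared architecture.
#'
#' @param net a [CellCountNet-class].
#' @return data.frame with `label`, `channels`, `pixels` (per image) and
#'   `side` per layer.
#' @export
forwardShapes <- function(net) {
  stopifnot(is(net, "CellCountNet"))
  s <- net@spec@inputSide
  x <- array(0, dim = c(s, s, 1L))
  res <- .cnnForward(.cppPlan(net@spec), net@params, x, shapes = TRUE)
  sh <- res$shapes
  data.frame(label = names(sh),
             channels = vapply(sh, `[[`, integer(1), "channels"),
             pixels = vapply(sh, `[[`, integer(1), "pixels"),
             side = vapply(sh, `[[`, integer(1), "side"),
             stringsAsFactors = FALSE)
}

#' Sample one stratified mini-batch
#'
#' Draws the configured number of samples per occupancy category (default
#' 77, 21, 10 and 11 for categories 0, 1, 2 and gt2: a batch of 119) and
#' applies random augmentation to each drawn image. Within a category every
#' member of the pool is drawn with equal probability; when a category has
#' fewer distinct members than requested, sampling is with replacement. A
#' category entirely absent from the pool is an error naming the category.
#'
#' @param images list of image matrices (the training pool).
#' @param labels factor of occupancy categories parallel to `images`.
#' @param composition integer vector of per-category counts in order
#'   0/1/2/gt2.
#' @param transformProb augmentation probability (see [augmentImage()]).
#' @return list with `images` (list, length `sum(composition)`) and
#'   `labels` (factor).
#' @export
sampleMinibatch <- function(images, labels,
                            composition = c(77L, 21L, 10L, 11L),
                            transformProb = 0.2) {
  labels <- asCategory(labels)
  stopifnot(length(images) == length(labels),
            length(composition) == 4L, all(composition >= 1L))
  pick <- integer(0)
  for (k in seq_along(CATEGORY_LEVELS)) {
    idx <- which(labels == CATEGORY_LEVELS[k])
    if (length(idx) == 0L)
      stop("no samples of category '", CATEGORY_LEVELS[k],
           "' in the training pool")
    pick <- c(pick, idx[sample.int(length(idx), composition[k],
                                   replace = length(idx) < composition[k])])
  }
  out <- lapply(images[pick], augmentImage, transformProb = transformProb)
  list(images = out, labels = labels[pick])
}

# loss and accuracy of prepared ([0,1]-scaled) images, in memory-bounded
# chunks
.evalPrepared <- function(plan, params, images, labels, chunk = 64L) {
  n <- length(images)
  loss <- 0
  correct <- 0L
  probs <- matrix(NA_real_, n, 4L)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    x <- .stackImages(images[idx])
    p <- .cnnForward(plan, params, x)$probs
    probs[idx, ] <- p
    py <- p[cbind(seq_along(idx), as.integer(labels[idx]))]
    loss <- loss + sum(-log(pmax(py, 1e-12)))
    correct <- correct +
      sum(max.col(p, ties.method = "first") == as.integer(labels[idx]))
  }
  list(loss = loss / n, accuracy = correct / n, probs = probs)
}

#' Train the counting network
#'
#' Stratified mini-batch stochastic gradient descent on the cross-entropy
#' loss, over a staged schedule of training plates: each stage draws its
#' mini-batches from a stated group of plates for a stated number of
#' iterations (the reference protocol: 20000 iterations on the first 5
#' plates, 10000 on the next 5, 5000 on the next 5, then repeated
#' 5000-iteration stages on random sets of 6). The validation plates are
#' evaluated every `evalEvery` iterations; training stops early when the
#' validation loss has not improved for `patience` consecutive evaluations,
#' and the returned network carries the parameters of the best-validation
#' checkpoint. Images are min-max normalized and scaled to \[0, 1\] before
#' entering the network. A fixed seed makes the whole run reproducible.
#'
#' @param net a [CellCountNet-class] (the starting point).
#' @param data a [WellDataset-class] with images, covering the training and
#'   validation plates.
#' @param partition a [SubsetPartition-class]; plate IDs refer to
#'   `wellInfo(data)$plate_id`.
#' @param config a [TrainingConfig-class]; its `stageSchedule` must be
#'   non-empty.
#' @param seed RNG seed for sampling, augmentation and dropout.
#' @param verbose print progress every validation (default FALSE).
#' @return list with `network` (the best-validation [CellCountNet-class]),
#'   `trace` (data.frame of per-iteration training loss and accuracy),
#'   `validation` (data.frame of periodic validation loss and accuracy),
#'   `bestIteration` and `stoppedEarly`.
#' @export
trainNetwork <- function(net, data, partition, config, seed = 1L,
                         verbose = FALSE) {
  stopifnot(is(net, "CellCountNet"), is(data, "WellDataset"),
            is(partition, "SubsetPartition"), is(config, "TrainingConfig"))
  validObject(partition); validObject(config)
  if (!length(config@stageSchedule)) stop("stageSchedule is empty")
  if (!length(partition@trainSubsets) ||
      !length(partition@validationSubsets))
    stop("training and validation plate lists must be non-empty")
  info <- wellInfo(data)
  have <- unique(info$plate_id)
  need <- c(partition@trainSubsets, partition@validationSubsets)
  if (!all(need %in% have))
    stop("plates missing from the dataset: ",
         paste(setdiff(need, have), collapse = ", "))

  set.seed(seed)
  plan <- .cppPlan(net@spec)
  params <- net@params
  prepAll <- lapply(wellImages(data), .prepareImage)
  labsAll <- wellCategories(data)
  byPlate <- split(seq_len(nrow(info)), info$plate_id)
  valIdx <- unlist(byPlate[partition@validationSubsets], use.names = FALSE)
  valImages <- prepAll[valIdx]
  valLabels <- labsAll[valIdx]

  trace <- list()
  valRows <- list()
  iter <- 0L
  bestLoss <- Inf
  bestParams <- params
  bestIter <- 0L
  sinceBest <- 0L
  stopped <- FALSE

  for (stage in config@stageSchedule) {
    if (stopped) break
    sIdx <- unlist(byPlate[stage$subsets], use.names = FALSE)
    if (!length(sIdx))
      stop("stage refers to plates with no wells: ",
           paste(stage$subsets, collapse = ", "))
    pool <- prepAll[sIdx]
    poolLabs <- labsAll[sIdx]
    nIter <- stage$iterations
    for (i in seq_len(nIter)) {
      batch <- sampleMinibatch(pool, poolLabs, config@minibatchComposition,
                               config@transformProb)
      x <- .stackImages(batch$images)
      dropSeed <- sample.int(.Machine$integer.max, 1L)
      step <- .cnnTrainStep(plan, params, x, as.integer(batch$labels),
                            config@learningRate, net@spec@dropoutRate,
                            dropSeed)
      params <- step$params
      iter <- iter + 1L
      trace[[iter]] <- c(iteration = iter, loss = step$loss,
                         accuracy = step$accuracy)
      if (iter %% config@evalEvery == 0L) {
        ev <- .evalPrepared(plan, params, valImages, valLabels)
        valRows[[length(valRows) + 1L]] <-
          c(iteration = iter, loss = ev$loss, accuracy = ev$accuracy)
        if (verbose)
          message(sprintf(
            "iter %d: train loss %.4f acc %.3f | valid loss %.4f acc %.3f",
            iter, step$loss, step$accuracy, ev$loss, ev$accuracy))
        if (ev$loss < bestLoss) {
          bestLoss <- ev$loss
          bestParams <- params
          bestIter <- iter
          sinceBest <- 0L
        } else {
          sinceBest <- sinceBest + 1L
          if (sinceBest >= config@patience) { stopped <- TRUE; break }
        }
      }
    }
  }
  if (iter > 0L && bestIter == 0L) {  # no validation fired: keep final
    bestParams <- params
    bestIter <- iter
  }
  list(network = new("CellCountNet", spec = net@spec, params = bestParams),
       trace = as.data.frame(do.call(rbind, trace)),
       validation = as.data.frame(do.call(rbind, valRows)),
       bestIteration = bestIter,
       stoppedEarly = stopped)
}

#' Predict occupancy categories for well images
#'
#' Applies the trained network, with dropout disabled and no augmentation.
#' Each well gets the 4-category posterior (a softmax, so it sums to 1 and
#' its maximum is at least 0.25), the argmax category, and the highest
#' output h(s) used by the triage.
#'
#' @param net a [CellCountNet-class].
#' @param x a [WellDataset-class] with images, or a list of image matrices.
#' @param normalize min-max normalize and scale images before prediction
#'   (default TRUE; set FALSE if inputs are already prepared to \[0, 1\]).
#' @param chunk prediction batch size (memory bound, default 64).
#' @return data.frame with columns `well_id`, `p0`, `p1`, `p2`, `pgt2`,
#'   `predicted` (factor) and `highest_output`.
#' @export
predictWells <- function(net, x, normalize = TRUE, chunk = 64L) {
  stopifnot(is(net, "CellCountNet"))
  if (is(x, "WellDataset")) {
    images <- wellImages(x)
    ids <- wellInfo(x)$well_id
  } else {
    images <- x
    ids <- if (!is.null(names(x))) names(x)
           else sprintf("well%05d", seq_along(x))
  }
  if (!length(images)) stop("no images to predict")
  side <- net@spec@inputSide
  bad <- which(vapply(images, nrow, integer(1)) != side |
               vapply(images, ncol, integer(1)) != side)
  if (length(bad))
    stop("image size incompatible with the network (expected ", side, " x ",
         side, "): well ", ids[bad[1]])
  if (normalize) images <- lapply(images, .prepareImage)
  plan <- .cppPlan(net@spec)
  n <- length(images)
  probs <- matrix(NA_real_, n, 4L)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    probs[idx, ] <- .cnnForward(plan, net@params,
                                .stackImages(images[idx]))$probs
  }
  data.frame(well_id = ids,
             p0 = probs[, 1], p1 = probs[, 2], p2 = probs[, 3],
             pgt2 = probs[, 4],
             predicted = factor(
               CATEGORY_LEVELS[max.col(probs, ties.method = "first")],
               levels = CATEGORY_LEVELS),
             highest_output = apply(probs, 1, max),
             stringsAsFactors = FALSE)
}

#' Write and read predictions
#'
#' Tab-separated serialization of a prediction table:
#' `well_id  p0  p1  p2  pgt2  predicted  highest_output`.
#'
#' @param predictions data.frame as returned by [predictWells()].
#' @param path TSV path.
#' @return `path` (write) or the prediction data.frame (read).
#' @export
writePredictions <- function(predictions, path) {
  out <- predictions
  out$predicted <- as.character(out$predicted)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(well_id = "character",
                                 predicted = "character"))
  p$predicted <- asCategory(p$predicted)
  p
}
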