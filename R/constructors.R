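# Constructors, accessors and show methods for the S4 classes.

#' Construct a WellGeometry
#'
#' @param shape `"square"` or `"round"`.
#' @param imageSide image side length in pixels (default 511, the native
#'   frame size of the imaging platform).
#' @param wallThickness wall thickness in pixels.
#' @param wallIntensity wall gray level in \[0, 255\].
#' @param backgroundIntensity interior gray level in \[0, 255\].
#' @return a [WellGeometry-class] object.
#' @examples
#' wellGeometry("round", imageSide = 128)
#' @export
wellGeometry <- function(shape = c("square", "round"), imageSide = 511L,
                         wallThickness = max(2, round(imageSide / 64)),
                         wallIntensity = 60, backgroundIntensity = 110) {
  shape <- match.arg(shape)
  new("WellGeometry", shape = shape, imageSide = as.integer(imageSide),
      wallThickness = wallThickness, wallIntensity = wallIntensity,
      backgroundIntensity = backgroundIntensity)
}

#' Construct an OccupancyModel
#'
#' @param lambda mean cells per well; the reference plates are loaded at
#'   roughly 0.2 cells per well so that most occupied wells hold one cell.
#' @param clusterExcess probability that a nonzero count is incremented by
#'   one, emulating the observed excess of multi-cell wells over the pure
#'   Poisson expectation (default 0.15).
#' @param maxRender cap on rendered cells per image (default 5).
#' @return an [OccupancyModel-class] object.
#' @examples
#' occupancyModel(lambda = 0.2)
#' @export
occupancyModel <- function(lambda = 0.2, clusterExcess = 0.15,
                           maxRender = 5L) {
  new("OccupancyModel", lambda = lambda, clusterExcess = clusterExcess,
      maxRender = as.integer(maxRender))
}

#' Construct an ArtifactModel
#'
#' Defaults emulate mildly imperfect bright-field acquisition: occasional
#' debris and defocused frames, a per-image illumination offset and faint
#' pixel noise.
#'
#' @param debrisProb probability a well contains debris (default 0.05).
#' @param defocusProb probability a frame is defocused (default 0.03).
#' @param defocusBlurSigma blur sigma in pixels for defocused frames
#'   (default 3).
#' @param intensityOffsetRange per-image uniform offset range in gray
#'   levels (default `c(-20, 20)`).
#' @param noiseSigma pixel noise standard deviation (default 4).
#' @return an [ArtifactModel-class] object.
#' @examples
#' artifactModel(debrisProb = 0)   # clean plates
#' @export
artifactModel <- function(debrisProb = 0.05, defocusProb = 0.03,
                          defocusBlurSigma = 3,
                          intensityOffsetRange = c(-20, 20),
                          noiseSigma = 4) {
  new("ArtifactModel", debrisProb = debrisProb, defocusProb = defocusProb,
      defocusBlurSigma = defocusBlurSigma,
      intensityOffsetRange = intensityOffsetRange, noiseSigma = noiseSigma)
}

#' Construct a SubsetPartition
#'
#' @param train,validation,test character vectors of plate IDs; the three
#'   must be disjoint. The reference protocol assigns 24 / 4 / 2 plates.
#' @return a [SubsetPartition-class] object.
#' @examples
#' subsetPartition(train = c("p1", "p2"), validation = "p3", test = "p4")
#' @export
subsetPartition <- function(train, validation, test) {
  new("SubsetPartition", trainSubsets = as.character(train),
      validationSubsets = as.character(validation),
      testSubsets = as.character(test))
}

#' Construct a TrainingConfig
#'
#' @param minibatchComposition per-category counts per batch in order
#'   0/1/2/gt2; the reference protocol uses `c(77, 21, 10, 11)` (a batch of
#'   119) and is sensitive to deviations from it.
#' @param stageSchedule list of stages, each `list(iterations=, subsets=)`;
#'   see [referenceSchedule()] for the reference staged schedule.
#' @param learningRate SGD step size (default 0.01).
#' @param evalEvery validation cadence in iterations (default 100).
#' @param patience early-stopping patience in evaluations (default 10).
#' @param transformProb augmentation probability for training batches
#'   (default 0.2).
#' @return a [TrainingConfig-class] object.
#' @export
trainingConfig <- function(minibatchComposition = c(77L, 21L, 10L, 11L),
                           stageSchedule = list(),
                           learningRate = 0.01, evalEvery = 100L,
                           patience = 10L, transformProb = 0.2) {
  new("TrainingConfig",
      minibatchComposition = as.integer(minibatchComposition),
      stageSchedule = stageSchedule, learningRate = learningRate,
      evalEvery = as.integer(evalEvery), patience = as.integer(patience),
      transformProb = transformProb)
}

#' Reference staged training schedule
#'
#' The reference protocol trains in stages over plates: 20000 iterations on
#' the first 5 training plates, 10000 on the next 5, 5000 on the next 5,
#' then repeated 5000-iteration stages each drawing 6 plates at random from
#' all training plates.
#'
#' @param trainPlates character vector of training plate IDs (in order).
#' @param randomStages how many trailing random-6 stages to append
#'   (default 1).
#' @param scale multiply all stage iteration counts by this factor; useful
#'   for scaled-down experiments (default 1).
#' @return a stage list suitable for [trainingConfig()].
#' @export
referenceSchedule <- function(trainPlates, randomStages = 1L, scale = 1) {
  np <- length(trainPlates)
  take <- function(from, n) trainPlates[seq(from, min(from + n - 1L, np))]
  stages <- list(
    list(iterations = round(20000 * scale), subsets = take(1L, 5L)),
    list(iterations = round(10000 * scale), subsets = take(6L, 5L)),
    list(iterations = round(5000 * scale), subsets = take(11L, 5L)))
  stages <- Filter(function(s) length(s$subsets) > 0, stages)
  for (i in seq_len(randomStages))
    stages[[length(stages) + 1L]] <-
      list(iterations = round(5000 * scale),
           subsets = trainPlates[sample.int(np, min(6L, np))])
  stages
}

# ---- accessors ----

#' Manifest accessor for a WellDataset
#' @param x a [WellDataset-class].
#' @return the manifest data.frame (one row per well).
#' @export
wellInfo <- function(x) {
  stopifnot(is(x, "WellDataset"))
  x@info
}

#' Image list accessor for a WellDataset
#' @param x a [WellDataset-class].
#' @return list of numeric matrices (gray levels).
#' @export
wellImages <- function(x) {
  stopifnot(is(x, "WellDataset"))
  x@images
}

#' Category labels of a WellDataset
#' @param x a [WellDataset-class].
#' @return factor of occupancy categories, one per well.
#' @export
wellCategories <- function(x) asCategory(wellInfo(x)$category)

#' Number of wells in a WellDataset
#' @param x a [WellDataset-class].
#' @return integer well count.
#' @export
nWells <- function(x) nrow(wellInfo(x))

#' Subset a WellDataset by well index
#' @param x a [WellDataset-class]; \code{i} integer or logical index.
#' @param i,j,...,drop standard subsetting arguments (only \code{i} is used).
#' @export
setMethod("[", "WellDataset", function(x, i, j, ..., drop = FALSE) {
  info <- x@info[i, , drop = FALSE]
  rownames(info) <- NULL
  imgs <- if (length(x@images)) x@images[i] else list()
  new("WellDataset", images = imgs, info = info)
})

#' Concatenate WellDatasets
#' @param x a [WellDataset-class].
#' @param ... further [WellDataset-class] objects.
#' @export
setMethod("c", "WellDataset", function(x, ...) {
  all <- c(list(x), list(...))
  new("WellDataset",
      images = do.call(c, lapply(all, wellImages)),
      info = do.call(rbind, lapply(all, wellInfo)))
})

#' Counts accessor for a ConfusionMatrix
#' @param x a [ConfusionMatrix-class].
#' @return the 4x4 integer count matrix (rows = truth, cols = predicted).
#' @export
cmCounts <- function(x) {
  stopifnot(is(x, "ConfusionMatrix"))
  x@counts
}

#' Estimated rate accessor for a PoissonOccupancyFit
#' @param x a [PoissonOccupancyFit-class].
#' @return the ML estimate of lambda.
#' @export
lambdaHat <- function(x) {
  stopifnot(is(x, "PoissonOccupancyFit"))
  x@lambdaHat
}

#' Ambiguous well IDs of a TriageResult
#' @param x a [TriageResult-class].
#' @return character vector of well IDs flagged ambiguous.
#' @export
ambiguousWells <- function(x) {
  stopifnot(is(x, "TriageResult"))
  x@ambiguousIds
}

#' Retained well IDs of a TriageResult
#' @param x a [TriageResult-class].
#' @return character vector of retained well IDs.
#' @export
retainedWells <- function(x) {
  stopifnot(is(x, "TriageResult"))
  x@retainedIds
}

# ---- show methods ----

setMethod("show", "WellGeometry", function(object) {
  cat(sprintf("WellGeometry: %s well, %d x %d px, wall %.3g px (gray %g on %g)\n",
              object@shape, object@imageSide, object@imageSide,
              object@wallThickness, object@wallIntensity,
              object@backgroundIntensity))
})

setMethod("show", "OccupancyModel", function(object) {
  cat(sprintf("OccupancyModel: lambda = %g, clusterExcess = %g, maxRender = %d\n",
              object@lambda, object@clusterExcess, object@maxRender))
})

setMethod("show", "WellDataset", function(object) {
  tab <- table(asCategory(object@info$category))
  cat(sprintf("WellDataset: %d wells on %d plate(s)%s\n",
              nrow(object@info), length(unique(object@info$plate_id)),
              if (length(object@images)) " (images in memory)" else ""))
  cat("  categories:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf("NetworkSpec: %d-px input, %d layers, %s weights (dropout %.2f)\n",
              object@inputSide, sum(!vapply(object@layers, function(l)
                l@kind == "input", logical(1))),
              format(countWeights(object), big.mark = ","),
              object@dropoutRate))
})

setMethod("show", "CellCountNet", function(object) {
  cat(sprintf("CellCountNet: input %d px, %s weights (+ %s biases)\n",
              object@spec@inputSide,
              format(countWeights(object@spec), big.mark = ","),
              format(countBiases(object@spec), big.mark = ",")))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = truth, cols = predicted):\n")
  print(object@counts)
  cat(sprintf("  n = %d, overall concordance = %.5f\n", sum(object@counts),
              sum(diag(object@counts)) / sum(object@counts)))
})

setMethod("show", "PoissonOccupancyFit", function(object) {
  cat(sprintf("PoissonOccupancyFit: lambdaHat = %.6f (logLik %.2f, n = %d)\n",
              object@lambdaHat, object@logLik, sum(object@counts)))
})

setMethod("show", "TriageResult", function(object) {
  cat(sprintf("TriageResult: t = %.4g, %d ambiguous / %d wells (%.2f%%), policy %s",
              object@threshold, length(object@ambiguousIds),
              length(object@ambiguousIds) + length(object@retainedIds),
              100 * object@realizedProportion, object@policy))
  if (!is.na(object@concordance))
    cat(sprintf(", concordance %.4f", object@concordance))
  cat("\n")
})
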