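# S4 classes for the nanowell pipeline. Validity methods enforce the
# invariants the rest of the package assumes; user code should go through
# the constructor functions (wellGeometry(), occupancyModel(), ...) and the
# accessors rather than touching slots.

#' WellGeometry: physical layout of one imaged well
#'
#' Describes the square or round nanoliter well as it appears in one
#' grayscale frame: image side length, wall thickness and the gray levels of
#' wall and background.
#'
#' @slot shape `"square"` or `"round"`.
#' @slot imageSide side length of the square image in pixels (>= 64).
#' @slot wallThickness wall thickness in pixels; the wall must fit inside
#'   the image.
#' @slot wallIntensity gray level of the wall, in \[0, 255\].
#' @slot backgroundIntensity gray level of the well interior, in \[0, 255\].
#' @seealso [wellGeometry()]
#' @export
setClass("WellGeometry",
  representation(shape = "character", imageSide = "integer",
                 wallThickness = "numeric", wallIntensity = "numeric",
                 backgroundIntensity = "numeric"))

setValidity("WellGeometry", function(object) {
  msg <- character()
  if (!object@shape %in% c("square", "round"))
    msg <- c(msg, "shape must be 'square' or 'round'")
  if (object@imageSide < 64L)
    msg <- c(msg, "imageSide must be at least 64 pixels")
  if (object@wallThickness < 0 ||
      2 * object@wallThickness >= object@imageSide)
    msg <- c(msg, "wall must fit inside the image")
  ints <- c(object@wallIntensity, object@backgroundIntensity)
  if (any(ints < 0) || any(ints > 255))
    msg <- c(msg, "intensities must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' OccupancyModel: how many cells land in a well
#'
#' Cell counts per well follow a Poisson(lambda) law, optionally modified by
#' a cluster excess: with probability `clusterExcess` a nonzero draw is
#' incremented by one, emulating the observed surplus of multi-cell wells
#' when cells divide or adhere in clusters. With `clusterExcess = 0` the
#' counts are exactly Poisson(lambda).
#'
#' @slot lambda mean cells per well (Poisson rate, >= 0).
#' @slot clusterExcess probability in \[0, 1\] that a nonzero draw is
#'   incremented by one.
#' @slot maxRender integer cap on the number of cells actually drawn into an
#'   image; counts above the cap are still labeled `gt2`.
#' @seealso [occupancyModel()], [sampleCellCount()]
#' @export
setClass("OccupancyModel",
  representation(lambda = "numeric", clusterExcess = "numeric",
                 maxRender = "integer"))

setValidity("OccupancyModel", function(object) {
  msg <- character()
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@clusterExcess < 0 || object@clusterExcess > 1)
    msg <- c(msg, "clusterExcess must lie in [0, 1]")
  if (object@maxRender < 1L) msg <- c(msg, "maxRender must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ArtifactModel: imaging imperfections of real plates
#'
#' Controls the non-cell structure of rendered images: debris probability,
#' defocus (whole-image Gaussian blur) probability and strength, a per-image
#' uniform intensity offset (the illumination drift that motivates min-max
#' normalization) and pixel-wise Gaussian noise.
#'
#' @slot debrisProb probability in \[0, 1\] that a well contains debris.
#' @slot defocusProb probability in \[0, 1\] that a frame is defocused.
#' @slot defocusBlurSigma Gaussian blur sigma in pixels for defocused frames.
#' @slot intensityOffsetRange length-2 numeric; a per-image offset in gray
#'   levels is drawn uniformly from this range.
#' @slot noiseSigma standard deviation of additive pixel noise (gray levels).
#' @seealso [artifactModel()], [renderWell()]
#' @export
setClass("ArtifactModel",
  representation(debrisProb = "numeric", defocusProb = "numeric",
                 defocusBlurSigma = "numeric",
                 intensityOffsetRange = "numeric", noiseSigma = "numeric"))

setValidity("ArtifactModel", function(object) {
  msg <- character()
  p <- c(object@debrisProb, object@defocusProb)
  if (any(p < 0) || any(p > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@defocusBlurSigma < 0 || object@noiseSigma < 0)
    msg <- c(msg, "sigmas must be >= 0")
  if (length(object@intensityOffsetRange) != 2L ||
      diff(object@intensityOffsetRange) < 0)
    msg <- c(msg, "intensityOffsetRange must be an increasing length-2 range")
  if (length(msg)) msg else TRUE
})

#' WellDataset: images plus their per-well manifest
#'
#' A collection of well images together with a manifest data.frame holding
#' one record per well: `plate_id`, `well_id`, `filename`, `count`,
#' `category`, `debris`, `defocus`. One object can hold one plate or the
#' concatenation of several.
#'
#' @slot images list of numeric matrices (gray levels, one per well), or an
#'   empty list when only the manifest is carried.
#' @slot info the manifest data.frame.
#' @seealso [generatePlate()], [loadDataset()], [wellInfo()]
#' @export
setClass("WellDataset",
  representation(images = "list", info = "data.frame"))

setValidity("WellDataset", function(object) {
  msg <- character()
  need <- c("plate_id", "well_id", "filename", "count", "category",
            "debris", "defocus")
  miss <- setdiff(need, names(object@info))
  if (length(miss))
    msg <- c(msg, paste("manifest lacks columns:", paste(miss, collapse = ", ")))
  if (length(object@images) > 0 &&
      length(object@images) != nrow(object@info))
    msg <- c(msg, "number of images must match manifest records")
  if ("category" %in% names(object@info)) {
    bad <- !as.character(object@info$category) %in% CATEGORY_LEVELS
    if (any(bad))
      msg <- c(msg, paste("invalid categories in rows:",
                          paste(which(bad), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' SubsetPartition: plates assigned to training, validation and test
#'
#' The dataset is organized in plates (subsets) of wells; whole plates are
#' assigned to exactly one of the three roles. The reference protocol uses
#' 24 training, 4 validation and 2 test plates.
#'
#' @slot trainSubsets character vector of plate IDs used for training.
#' @slot validationSubsets plate IDs used for validation / early stopping.
#' @slot testSubsets plate IDs held out for the final test.
#' @seealso [subsetPartition()]
#' @export
setClass("SubsetPartition",
  representation(trainSubsets = "character",
                 validationSubsets = "character",
                 testSubsets = "character"))

setValidity("SubsetPartition", function(object) {
  all3 <- c(object@trainSubsets, object@validationSubsets,
            object@testSubsets)
  if (anyDuplicated(all3))
    "train, validation and test plate lists must be disjoint"
  else TRUE
})

#' LayerSpec: one layer of the counting network
#'
#' Declarative description of a single layer, carrying the node and weight
#' bookkeeping from which the model and its parameter count are built.
#'
#' @slot kind one of `"input"`, `"lrn"`, `"max_pool"`, `"conv"`,
#'   `"fully_connected"`, `"output"`.
#' @slot label human-readable layer name (e.g. `"conv3"`).
#' @slot outChannels number of channels (feature maps) of the output.
#' @slot spatialSize side length of the (square) output feature map; 1 for
#'   fully connected layers.
#' @slot kernel for conv layers, the kernel shape `(h, w, in_ch, out_ch)`;
#'   empty otherwise.
#' @slot weightShape element counts of the weight tensor (empty for layers
#'   without weights).
#' @slot stride spatial stride (1 for non-strided layers).
#' @slot fanIn number of input nodes feeding one unit, used for He
#'   initialization (variance 2 / fanIn).
#' @export
setClass("LayerSpec",
  representation(kind = "character", label = "character",
                 outChannels = "integer", spatialSize = "integer",
                 kernel = "integer", weightShape = "integer",
                 stride = "integer", fanIn = "integer"))

setValidity("LayerSpec", function(object) {
  msg <- character()
  kinds <- c("input", "lrn", "max_pool", "conv", "fully_connected", "output")
  if (!object@kind %in% kinds)
    msg <- c(msg, paste("unknown layer kind:", object@kind))
  if (object@kind == "conv" && length(object@kernel) != 4L)
    msg <- c(msg, "conv layers need a length-4 kernel shape")
  if (length(object@kernel) == 4L &&
      length(object@weightShape) > 0 &&
      prod(object@kernel) != prod(object@weightShape))
    msg <- c(msg, "kernel and weightShape element counts disagree")
  if (length(msg)) msg else TRUE
})

#' NetworkSpec: the full 18-layer architecture
#'
#' Ordered list of [LayerSpec-class] objects describing the counting
#' network: input, then local response normalization, max pooling and
#' convolution stages, then two fully connected layers and a 4-node softmax
#' output. Built by [tableSpec()], possibly at a scaled-down input side for
#' desk-scale experiments.
#'
#' @slot layers ordered list of [LayerSpec-class] objects.
#' @slot inputSide input image side length in pixels.
#' @slot dropoutRate dropout probability on the fully connected layers
#'   during training (default 0.3).
#' @slot lrnRadius,lrnAlpha,lrnBeta,lrnBias local-response-normalization
#'   hyperparameters (cross-channel window radius and scaling).
#' @seealso [tableSpec()], [countWeights()], [layerShapes()]
#' @export
setClass("NetworkSpec",
  representation(layers = "list", inputSide = "integer",
                 dropoutRate = "numeric", lrnRadius = "integer",
                 lrnAlpha = "numeric", lrnBeta = "numeric",
                 lrnBias = "numeric"))

setValidity("NetworkSpec", function(object) {
  msg <- character()
  if (!all(vapply(object@layers, is, logical(1), "LayerSpec")))
    msg <- c(msg, "layers must all be LayerSpec objects")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  nl <- length(object@layers)
  if (nl > 0) {
    last <- object@layers[[nl]]
    if (last@kind != "output" || last@outChannels != 4L)
      msg <- c(msg, "the final layer must be a 4-node output layer")
  }
  if (length(msg)) msg else TRUE
})

#' CellCountNet: a spec plus its parameters
#'
#' A concrete network: the [NetworkSpec-class] plus one numeric parameter
#' set (weights and biases per learnable layer). Produced by
#' [buildNetwork()] and updated by [trainNetwork()].
#'
#' @slot spec the [NetworkSpec-class].
#' @slot params list with one element per learnable layer, each a list with
#'   `W` (weight matrix, out x fan-in) and `b` (bias vector).
#' @seealso [buildNetwork()], [predictWells()]
#' @export
setClass("CellCountNet",
  representation(spec = "NetworkSpec", params = "list"))

#' TrainingConfig: stratified mini-batch SGD protocol
#'
#' @slot minibatchComposition integer vector of per-category sample counts
#'   in one mini-batch, in category order 0/1/2/gt2 (default
#'   `c(77, 21, 10, 11)`, total 119).
#' @slot stageSchedule list of stages, each a list with `iterations` (int)
#'   and `subsets` (character vector of training plate IDs drawn from during
#'   that stage).
#' @slot learningRate SGD step size (default 0.01).
#' @slot evalEvery validate every this many iterations (default 100).
#' @slot patience stop when validation loss has not improved for this many
#'   consecutive evaluations (default 10).
#' @slot transformProb augmentation probability applied when sampling
#'   training batches (default 0.2).
#' @seealso [trainingConfig()], [referenceSchedule()], [trainNetwork()]
#' @export
setClass("TrainingConfig",
  representation(minibatchComposition = "integer", stageSchedule = "list",
                 learningRate = "numeric", evalEvery = "integer",
                 patience = "integer", transformProb = "numeric"))

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (length(object@minibatchComposition) != 4L ||
      any(object@minibatchComposition < 1L))
    msg <- c(msg, "minibatchComposition must be 4 positive counts")
  ok <- vapply(object@stageSchedule, function(s)
    is.list(s) && all(c("iterations", "subsets") %in% names(s)) &&
      s$iterations >= 0, logical(1))
  if (!all(ok))
    msg <- c(msg, "each stage needs 'iterations' and 'subsets'")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@transformProb < 0 || object@transformProb > 1)
    msg <- c(msg, "transformProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' TriageResult: partition of wells into ambiguous and retained
#'
#' Output of [flagAmbiguous()] / [concordanceWithTriage()]: every well falls
#' in exactly one of the ambiguous (highest output below threshold) or
#' retained sets.
#'
#' @slot threshold the applied highest-output cutoff t.
#' @slot policy `"resolve_by_human"`, `"exclude"`, or `"none"` when no
#'   concordance was computed.
#' @slot ambiguousIds well IDs with h(s) < t.
#' @slot retainedIds the complementary well IDs.
#' @slot realizedProportion fraction of wells flagged ambiguous.
#' @slot concordance concordance rate under the policy (NA when truth was
#'   not supplied).
#' @export
setClass("TriageResult",
  representation(threshold = "numeric", policy = "character",
                 ambiguousIds = "character", retainedIds = "character",
                 realizedProportion = "numeric", concordance = "numeric"))

setValidity("TriageResult", function(object) {
  msg <- character()
  if (length(intersect(object@ambiguousIds, object@retainedIds)) > 0)
    msg <- c(msg, "ambiguous and retained sets must be disjoint")
  if (!is.na(object@concordance) &&
      (object@concordance < 0 || object@concordance > 1))
    msg <- c(msg, "concordance must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ConfusionMatrix: 4x4 technician-versus-classifier counts
#'
#' Rows are the technician (truth) categories, columns the predicted
#' categories; entry (i, j) counts wells with truth i and prediction j. The
#' source object for sensitivities, positive predictive values and the
#' discordance matrix.
#'
#' @slot counts 4x4 non-negative integer matrix with category dimnames.
#' @seealso [confusionMatrix()], [categoryRates()], [discordanceMatrix()]
#' @export
setClass("ConfusionMatrix", representation(counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  m <- object@counts
  msg <- character()
  if (!all(dim(m) == c(4L, 4L))) msg <- c(msg, "counts must be 4x4")
  if (any(m < 0) || any(m != floor(m)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' PoissonOccupancyFit: censored-Poisson estimate of well loading
#'
#' Maximum-likelihood fit of the Poisson rate lambda (mean cells per well)
#' from the categorized counts (n0, n1, n2, n_gt2), with the `gt2` class
#' treated as right-censored.
#'
#' @slot lambdaHat the ML estimate (>= 0).
#' @slot logLik multinomial log-likelihood at the optimum.
#' @slot counts the four input counts.
#' @seealso [fitPoissonOccupancy()], [expectedPoissonProportions()]
#' @export
setClass("PoissonOccupancyFit",
  representation(lambdaHat = "numeric", logLik = "numeric",
                 counts = "numeric"))
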