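# Declarative description of the 18-layer counting network. The printed
# architecture (at a 511-px input) is:
#   input 511x511 -> lrn1 -> maxpool1 (256) -> conv1..2 (32 ch, 256)
#   -> maxpool2 (128) -> lrn2 -> conv3 (stride 2, 64 ch, 64) -> conv4..5
#   -> maxpool3 (32) -> lrn3 -> conv6 (stride 2, 32 ch, 16) -> conv7..8
#   -> maxpool4 (8) -> lrn4 -> fc1 (32) -> fc2 (512) -> output (4),
# totalling 468,768 weight elements (biases counted separately). Strides
# and padding are the unique minimal assignment reproducing those printed
# shapes: all pools 2x2 stride 2 with ceil (size-preserving) padding,
# conv3 and conv6 stride 2, all other convolutions stride 1, same padding.

.layerSpec <- function(kind, label, outChannels, spatialSize,
                       kernel = integer(0), weightShape = integer(0),
                       stride = 1L, fanIn = 0L) {
  new("LayerSpec", kind = kind, label = label,
      outChannels = as.integer(outChannels),
      spatialSize = as.integer(spatialSize),
      kernel = as.integer(kernel), weightShape = as.integer(weightShape),
      stride = as.integer(stride), fanIn = as.integer(fanIn))
}

.ceilHalf <- function(n) as.integer(ceiling(n / 2))

#' Build the counting-network architecture
#'
#' Constructs the 18-layer [NetworkSpec-class] (8 convolution, 4 max
#' pooling, 4 local response normalization, 2 fully connected layers plus
#' the 4-node softmax output) for a given input side. At the native
#' `inputSide = 511` the layer shapes and the 468,768-element weight count
#' match the published architecture exactly. Smaller inputs keep the
#' channel plan and kernel sizes and recompute the first fully connected
#' layer's weight shape from the resulting feature-map size, which is the
#' scaled-spec rule used for desk-scale experiments.
#'
#' @param inputSide input image side length in pixels (default 511; must be
#'   at least 64).
#' @param dropoutRate dropout probability on fully connected layers during
#'   training (default 0.3).
#' @param lrnRadius,lrnAlpha,lrnBeta,lrnBias local-response-normalization
#'   hyperparameters (cross-channel window radius 2, alpha 1e-4, beta 0.75,
#'   bias 1 by default).
#' @return a [NetworkSpec-class].
#' @examples
#' spec <- tableSpec()
#' countWeights(spec)   # 468768
#' @export
tableSpec <- function(inputSide = 511L, dropoutRate = 0.3,
                      lrnRadius = 2L, lrnAlpha = 1e-4, lrnBeta = 0.75,
                      lrnBias = 1.0) {
  s <- as.integer(inputSide)
  if (s < 64L) stop("inputSide must be at least 64 pixels")
  layers <- list(.layerSpec("input", "input", 1L, s))
  addLrn <- function(label, ch, sp)
    layers[[length(layers) + 1L]] <<- .layerSpec("lrn", label, ch, sp)
  addPool <- function(label, ch, sp)
    layers[[length(layers) + 1L]] <<- .layerSpec("max_pool", label, ch, sp,
                                                 stride = 2L)
  addConv <- function(label, inCh, outCh, sp, stride)
    layers[[length(layers) + 1L]] <<- .layerSpec(
      "conv", label, outCh, sp, kernel = c(5L, 5L, inCh, outCh),
      weightShape = c(5L, 5L, inCh, outCh), stride = stride,
      fanIn = 25L * inCh)
  addLrn("lrn1", 1L, s)
  s1 <- .ceilHalf(s); addPool("maxpool1", 1L, s1)
  addConv("conv1", 1L, 32L, s1, 1L)
  addConv("conv2", 32L, 32L, s1, 1L)
  s2 <- .ceilHalf(s1); addPool("maxpool2", 32L, s2)
  addLrn("lrn2", 32L, s2)
  s3 <- .ceilHalf(s2)
  addConv("conv3", 32L, 64L, s3, 2L)
  addConv("conv4", 64L, 64L, s3, 1L)
  addConv("conv5", 64L, 64L, s3, 1L)
  s4 <- .ceilHalf(s3); addPool("maxpool3", 64L, s4)
  addLrn("lrn3", 64L, s4)
  s5 <- .ceilHalf(s4)
  addConv("conv6", 64L, 32L, s5, 2L)
  addConv("conv7", 32L, 32L, s5, 1L)
  addConv("conv8", 32L, 32L, s5, 1L)
  s6 <- .ceilHalf(s5); addPool("maxpool4", 32L, s6)
  addLrn("lrn4", 32L, s6)
  fcIn <- 32L * s6 * s6
  layers[[length(layers) + 1L]] <- .layerSpec(
    "fully_connected", "fc1", 32L, 1L, weightShape = c(32L, fcIn),
    fanIn = fcIn)
  layers[[length(layers) + 1L]] <- .layerSpec(
    "fully_connected", "fc2", 512L, 1L, weightShape = c(512L, 32L),
    fanIn = 32L)
  layers[[length(layers) + 1L]] <- .layerSpec(
    "output", "output", 4L, 1L, weightShape = c(4L, 512L), fanIn = 512L)
  new("NetworkSpec", layers = layers, inputSide = s,
      dropoutRate = dropoutRate, lrnRadius = as.integer(lrnRadius),
      lrnAlpha = lrnAlpha, lrnBeta = lrnBeta, lrnBias = lrnBias)
}

# minimal architecture (input flattened straight into the 4-node softmax);
# used to exercise the network machinery at trivial scale
.minimalSpec <- function(inputSide = 64L, dropoutRate = 0) {
  s <- as.integer(inputSide)
  layers <- list(
    .layerSpec("input", "input", 1L, s),
    .layerSpec("output", "output", 4L, 1L,
               weightShape = c(4L, s * s), fanIn = s * s))
  new("NetworkSpec", layers = layers, inputSide = s,
      dropoutRate = dropoutRate, lrnRadius = 2L, lrnAlpha = 1e-4,
      lrnBeta = 0.75, lrnBias = 1.0)
}

#' Count the weight elements of an architecture
#'
#' Sums the element counts of all weight tensors, excluding bias terms
#' (the convention of the published total, 468,768 at the native input
#' side). [countBiases()] reports the bias count separately.
#'
#' @param spec a [NetworkSpec-class].
#' @return integer total number of weight elements.
#' @examples
#' countWeights(tableSpec())          # 468768
#' countWeights(tableSpec(128))       # scaled spec: smaller fc1
#' @export
countWeights <- function(spec) {
  stopifnot(is(spec, "NetworkSpec"))
  sum(vapply(spec@layers, function(l)
    if (length(l@weightShape)) prod(l@weightShape) else 0, numeric(1)))
}

#' Count the bias terms of an architecture
#'
#' @param spec a [NetworkSpec-class].
#' @return integer number of bias parameters (one per output channel or
#'   node of each learnable layer).
#' @export
countBiases <- function(spec) {
  stopifnot(is(spec, "NetworkSpec"))
  sum(vapply(spec@layers, function(l)
    if (length(l@weightShape)) as.numeric(l@outChannels) else 0, numeric(1)))
}

#' Per-layer shape table of an architecture
#'
#' @param spec a [NetworkSpec-class].
#' @return data.frame with one row per layer: `label`, `kind`, `channels`,
#'   `spatial`, `nodes` (channels x spatial^2) and `weights` (weight
#'   element count).
#' @examples
#' layerShapes(tableSpec())
#' @export
layerShapes <- function(spec) {
  stopifnot(is(spec, "NetworkSpec"))
  rows <- lapply(spec@layers, function(l) {
    sp <- if (l@kind %in% c("fully_connected", "output")) 1L else l@spatialSize
    data.frame(label = l@label, kind = l@kind, channels = l@outChannels,
               spatial = sp,
               nodes = as.numeric(l@outChannels) * as.numeric(sp)^2,
               weights = if (length(l@weightShape))
                 prod(l@weightShape) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# SAME-padding bookkeeping: output side, total padding split with the
# extra pixel at the end
.samePad <- function(inSide, k, stride) {
  out <- as.integer(ceiling(inSide / stride))
  total <- max((out - 1L) * stride + k - inSide, 0L)
  list(out = out, beg = total %/% 2L)
}

# compile a NetworkSpec into the flat integer plan the C++ engine executes
.cppPlan <- function(spec) {
  layers <- list()
  paramIdx <- 0L
  prevCh <- 1L
  prevSide <- spec@inputSide
  for (l in spec@layers) {
    if (l@kind == "input") { prevCh <- 1L; prevSide <- l@spatialSize; next }
    entry <- list(label = l@label)
    if (l@kind == "lrn") {
      entry$kind <- 1L
      entry$out_ch <- prevCh; entry$out_side <- prevSide
    } else if (l@kind == "max_pool") {
      p <- .samePad(prevSide, 2L, 2L)
      if (p$out != l@spatialSize)
        stop("shape mismatch at ", l@label, ": pooling ", prevSide,
             " gives ", p$out, " but the spec declares ", l@spatialSize)
      entry$kind <- 2L
      entry$k <- 2L; entry$stride <- 2L; entry$pad <- p$beg
      entry$in_side <- prevSide
      entry$out_ch <- prevCh; entry$out_side <- p$out
      prevSide <- p$out
    } else if (l@kind == "conv") {
      if (l@kernel[3] != prevCh)
        stop("shape mismatch between ", l@label, " (expects ", l@kernel[3],
             " channels) and its input layer (", prevCh, " channels)")
      p <- .samePad(prevSide, l@kernel[1], l@stride)
      if (p$out != l@spatialSize)
        stop("shape mismatch at ", l@label, ": stride ", l@stride, " over ",
             prevSide, " gives ", p$out, " but the spec declares ",
             l@spatialSize)
      paramIdx <- paramIdx + 1L
      entry$kind <- 3L
      entry$k <- l@kernel[1]; entry$stride <- l@stride; entry$pad <- p$beg
      entry$in_side <- prevSide; entry$in_ch <- prevCh
      entry$out_ch <- l@outChannels; entry$out_side <- p$out
      entry$param <- paramIdx
      prevCh <- l@outChannels; prevSide <- p$out
    } else {                       # fully_connected or output
      inNodes <- prevCh * prevSide * prevSide
      if (l@weightShape[2] != inNodes)
        stop("shape mismatch at ", l@label, ": weight expects ",
             l@weightShape[2], " inputs but the previous layer provides ",
             inNodes, " nodes")
      paramIdx <- paramIdx + 1L
      entry$kind <- if (l@kind == "output") 5L else 4L
      entry$in_nodes <- inNodes; entry$out_ch <- l@outChannels
      entry$out_side <- 1L
      entry$param <- paramIdx
      entry$dropout <- l@kind == "fully_connected"
      prevCh <- l@outChannels; prevSide <- 1L
    }
    layers[[length(layers) + 1L]] <- entry
  }
  list(layers = layers, lrn_radius = spec@lrnRadius,
       lrn_alpha = spec@lrnAlpha, lrn_beta = spec@lrnBeta,
       lrn_bias = spec@lrnBias)
}
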