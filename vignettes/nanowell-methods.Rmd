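---
title: "Counting cells in nanoliter wells: model, training protocol and triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cells in nanoliter wells: model, training protocol and triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanowell)
```

## The problem

Single-cell experiments distribute unstained, label-free cells into plates
of thousands of nanoliter wells (3,984 wells on the plates this package
models) and need to know, for every well, whether it received 0, 1, 2 or
more than 2 cells. Wells are imaged as 511 × 511 pixel 8-bit grayscale
frames. Manual counting is the accuracy gold standard but takes tens of
minutes per plate; `nanowell` implements an automated counter: a
convolutional neural network that maps a raw well image — no segmentation,
no background subtraction, no well-boundary detection — to a posterior
probability over the four occupancy categories, plus a confidence-threshold
triage that routes the small set of genuinely ambiguous wells back to a
human.

## The classifier

The network (built by `tableSpec()`) has, apart from input and output, 18
layers: 8 convolutions, 4 max poolings, 4 cross-channel local response
normalizations (LRN) and 2 fully connected layers. At the native 511-px
input the stages are

| stage | output shape |
|---|---|
| input, lrn1 | 1 × 511 × 511 |
| maxpool1, conv1, conv2 | 32 × 256 × 256 |
| maxpool2, lrn2 | 32 × 128 × 128 |
| conv3 (stride 2), conv4, conv5 | 64 × 64 × 64 |
| maxpool3, lrn3 | 64 × 32 × 32 |
| conv6 (stride 2), conv7, conv8 | 32 × 16 × 16 |
| maxpool4, lrn4 | 32 × 8 × 8 |
| fc1 | 32 |
| fc2 | 512 |
| output (softmax) | 4 |

All convolutions use 5 × 5 kernels; `countWeights(tableSpec())` is 468,768
weight elements, with biases (900 of them) counted separately,
matching the published parameter census of this architecture. Strides and
padding are not part of that census and were inferred as the unique minimal
assignment that reproduces every printed stage shape: every pool is 2 × 2
with stride 2 and ceiling ("same") padding, conv3 and conv6 use stride 2,
and all other convolutions are stride-1, size-preserving. The fully
connected stage is 2048 → 32 → 512 → 4 — the 32 → 512 expansion is unusual
but is exactly what the printed weight shapes (32 × 32 × 8 × 8, 512 × 32,
4 × 512) specify, and it is required to reach the 468,768 total.

Activations are rectified linear everywhere except the softmax output.
Dropout (rate 0.3) acts on both fully connected layers during training
only; prediction is deterministic. Weights are He-initialized
(normal with mean 0, variance 2/N~in~, N~in~ the fan-in node count), biases
start at zero.

The LRN hyperparameters are not published; the package uses the
conventional cross-channel defaults (window radius 2, α = 10^-4^, β = 0.75,
bias 1), exposed as arguments of `tableSpec()`. The first LRN is applied
directly to the raw input, which is unconventional but follows the printed
layer order. Inverted dropout scaling (division by the keep probability at
training time) is used so that no rescaling is needed at prediction.

### Implementation

No deep-learning framework is involved: the forward and backward passes
(im2col convolution over BLAS matrix products, max pooling with argmax
bookkeeping, LRN with its exact analytic gradient, softmax cross-entropy)
are implemented in C++ (RcppArmadillo), double precision and single
threaded, so that a training step is a pure function of parameters, batch
and seed. The backward pass is verified against central finite differences
in the test suite (relative error below 10^-4^ on every layer; observed
around 10^-7^).

## Training protocol

Training is plain stochastic gradient descent (no momentum — none is
claimed for the reference protocol) on the cross-entropy loss, with a
learning rate defaulting to 0.01 (not published; exposed in
`trainingConfig()`).

Two protocol features matter more than the optimizer:

* **Stratified mini-batches.** A batch of 119 samples contains exactly 77,
  21, 10 and 11 samples of categories 0, 1, 2 and >2 — heavily
  over-representing the rare multi-cell wells relative to their ~82/14/3/1%
  plate frequencies. The reference protocol reports that deviating from
  this composition degrades the result, so `sampleMinibatch()` treats the
  composition as a contract: batches always have exactly the configured
  counts, with within-category uniform sampling, falling back to sampling
  with replacement when a category has fewer distinct members than
  requested (at Poisson loading λ ≈ 0.2 a single plate may hold only a
  handful of >2 wells).
* **Staged schedules.** Plates ("subsets") enter training in stages —
  20,000 iterations on the first 5 plates, 10,000 on the next 5, 5,000 on
  the next 5, then repeated 5,000-iteration stages on random sets of 6 of
  all 24 training plates (`referenceSchedule()`). This is a memory-bounded
  curriculum, not a statistical device; `trainNetwork()` accepts any stage
  list, and desk-scale runs use a single stage.

Each drawn training image is augmented with probability 0.2 by one
transform chosen uniformly among mirror flip and rotations by 90, 180 and
270 degrees. "Inverted" is read as the mirror reflection, since it is
listed alongside rotations as a geometric augmentation; the alternative
gray-level inversion reading remains available (`invert = "intensity"`).
Augmentation permutes pixels, so labels and intensity histograms are
untouched.

Every stored image is min-max normalized (minimum to 0, maximum to 255) to
absorb per-image illumination differences; normalization is per image (the
reference protocol does not state per-image versus per-plate; per-image is
what the stated motivation — frame-to-frame light variation — implies).
Constant images, which carry no content, map to all zeros rather than
dividing by zero. Immediately before entering the network, pixels are
further scaled to [0, 1]; this is standard conditioning and does not alter
the stored-image contract.

Validation loss is evaluated every 100 iterations (configurable), and
training stops early when it has not improved for 10 consecutive
evaluations; the returned model is the best-validation checkpoint. The
reference protocol states only that learning was stopped before
overfitting; validation *loss* rather than accuracy is used here because it
is the quantity the optimizer targets and it moves more smoothly at these
batch sizes.

## The enhanced system: confidence triage

The softmax maximum h(s) — the "highest output" — is a usable confidence
score: wells the classifier gets wrong have markedly lower h(s) than wells
it gets right (`confidenceSeparationTest()` makes this a Mann-Whitney U
test on log h). The enhanced system fixes a threshold t and declares the
set {s : h(s) < t} ambiguous (strict inequality, exactly as the set-builder
definition; ties at t are retained). Ambiguous wells are either re-judged
by a technician — assumed thereafter correct — or excluded from the
experiment; `concordanceWithTriage()` implements both policies, and
`concordanceCurve()` sweeps the accuracy/workload trade-off.

In practice one chooses the workload, not the threshold:
`thresholdForProportion()` returns the largest observed-h threshold whose
realized ambiguous fraction does not exceed the target proportion. The
never-overshoot convention was chosen because the human review workload is
the binding constraint; with heavily tied h values the realized fraction
can undershoot the target, never exceed it. Since a 4-class softmax maximum
is at least 0.25, any threshold at or below 0.25 flags nothing.

## Synthetic plates

The real well images are not publicly deposited, so the package ships a
generator (`generatePlate()`) that reproduces the statistical structure the
method depends on, and the whole pipeline is exercised end to end on its
output.

* **Occupancy.** Counts are Poisson(λ) with λ defaulting to 0.2 — the
  benchmark plates' estimated loading is λ = 0.202247 — modified by a
  *cluster excess*: with probability `clusterExcess` (default 0.15) a
  nonzero draw is incremented by one. This emulates the observed surplus of
  2-cell and >2-cell wells over the Poisson expectation (cells divide, or
  adhere in clusters) with a single interpretable parameter, rather than a
  mechanistic clustered point process the data would not identify. With
  `clusterExcess = 0` counts are exactly Poisson, which the test suite
  verifies by goodness of fit.
* **Scene.** Square wells draw a rectilinear wall, round wells a circular
  ring. Cells are bright discs with a darker rim (radius uniform 8–20 px at
  the native 511-px frame, scaled linearly for smaller frames; peak
  intensity 150–230), approximating unstained bright-field lymphocytes; no
  pixel-size calibration is published, so these are plausible rather than
  measured values. Cells are placed without overlap strictly inside the
  well; placement failure after a bounded number of attempts is an error.
* **Artifacts.** The two named failure modes of real discordant wells are
  modeled: debris (small irregular low-contrast polygons) and defocus
  (whole-image Gaussian blur), plus a per-image uniform intensity offset —
  the reason min-max normalization exists — and Gaussian pixel noise.
* **Serialization.** 8-bit grayscale PNG plus a tab-separated manifest
  (`well_id, filename, count, category, debris, defocus`), lossless and
  universally readable. Categories above the rendering cap (`maxRender`,
  default 5) are still labeled `gt2`; wells with 4+ cells are extremely
  rare at these loadings and their rendered fidelity is not load-bearing.

What the generator does *not* emulate: photorealistic optics, fluorescence,
time-series morphology changes, or the full diversity of real debris.
Passing the synthetic benchmark therefore demonstrates that the
architecture and protocol can learn this counting task from realistic
occupancy statistics and imaging nuisances — it does not certify the
published accuracy on real ILC2 plates, which would require the original
data.

## Desk-scale study sizes

The full-resolution protocol (119-sample batches of 511-px images, tens of
thousands of iterations) is a GPU-scale computation. The package's own
benchmark, used in the test suite and the acceptance script, runs the
architecture at a 64-px input side — the scaled-spec rule keeps the channel
plan and kernel sizes and recomputes the first fully connected layer from
the resulting feature map — with two 500-well training plates, a 250-well
validation plate, a 400-well held-out plate, mini-batch composition
(11, 3, 2, 2) preserving the stratified ratios, learning rate 0.02, and
400 iterations. Under these conditions held-out accuracy reaches the low
90s percent for both well shapes (majority-class baseline ≈ 82%), and 5%
triage adds roughly one further point — the qualitative behaviour of the
full-scale system, at desk scale.

## Numerical and degenerate-input choices

* Constant images normalize to all zeros (stated above).
* `fitPoissonOccupancy()` maximizes the multinomial likelihood with the >2
  class right-censored (probability 1 − P(0) − P(1) − P(2)), because
  categorized counts do not resolve values above 2; the optimum is located
  to |Δλ| < 10^-7^, and the all-empty boundary returns λ = 0 exactly. The
  fit is invariant to scaling all counts.
* `compareConcordanceChi2()` defaults to the uncorrected Pearson statistic
  (the closed form n(ad−bc)²/((a+b)(c+d)(a+c)(b+d))); whether the published
  comparison used a continuity correction is not stated, so a corrected
  variant is available by flag. Both agree on the printed p < 0.0001.
* `confidenceSeparationTest()` uses exact enumeration for small tie-free
  samples and the tie-corrected normal approximation otherwise (the
  standard `wilcox.test` behaviour); as a rank test it is invariant to the
  log transform.
* Ties in the posterior argmax are broken toward the lower category index;
  with continuous-valued posteriors ties effectively never occur.

## Known limitations

* The synthetic benchmark bounds what the tests can claim about real
  plates (see above).
* Crowded wells and genuine cell clusters are outside the method's design:
  everything above 2 cells collapses into one category, and the generator
  caps rendering at `maxRender` cells.
* The censored-λ estimate is published to six decimals but the categorized
  counts it came from are not, so the estimator's agreement with the
  published value can only be checked by parameter recovery on simulated
  data, not by reproduction.
* Training at the native 511-px resolution is supported by the same code
  paths (the full-resolution forward pass is shape-verified in the tests)
  but is not practical on a single CPU; the staged schedule exists
  precisely because the reference protocol was memory-bound even on GPU
  hardware.
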