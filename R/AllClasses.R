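#' Parameters of the synthetic head-phantom generator
#'
#' Describes one phantom "condition": geometry of the simulated head, lesion
#' contrast and size, parenchymal texture, and additive noise. A length-2
#' `lesionContrast` is interpreted as a uniform sampling band, which is how
#' mixed-difficulty datasets express easy and hard cases.
#'
#' @slot imageSize integer, pixels per side of the square image.
#' @slot lesionContrast numeric of length 1 or 2, intensity decrement of the
#'   hypodense lesion, each value in \[0.02, 0.3\].
#' @slot lesionRadiusFrac numeric, lesion radius as a fraction of the brain
#'   radius, in (0, 0.5\].
#' @slot noiseSigma numeric, standard deviation of additive Gaussian noise,
#'   in \[0, 0.1\].
#' @slot textureScale numeric, smoothing length (pixels) of the parenchymal
#'   random field.
#' @slot seed integer RNG seed; identical parameters and seed give
#'   bit-identical phantoms.
#' @exportClass PhantomParams
setClass("PhantomParams",
  representation(
    imageSize = "integer",
    lesionContrast = "numeric",
    lesionRadiusFrac = "numeric",
    noiseSigma = "numeric",
    textureScale = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomParams", function(object) {
  msgs <- character()
  if (length(object@imageSize) != 1 || object@imageSize < 16)
    msgs <- c(msgs, "imageSize must be a single integer >= 16")
  lc <- object@lesionContrast
  if (!length(lc) %in% c(1L, 2L) || any(lc < 0.02) || any(lc > 0.3))
    msgs <- c(msgs, "lesionContrast must be 1 or 2 values in [0.02, 0.3]")
  if (length(lc) == 2L && lc[1] > lc[2])
    msgs <- c(msgs, "lesionContrast range must be increasing")
  rf <- object@lesionRadiusFrac
  if (length(rf) != 1 || rf <= 0 || rf > 0.5)
    msgs <- c(msgs, "lesionRadiusFrac must be in (0, 0.5]")
  ns <- object@noiseSigma
  if (length(ns) != 1 || ns < 0 || ns > 0.1)
    msgs <- c(msgs, "noiseSigma must be in [0, 0.1]")
  if (length(object@textureScale) != 1 || object@textureScale <= 0)
    msgs <- c(msgs, "textureScale must be positive")
  if (length(object@seed) != 1 || is.na(object@seed))
    msgs <- c(msgs, "seed must be a single integer")
  if (length(msgs)) msgs else TRUE
})

#' A labelled grayscale image with optional ground-truth lesion mask
#'
#' @slot pixels numeric matrix with values in \[0, 1\].
#' @slot label either `"stroke"` or `"normal"`.
#' @slot lesionMask binary matrix of the same size (all zero for normal
#'   images; only synthetic data carry a ground-truth mask).
#' @slot sourceId identifier string.
#' @exportClass LabeledImage
setClass("LabeledImage",
  representation(
    pixels = "matrix",
    label = "character",
    lesionMask = "matrix",
    sourceId = "character"
  )
)

setValidity("LabeledImage", function(object) {
  msgs <- character()
  p <- object@pixels
  if (min(p) < 0 || max(p) > 1)
    msgs <- c(msgs, "pixels must lie in [0, 1]")
  if (!object@label %in% c("stroke", "normal"))
    msgs <- c(msgs, "label must be 'stroke' or 'normal'")
  if (!identical(dim(p), dim(object@lesionMask)))
    msgs <- c(msgs, "lesionMask must match pixel dimensions")
  if (any(object@lesionMask != 0) && object@label != "stroke")
    msgs <- c(msgs, "nonzero lesionMask requires label 'stroke'")
  if (length(msgs)) msgs else TRUE
})

#' A synthetic phantom dataset: images plus a split manifest
#'
#' @slot manifest data.frame with columns `source_id`, `path`, `label`,
#'   `split` (train/validation/test).
#' @slot images named list of [LabeledImage-class] objects, names matching
#'   `source_id`.
#' @slot params list recording the generation parameters (difficulty mix,
#'   fractions).
#' @slot seed master integer seed of the generation run.
#' @exportClass PhantomDataset
setClass("PhantomDataset",
  representation(
    manifest = "data.frame",
    images = "list",
    params = "list",
    seed = "integer"
  )
)

setValidity("PhantomDataset", function(object) {
  m <- object@manifest
  msgs <- character()
  need <- c("source_id", "path", "label", "split")
  if (!all(need %in% names(m)))
    msgs <- c(msgs, "manifest must have source_id, path, label, split")
  else {
    if (anyDuplicated(m$path)) msgs <- c(msgs, "manifest paths must be unique")
    if (!all(m$split %in% c("train", "validation", "test")))
      msgs <- c(msgs, "split must be train/validation/test")
    if (length(object@images) && !all(m$source_id %in% names(object@images)))
      msgs <- c(msgs, "every manifest row needs a matching image")
  }
  if (length(msgs)) msgs else TRUE
})

#' Architecture configuration of the residual network
#'
#' One entry of `blockChannels` per residual block; each block is
#' convolution (kernelSize, stride 1, size-preserving padding) -> batch
#' normalization -> ReLU -> skip addition (1x1 projection only when channel
#' counts differ) -> dropout -> 2x2 max pooling. The head is adaptive average
#' pooling to `poolOutput`^2, a linear latent layer, and a softmax classifier.
#'
#' @slot inChannels integer, input image channels (1 for grayscale CT).
#' @slot blockChannels integer vector of output channels per residual block.
#' @slot kernelSize odd integer convolution kernel size.
#' @slot dropoutRate train-time dropout probability in \[0, 1).
#' @slot poolOutput spatial side of the adaptive average pool output.
#' @slot latentDim width of the latent fully connected layer.
#' @slot numClasses number of output classes.
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(
    inChannels = "integer",
    blockChannels = "integer",
    kernelSize = "integer",
    dropoutRate = "numeric",
    poolOutput = "integer",
    latentDim = "integer",
    numClasses = "integer"
  )
)

setValidity("NetworkConfig", function(object) {
  msgs <- character()
  if (length(object@blockChannels) < 1 || any(object@blockChannels < 1))
    msgs <- c(msgs, "blockChannels must be a non-empty positive vector")
  if (object@kernelSize %% 2 != 1 || object@kernelSize < 1)
    msgs <- c(msgs, "kernelSize must be odd and positive")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msgs <- c(msgs, "dropoutRate must be in [0, 1)")
  if (object@poolOutput < 1) msgs <- c(msgs, "poolOutput must be >= 1")
  if (object@latentDim < 1) msgs <- c(msgs, "latentDim must be >= 1")
  if (object@numClasses < 2) msgs <- c(msgs, "numClasses must be >= 2")
  if (object@inChannels < 1) msgs <- c(msgs, "inChannels must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Weights, buffers, and provenance of a (possibly trained) network
#'
#' @slot config the [NetworkConfig-class] the weights were built for.
#' @slot params named list of trainable arrays (convolution and linear
#'   weights/biases, batch-norm scale/shift).
#' @slot buffers named list of non-trainable state (batch-norm running
#'   statistics).
#' @slot trained logical flag set by [trainNetwork()].
#' @slot seed integer seed used at initialization/training.
#' @slot history per-epoch training log.
#' @slot classes class labels in output-column order.
#' @exportClass NetworkState
setClass("NetworkState",
  representation(
    config = "NetworkConfig",
    params = "list",
    buffers = "list",
    trained = "logical",
    seed = "integer",
    history = "data.frame",
    classes = "character"
  )
)

#' Training hyperparameters
#'
#' @slot epochs maximum epochs (>= 1).
#' @slot learningRate Adam step size (> 0).
#' @slot batchSize minibatch size.
#' @slot optimizer optimizer name (only `"adam"` implemented).
#' @slot patience early-stopping patience in epochs (validation loss).
#' @slot seed integer training seed.
#' @exportClass TrainingConfig
setClass("TrainingConfig",
  representation(
    epochs = "integer",
    learningRate = "numeric",
    batchSize = "integer",
    optimizer = "character",
    patience = "integer",
    seed = "integer"
  )
)

setValidity("TrainingConfig", function(object) {
  msgs <- character()
  if (object@epochs < 1) msgs <- c(msgs, "epochs must be >= 1")
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (object@batchSize < 1) msgs <- c(msgs, "batchSize must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' A Monte-Carlo-dropout prediction for one image
#'
#' Holds the N stochastic per-pass probability vectors, their arithmetic
#' mean (the predictive distribution), the argmax label, and the normalized
#' predictive entropy in \[0, 1\].
#'
#' @slot perPassProbs N x C matrix of per-pass softmax vectors.
#' @slot meanProbs length-C mean probability vector.
#' @slot predictedLabel argmax class label of the mean.
#' @slot entropy normalized entropy of the mean, in \[0, 1\].
#' @slot nPasses number of stochastic forward passes N.
#' @slot dropoutRate inference-time dropout rate p.
#' @exportClass MCPrediction
setClass("MCPrediction",
  representation(
    perPassProbs = "matrix",
    meanProbs = "numeric",
    predictedLabel = "character",
    entropy = "numeric",
    nPasses = "integer",
    dropoutRate = "numeric"
  )
)

setValidity("MCPrediction", function(object) {
  msgs <- character()
  if (max(abs(colMeans(object@perPassProbs) - object@meanProbs)) > 1e-8)
    msgs <- c(msgs, "meanProbs must be the mean of perPassProbs")
  if (object@entropy < -1e-12 || object@entropy > 1 + 1e-12)
    msgs <- c(msgs, "entropy must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Dropout-rate calibration result
#'
#' For each candidate inference dropout rate p, validation images are scored
#' by MC-dropout; the separation score is the rank probability that a
#' misclassified image has higher entropy than a correctly classified one.
#'
#' @slot grid candidate dropout rates.
#' @slot summaries per-rate quartiles of entropy for correct/misclassified
#'   validation images.
#' @slot separation separation score per rate, in \[0, 1\].
#' @slot pStar selected rate (argmax separation, ties toward smaller p).
#' @slot note diagnostic note (e.g. fallback when no errors occur).
#' @exportClass DropoutCalibration
setClass("DropoutCalibration",
  representation(
    grid = "numeric",
    summaries = "data.frame",
    separation = "numeric",
    pStar = "numeric",
    note = "character"
  )
)

setValidity("DropoutCalibration", function(object) {
  msgs <- character()
  if (!object@pStar %in% object@grid)
    msgs <- c(msgs, "pStar must be a grid member")
  ok <- is.na(object@separation) | (object@separation >= 0 & object@separation <= 1)
  if (!all(ok)) msgs <- c(msgs, "separation scores must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Entropy rejection threshold
#'
#' @slot alpha entropy cutoff in \[0, 1\]; predictions with H <= alpha are
#'   reliable, H > alpha are flagged for expert review.
#' @slot source description of the sample set alpha was averaged over.
#' @exportClass UncertaintyThreshold
setClass("UncertaintyThreshold",
  representation(alpha = "numeric", source = "character")
)

setValidity("UncertaintyThreshold", function(object) {
  if (object@alpha < 0 || object@alpha > 1) "alpha must be in [0, 1]" else TRUE
})

#' A class-discriminative saliency heatmap
#'
#' @slot values U x V matrix normalized to \[0, 1\] (constant raw maps are
#'   normalized to all-zeros by convention).
#' @slot method one of `"gradcam"`, `"gradcam_pp"`, `"scorecam"`.
#' @slot mode `"deterministic"` or `"mcd"` (average over stochastic passes).
#' @slot targetLayer identifier of the explained feature layer.
#' @slot explainedClass class label whose score is explained.
#' @exportClass SaliencyMap
setClass("SaliencyMap",
  representation(
    values = "matrix",
    method = "character",
    mode = "character",
    targetLayer = "character",
    explainedClass = "character"
  )
)

setValidity("SaliencyMap", function(object) {
  msgs <- character()
  if (min(object@values) < 0 || max(object@values) > 1)
    msgs <- c(msgs, "saliency values must lie in [0, 1]")
  if (!object@method %in% c("gradcam", "gradcam_pp", "scorecam"))
    msgs <- c(msgs, "unknown saliency method")
  if (!object@mode %in% c("deterministic", "mcd"))
    msgs <- c(msgs, "mode must be deterministic or mcd")
  if (length(msgs)) msgs else TRUE
})

#' Mean-saliency-intensity decision threshold
#'
#' `d = min(max MSI over true positives, max MSI over true negatives)` fitted
#' on validation outcomes; retained predictions with MSI > d are flipped.
#'
#' @slot d the threshold in \[0, 1\].
#' @slot maxMsiTP maximum MSI over true-positive calibration cases.
#' @slot maxMsiTN maximum MSI over true-negative calibration cases.
#' @slot source descriptor of the fitting set.
#' @exportClass MSIThreshold
setClass("MSIThreshold",
  representation(
    d = "numeric",
    maxMsiTP = "numeric",
    maxMsiTN = "numeric",
    source = "character"
  )
)

setValidity("MSIThreshold", function(object) {
  if (abs(object@d - min(object@maxMsiTP, object@maxMsiTN)) > 1e-12)
    "d must equal min(maxMsiTP, maxMsiTN)" else TRUE
})

#' Calibrated thresholds of the cascaded decision pipeline
#'
#' @slot pStar calibrated inference dropout rate.
#' @slot alpha the [UncertaintyThreshold-class] (entropy rejection).
#' @slot msiThreshold the [MSIThreshold-class] (saliency flip rule).
#' @slot nPasses number of MC-dropout passes N.
#' @slot provenance list recording fitting split and seeds.
#' @exportClass DecisionThresholds
setClass("DecisionThresholds",
  representation(
    pStar = "numeric",
    alpha = "UncertaintyThreshold",
    msiThreshold = "MSIThreshold",
    nPasses = "integer",
    provenance = "list"
  )
)
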