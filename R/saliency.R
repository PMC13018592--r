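# Saliency-map generation and the quantitative saliency decision rule.

tensorToArray <- function(tn) {
  C <- ncol(tn$x)
  arr <- array(0, c(tn$h, tn$w, C))
  for (cc in seq_len(C)) arr[, , cc] <- matrix(tn$x[, cc], tn$h, tn$w, byrow = TRUE)
  arr
}

resizeBilinear <- function(m, nr, nc) {
  if (nrow(m) == nr && ncol(m) == nc) return(m)
  matrix(EBImage::imageData(EBImage::resize(m, w = nr, h = nc,
                                            filter = "bilinear")), nr, nc)
}

# classic Grad-CAM: channel weights are the spatial means of the gradient,
# the raw map is the ReLU of the weighted channel sum
gradcamRaw <- function(A, G) {
  C <- dim(A)[3]
  wts <- vapply(seq_len(C), function(cc) mean(G[, , cc]), numeric(1))
  raw <- matrix(0, dim(A)[1], dim(A)[2])
  for (cc in seq_len(C)) raw <- raw + wts[cc] * A[, , cc]
  raw[raw < 0] <- 0
  raw
}

# Grad-CAM++ per-pixel weighting built from elementwise powers of the class
# gradient (the exponential-score formulation)
gradcamPPRaw <- function(A, G) {
  C <- dim(A)[3]
  raw <- matrix(0, dim(A)[1], dim(A)[2])
  eps <- 1e-12
  for (cc in seq_len(C)) {
    g <- G[, , cc]
    g2 <- g * g
    g3 <- g2 * g
    denom <- 2 * g2 + sum(A[, , cc]) * g3
    alpha <- ifelse(abs(denom) < eps, 0, g2 / denom)
    wt <- sum(alpha * pmax(g, 0))
    raw <- raw + wt * A[, , cc]
  }
  raw[raw < 0] <- 0
  raw
}

# activation A and class-score gradient G at the last residual block's ReLU
# feature maps, for one image, in the requested inference mode
actAndGrad <- function(state, tn, classIdx, mode, p) {
  fw <- netForward(state@params, state@buffers, state@config, tn,
                   mode = mode, p = p, keepCache = TRUE)
  dLogits <- matrix(0, 1, state@config@numClasses)
  dLogits[1, classIdx] <- 1
  bw <- netBackward(fw, dLogits, state@params, state@config)
  list(A = tensorToArray(fw$targetA), G = tensorToArray(bw$dTargetA), fw = fw)
}

scorecamRaw <- function(state, image, A, classIdx) {
  h <- nrow(image)
  w <- ncol(image)
  C <- dim(A)[3]
  baseTn <- imagesToTensor(matrix(0, h, w))
  base <- netForward(state@params, state@buffers, state@config,
                     baseTn, mode = "eval")$probs[1, classIdx]
  raw <- matrix(0, dim(A)[1], dim(A)[2])
  for (cc in seq_len(C)) {
    act <- A[, , cc]
    rng <- range(act)
    if (rng[2] - rng[1] <= 0) next
    mask <- resizeBilinear((act - rng[1]) / (rng[2] - rng[1]), h, w)
    mask <- clamp01(mask)
    fw <- netForward(state@params, state@buffers, state@config,
                     imagesToTensor(image * mask), mode = "eval")
    wt <- fw$probs[1, classIdx] - base
    raw <- raw + wt * act
  }
  raw[raw < 0] <- 0
  raw
}

#' Class-discriminative saliency map
#'
#' Generates a normalized relevance heatmap for one image. `gradcam` weighs
#' the last residual block's ReLU feature maps by the spatial mean of the
#' explained-class score gradient; `gradcam_pp` uses the per-pixel
#' higher-order weighting; `scorecam` weighs channels by the class-score
#' increase obtained when the input is masked by each normalized activation
#' channel. The raw map is ReLU-clipped, bilinearly upsampled to the image
#' size, and min-max normalized to \[0, 1\] (constant raw maps become
#' all-zeros). In `mcd` mode one normalized map is computed per stochastic
#' dropout pass (rate `p`, nested per-pass seeds), the maps are averaged and
#' renormalized; with `p = 0` this equals the deterministic map exactly.
#'
#' @param state a trained [NetworkState-class].
#' @param image a [LabeledImage-class] or matrix in \[0, 1\].
#' @param explainedClass class label to explain; defaults to the model's
#'   deterministic prediction.
#' @param method `"gradcam"`, `"gradcam_pp"` or `"scorecam"`.
#' @param mode `"deterministic"` or `"mcd"`.
#' @param p dropout rate for `mcd` mode.
#' @param nPasses stochastic passes for `mcd` mode.
#' @param seed seed for `mcd` mode.
#' @return a [SaliencyMap-class].
#' @export
saliencyMap <- function(state, image, explainedClass = NULL,
                        method = c("gradcam", "gradcam_pp", "scorecam"),
                        mode = c("deterministic", "mcd"), p = 0.01,
                        nPasses = 20L, seed = 1L) {
  stopIf(!methods::is(state, "NetworkState") || !state@trained,
         "a trained NetworkState is required", "stateError")
  method <- match.arg(method)
  mode <- match.arg(mode)
  img <- if (methods::is(image, "LabeledImage")) image@pixels else image
  tn <- imagesToTensor(img)
  checkSpatial(tn$h, tn$w, state@config)
  if (is.null(explainedClass)) {
    probs <- predictProbs(state, img)
    explainedClass <- names(probs)[which.max(probs)]
  }
  classIdx <- match(explainedClass, state@classes)
  stopIf(is.na(classIdx), "unknown explainedClass", "configError")

  onePass <- function(fwMode, passP) {
    ag <- actAndGrad(state, tn, classIdx, fwMode, passP)
    raw <- switch(method,
      gradcam = gradcamRaw(ag$A, ag$G),
      gradcam_pp = gradcamPPRaw(ag$A, ag$G),
      scorecam = scorecamRaw(state, img, ag$A, classIdx)
    )
    minMaxNormalize(resizeBilinear(raw, nrow(img), ncol(img)))
  }

  vals <- if (mode == "deterministic" || p == 0) {
    onePass("eval", 0)
  } else {
    acc <- matrix(0, nrow(img), ncol(img))
    for (nIdx in seq_len(nPasses)) {
      set.seed(childSeed(seed, nIdx))
      acc <- acc + onePass("mc", p)
    }
    minMaxNormalize(acc / nPasses)
  }
  new("SaliencyMap", values = vals, method = method, mode = mode,
      targetLayer = sprintf("block%d_relu", length(state@config@blockChannels)),
      explainedClass = explainedClass)
}

#' Mean saliency intensity (MSI)
#'
#' The arithmetic mean of a normalized saliency map: `sum(C_ij) / (U * V)`.
#' High values indicate diffuse, indiscriminate attention; focal maps score
#' low.
#'
#' @param map a [SaliencyMap-class] or numeric matrix in \[0, 1\].
#' @return MSI in \[0, 1\].
#' @export
meanSaliencyIntensity <- function(map) {
  v <- if (methods::is(map, "SaliencyMap")) map@values else map
  stopIf(length(v) == 0, "empty saliency map", "inputError")
  mean(v)
}

#' Pearson consistency between two saliency maps
#'
#' Pearson correlation over the flattened values; when either map is
#' constant the correlation is undefined and `NA` is returned.
#'
#' @param mapA,mapB [SaliencyMap-class] objects or matrices of equal shape.
#' @return correlation in \[-1, 1\], or `NA` for constant maps.
#' @export
saliencyPCC <- function(mapA, mapB) {
  a <- if (methods::is(mapA, "SaliencyMap")) mapA@values else mapA
  b <- if (methods::is(mapB, "SaliencyMap")) mapB@values else mapB
  stopIf(!identical(dim(a), dim(b)), "saliency maps must share shape",
         "inputError")
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(as.vector(a), as.vector(b))
}

#' Fit the MSI flip threshold
#'
#' `D = min(max MSI over true positives, max MSI over true negatives)`,
#' computed from validation records only (outcomes are known there).
#'
#' @param records data.frame with columns `msi` and `outcome` (values among
#'   TP, TN, FP, FN), or a list of such pairs.
#' @param source descriptor of the fitting set.
#' @return an [MSIThreshold-class].
#' @export
computeMSIThreshold <- function(records, source = "validation") {
  if (!is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r) {
      data.frame(msi = r$msi, outcome = r$outcome)
    }))
  }
  tp <- records$msi[records$outcome == "TP"]
  tn <- records$msi[records$outcome == "TN"]
  stopIf(length(tp) == 0 || length(tn) == 0,
         "threshold fitting needs at least one TP and one TN record",
         "calibrationError")
  new("MSIThreshold", d = min(max(tp), max(tn)), maxMsiTP = max(tp),
      maxMsiTN = max(tn), source = source)
}

#' Saliency-driven label correction
#'
#' Retained predictions whose MSI exceeds the threshold D show diffuse,
#' unreliable attention: the binary label is flipped to the other class.
#' At `msi == D` (and below) the prediction is kept.
#'
#' @param predictedLabel `"stroke"` or `"normal"`.
#' @param msi the prediction's mean saliency intensity in \[0, 1\].
#' @param threshold an [MSIThreshold-class].
#' @return list with `finalLabel` and logical `flipped`.
#' @export
xaiCorrection <- function(predictedLabel, msi, threshold) {
  stopIf(msi < 0 || msi > 1, "msi must be in [0, 1]", "inputError")
  stopIf(!predictedLabel %in% c("stroke", "normal"),
         "predictedLabel must be stroke or normal", "inputError")
  flip <- msi > threshold@d
  final <- if (flip) setdiff(c("stroke", "normal"), predictedLabel) else predictedLabel
  list(finalLabel = final, flipped = flip)
}
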