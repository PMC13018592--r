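#' Normalized predictive entropy
#'
#' Shannon entropy of a probability vector divided by `log(C)` (C classes),
#' so that 0 means complete certainty and 1 the uniform, completely
#' uncertain distribution. The `0 * log 0 := 0` convention applies.
#'
#' @param probs probability vector (non-negative, summing to 1 within 1e-6).
#' @return entropy in \[0, 1\].
#' @examples
#' normalizedEntropy(c(0.5, 0.5)) # 1
#' normalizedEntropy(c(1, 0))     # 0
#' @export
normalizedEntropy <- function(probs) {
  stopIf(!isProbVector(probs), "probs must be a probability vector",
         "inputError")
  p <- probs[probs > 0]
  h <- -sum(p * log(p)) / log(length(probs))
  min(max(h, 0), 1)
}

#' Monte-Carlo-dropout prediction for one image
#'
#' Runs N stochastic forward passes with dropout active at rate `p` (batch
#' normalization stays in inference mode), averages the per-pass softmax
#' vectors into the predictive distribution, and scores its normalized
#' entropy. Pass `n` uses an RNG substream derived from (`seed`, `n`), so
#' the first N passes of a longer run are exactly the passes of a shorter
#' one (nested sweeps), and the result is deterministic in `seed`.
#'
#' @param state a trained [NetworkState-class].
#' @param image a [LabeledImage-class] or matrix in \[0, 1\].
#' @param nPasses number of stochastic passes N (>= 1).
#' @param p inference dropout rate in \[0, 1).
#' @param seed integer seed.
#' @return an [MCPrediction-class].
#' @export
mcPredict <- function(state, image, nPasses = 20L, p = 0.01, seed = 1L) {
  stopIf(!methods::is(state, "NetworkState"), "state must be a NetworkState",
         "stateError")
  stopIf(!state@trained, "network state is untrained", "stateError")
  stopIf(nPasses < 1, "nPasses must be >= 1", "inputError")
  stopIf(p < 0 || p >= 1, "p must be in [0, 1)", "inputError")
  tn <- imagesToTensor(image)
  checkSpatial(tn$h, tn$w, state@config)
  C <- state@config@numClasses
  passes <- matrix(0, nPasses, C)
  if (p == 0) {
    # all passes provably identical to deterministic inference
    fw <- netForward(state@params, state@buffers, state@config, tn, mode = "eval")
    passes[] <- rep(fw$probs[1L, ], each = nPasses)
  } else {
    for (nIdx in seq_len(nPasses)) {
      set.seed(childSeed(seed, nIdx))
      fw <- netForward(state@params, state@buffers, state@config, tn,
                       mode = "mc", p = p)
      passes[nIdx, ] <- fw$probs[1L, ]
    }
  }
  meanP <- colMeans(passes)
  lbl <- state@classes[which.max(meanP)]
  new("MCPrediction", perPassProbs = passes, meanProbs = meanP,
      predictedLabel = lbl, entropy = normalizedEntropy(meanP),
      nPasses = as.integer(nPasses), dropoutRate = p)
}

#' Accuracy as a function of the number of MC-dropout passes
#'
#' Computes, for every N in `nGrid`, the accuracy of the mean-probability
#' prediction on a validation set. Passes are generated once at `max(nGrid)`
#' per image and prefix-averaged, so smaller N use exactly the first N
#' passes of larger N (the seed streams are nested).
#'
#' @param state a trained [NetworkState-class].
#' @param dataset a [PhantomDataset-class].
#' @param nGrid integer vector of pass counts (>= 1).
#' @param p inference dropout rate.
#' @param seed master seed; per-image substreams are derived from it.
#' @param split which split to score (default validation).
#' @return data.frame with columns `n` and `accuracy`.
#' @export
sweepForwardPasses <- function(state, dataset, nGrid = c(1, 5, 10, 20),
                               p = 0.01, seed = 1L, split = "validation") {
  stopIf(any(nGrid < 1), "nGrid values must be >= 1", "inputError")
  sp <- splitImages(dataset, split)
  stopIf(length(sp$images) == 0, sprintf("empty %s split", split), "dataError")
  nMax <- max(nGrid)
  correct <- matrix(FALSE, length(sp$images), length(nGrid))
  for (i in seq_along(sp$images)) {
    pr <- mcPredict(state, sp$images[[i]], nPasses = nMax, p = p,
                    seed = childSeed(seed, i))
    pp <- pr@perPassProbs
    for (gi in seq_along(nGrid)) {
      meanP <- colMeans(pp[seq_len(nGrid[gi]), , drop = FALSE])
      correct[i, gi] <- state@classes[which.max(meanP)] == sp$labels[i]
    }
  }
  data.frame(n = nGrid, accuracy = colMeans(correct))
}

#' Rank-based separation between the entropies of misclassified and
#' correctly classified samples
#'
#' The probability that a uniformly drawn misclassified sample has strictly
#' higher entropy than a uniformly drawn correctly classified one, counting
#' ties as half. Equivalent to the area under the ROC curve of entropy as a
#' misclassification detector; 1 means perfect separation, 0.5 chance.
#'
#' @param entropies numeric entropy values.
#' @param correct logical correctness flags, aligned with `entropies`.
#' @return separation score in \[0, 1\], or `NA` when either group is empty.
#' @export
separationScore <- function(entropies, correct) {
  stopIf(length(entropies) != length(correct), "inputs must align", "inputError")
  hWrong <- entropies[!correct]
  hRight <- entropies[correct]
  if (length(hWrong) == 0 || length(hRight) == 0) return(NA_real_)
  r <- rank(c(hWrong, hRight), ties.method = "average")
  nw <- length(hWrong)
  (sum(r[seq_len(nw)]) - nw * (nw + 1) / 2) / (nw * length(hRight))
}

#' Calibrate the inference dropout rate
#'
#' For each candidate rate p, every validation image is scored by MC
#' dropout; correctness is judged against the MC mean prediction, and the
#' entropy separation between misclassified and correct samples is computed
#' with [separationScore()]. The selected rate p* is the argmax, ties broken
#' toward the smaller rate. If no rate produces a misclassification the
#' smallest grid rate is selected with a warning note.
#'
#' @param state a trained [NetworkState-class].
#' @param dataset a [PhantomDataset-class] with a validation split.
#' @param pGrid candidate dropout rates.
#' @param nPasses MC passes per image.
#' @param seed master seed.
#' @param split split to calibrate on (default validation).
#' @return a [DropoutCalibration-class].
#' @export
calibrateDropout <- function(state, dataset,
                             pGrid = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5),
                             nPasses = 20L, seed = 1L, split = "validation") {
  sp <- splitImages(dataset, split)
  stopIf(length(sp$images) == 0, sprintf("empty %s split", split), "dataError")
  pGrid <- sort(pGrid)
  sep <- rep(NA_real_, length(pGrid))
  rows <- list()
  entStore <- vector("list", length(pGrid))
  for (pi in seq_along(pGrid)) {
    ents <- numeric(length(sp$images))
    corr <- logical(length(sp$images))
    for (i in seq_along(sp$images)) {
      pr <- mcPredict(state, sp$images[[i]], nPasses = nPasses, p = pGrid[pi],
                      seed = childSeed(seed, i))
      ents[i] <- pr@entropy
      corr[i] <- pr@predictedLabel == sp$labels[i]
    }
    entStore[[pi]] <- list(entropies = ents, correct = corr)
    sep[pi] <- separationScore(ents, corr)
    qs <- function(x) {
      if (length(x) == 0) rep(NA_real_, 3) else unname(stats::quantile(x, c(0.25, 0.5, 0.75)))
    }
    qc <- qs(ents[corr])
    qm <- qs(ents[!corr])
    rows[[pi]] <- data.frame(p = pGrid[pi],
                             correct_q1 = qc[1], correct_med = qc[2],
                             correct_q3 = qc[3],
                             mis_q1 = qm[1], mis_med = qm[2], mis_q3 = qm[3],
                             n_correct = sum(corr), n_mis = sum(!corr))
  }
  sel <- selectRate(pGrid, sep)
  if (nzchar(sel$note)) warning(sel$note)
  new("DropoutCalibration", grid = pGrid, summaries = do.call(rbind, rows),
      separation = sep, pStar = sel$pStar, note = sel$note)
}

# argmax separation with ties broken toward the smaller rate; grid assumed
# sorted. All-NA scores fall back to the smallest rate with a warning note.
selectRate <- function(grid, sep) {
  if (all(is.na(sep))) {
    return(list(pStar = grid[1],
                note = "no misclassified validation samples at any rate; smallest rate selected"))
  }
  best <- max(sep, na.rm = TRUE)
  list(pStar = grid[which(!is.na(sep) & abs(sep - best) < 1e-12)][1], note = "")
}

#' Entropy rejection threshold from a set of entropies
#'
#' The cutoff alpha is the arithmetic mean of the supplied entropy values
#' (typically the validation-set entropies at the calibrated dropout rate).
#'
#' @param entropies non-empty numeric vector of entropy values in \[0, 1\].
#' @param source description of the sample set.
#' @return an [UncertaintyThreshold-class].
#' @export
computeAlpha <- function(entropies, source = "validation") {
  stopIf(length(entropies) == 0, "entropies must be non-empty", "dataError")
  new("UncertaintyThreshold", alpha = mean(entropies), source = source)
}

#' Entropy rejection rule
#'
#' A prediction is reliable when its entropy H satisfies `H <= alpha`
#' (inclusive); otherwise it is flagged for expert review.
#'
#' @param prediction an [MCPrediction-class].
#' @param threshold an [UncertaintyThreshold-class].
#' @return `"reliable"` or `"flagged"`.
#' @export
uqFilter <- function(prediction, threshold) {
  stopIf(!methods::is(prediction, "MCPrediction"),
         "prediction must be an MCPrediction", "inputError")
  stopIf(!methods::is(threshold, "UncertaintyThreshold"),
         "threshold must be an UncertaintyThreshold", "inputError")
  if (prediction@entropy <= threshold@alpha) "reliable" else "flagged"
}
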