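#' Fit the cascaded decision thresholds on the validation split
#'
#' Sequential calibration, all on validation data: (1) the inference
#' dropout rate p* maximizing entropy separation between correct and
#' misclassified MC predictions ([calibrateDropout()]); (2) the entropy
#' rejection cutoff alpha as the mean validation entropy at p*
#' ([computeAlpha()]); (3) the MSI flip threshold D from the MCD-mode
#' saliency of validation true positives and true negatives
#' ([computeMSIThreshold()]). All seeds are recorded in the provenance.
#'
#' @param state a trained [NetworkState-class].
#' @param dataset a [PhantomDataset-class] with a validation split holding
#'   both labels.
#' @param nPasses MC-dropout passes N.
#' @param pGrid candidate dropout rates.
#' @param method saliency method for the MSI stage.
#' @param seed master seed.
#' @return a [DecisionThresholds-class].
#' @export
fitCascade <- function(state, dataset, nPasses = 20L,
                       pGrid = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5),
                       method = "gradcam", seed = 1L) {
  stopIf(!methods::is(state, "NetworkState") || !state@trained,
         "a trained NetworkState is required", "stateError")
  cal <- calibrateDropout(state, dataset, pGrid = pGrid, nPasses = nPasses,
                          seed = childSeed(seed, 1L))
  pStar <- cal@pStar
  sp <- splitImages(dataset, "validation")
  ents <- numeric(length(sp$images))
  outcomes <- character(length(sp$images))
  msis <- numeric(length(sp$images))
  for (i in seq_along(sp$images)) {
    pr <- mcPredict(state, sp$images[[i]], nPasses = nPasses, p = pStar,
                    seed = childSeed(childSeed(seed, 1L), i))
    ents[i] <- pr@entropy
    truth <- sp$labels[i]
    pred <- pr@predictedLabel
    outcomes[i] <- if (pred == "stroke" && truth == "stroke") "TP"
      else if (pred == "normal" && truth == "normal") "TN"
      else if (pred == "stroke") "FP" else "FN"
    sm <- saliencyMap(state, sp$images[[i]], explainedClass = pred,
                      method = method, mode = "mcd", p = pStar,
                      nPasses = nPasses, seed = childSeed(seed, 2L + i))
    msis[i] <- meanSaliencyIntensity(sm)
  }
  msiThr <- tryCatch(
    computeMSIThreshold(data.frame(msi = msis, outcome = outcomes)),
    error = function(e) {
      stop(errorCondition(
        sprintf("MSI threshold stage failed: %s", conditionMessage(e)),
        class = c("calibrationError", "cascadectError")))
    }
  )
  alpha <- computeAlpha(ents, source = sprintf("validation at p*=%g", pStar))
  new("DecisionThresholds", pStar = pStar, alpha = alpha,
      msiThreshold = msiThr, nPasses = as.integer(nPasses),
      provenance = list(seed = seed, split = "validation",
                        method = method, separation = cal@separation,
                        grid = cal@grid, calibrationNote = cal@note))
}

#' Run the cascaded decision pipeline
#'
#' Per image: MC-dropout prediction at (N, p*) gives the baseline label and
#' entropy H. If H > alpha the case is flagged for expert review and the
#' saliency stage never sees it. Otherwise the MCD-mode saliency map of the
#' predicted class is computed; if its MSI exceeds D the binary label is
#' flipped, otherwise the baseline label is accepted. Every input ends in
#' exactly one of accepted / flagged_for_review / flipped.
#'
#' @param state a trained [NetworkState-class].
#' @param thresholds a fitted [DecisionThresholds-class].
#' @param imgs list of [LabeledImage-class] objects (or matrices).
#' @param seed master seed for the MC substreams.
#' @return data.frame with one row per image: `source_id`,
#'   `baseline_label`, `p_stroke_mean`, `entropy`, `status`, `final_label`
#'   (`NA` when flagged), `msi` (`NA` when not computed).
#' @export
runCascade <- function(state, thresholds, imgs, seed = 1L) {
  stopIf(!methods::is(thresholds, "DecisionThresholds"),
         "thresholds must be fitted DecisionThresholds", "stateError")
  stopIf(!methods::is(state, "NetworkState") || !state@trained,
         "a trained NetworkState is required", "stateError")
  if (methods::is(imgs, "LabeledImage") || is.matrix(imgs)) imgs <- list(imgs)
  n <- length(imgs)
  ids <- vapply(seq_len(n), function(i) {
    im <- imgs[[i]]
    if (methods::is(im, "LabeledImage") && nzchar(im@sourceId)) im@sourceId
    else sprintf("case%04d", i)
  }, character(1))
  out <- data.frame(source_id = ids, baseline_label = NA_character_,
                    p_stroke_mean = NA_real_, entropy = NA_real_,
                    status = NA_character_, final_label = NA_character_,
                    msi = NA_real_, stringsAsFactors = FALSE)
  alpha <- thresholds@alpha@alpha
  D <- thresholds@msiThreshold@d
  for (i in seq_len(n)) {
    pr <- mcPredict(state, imgs[[i]], nPasses = thresholds@nPasses,
                    p = thresholds@pStar, seed = childSeed(seed, i))
    out$baseline_label[i] <- pr@predictedLabel
    out$p_stroke_mean[i] <- pr@meanProbs[match("stroke", state@classes)]
    out$entropy[i] <- pr@entropy
    if (pr@entropy > alpha) {
      out$status[i] <- "flagged_for_review"
      next
    }
    sm <- saliencyMap(state, imgs[[i]], explainedClass = pr@predictedLabel,
                      method = thresholds@provenance$method %||% "gradcam",
                      mode = "mcd", p = thresholds@pStar,
                      nPasses = thresholds@nPasses,
                      seed = childSeed(seed, n + i))
    msi <- meanSaliencyIntensity(sm)
    out$msi[i] <- msi
    corr <- xaiCorrection(pr@predictedLabel, msi, thresholds@msiThreshold)
    out$final_label[i] <- corr$finalLabel
    out$status[i] <- if (corr$flipped) "flipped" else "accepted"
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
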