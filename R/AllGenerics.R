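#' @name accessors
#' @title Accessors for CascadeCT objects
#' @description Small accessor generics for the package's S4 containers.
#' @param x an object.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("imageLabel", function(x) standardGeneric("imageLabel"))
#' @rdname accessors
#' @export
setGeneric("lesionMask", function(x) standardGeneric("lesionMask"))
#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
#' @rdname accessors
#' @export
setGeneric("images", function(x) standardGeneric("images"))
#' @rdname accessors
#' @export
setGeneric("meanProbs", function(x) standardGeneric("meanProbs"))
#' @rdname accessors
#' @export
setGeneric("perPassProbs", function(x) standardGeneric("perPassProbs"))
#' @rdname accessors
#' @export
setGeneric("predictedLabel", function(x) standardGeneric("predictedLabel"))
#' @rdname accessors
#' @export
setGeneric("entropyValue", function(x) standardGeneric("entropyValue"))
#' @rdname accessors
#' @export
setGeneric("saliencyValues", function(x) standardGeneric("saliencyValues"))
#' @rdname accessors
#' @export
setGeneric("netConfig", function(x) standardGeneric("netConfig"))
#' @rdname accessors
#' @export
setGeneric("isTrained", function(x) standardGeneric("isTrained"))
#' @rdname accessors
#' @export
setGeneric("alphaValue", function(x) standardGeneric("alphaValue"))
#' @rdname accessors
#' @export
setGeneric("msiCutoff", function(x) standardGeneric("msiCutoff"))
#' @rdname accessors
#' @export
setGeneric("selectedDropout", function(x) standardGeneric("selectedDropout"))

#' @rdname accessors
setMethod("pixels", "LabeledImage", function(x) x@pixels)
#' @rdname accessors
setMethod("imageLabel", "LabeledImage", function(x) x@label)
#' @rdname accessors
setMethod("lesionMask", "LabeledImage", function(x) x@lesionMask)
#' @rdname accessors
setMethod("sourceId", "LabeledImage", function(x) x@sourceId)
#' @rdname accessors
setMethod("manifest", "PhantomDataset", function(x) x@manifest)
#' @rdname accessors
setMethod("images", "PhantomDataset", function(x) x@images)
#' @rdname accessors
setMethod("meanProbs", "MCPrediction", function(x) x@meanProbs)
#' @rdname accessors
setMethod("perPassProbs", "MCPrediction", function(x) x@perPassProbs)
#' @rdname accessors
setMethod("predictedLabel", "MCPrediction", function(x) x@predictedLabel)
#' @rdname accessors
setMethod("entropyValue", "MCPrediction", function(x) x@entropy)
#' @rdname accessors
setMethod("saliencyValues", "SaliencyMap", function(x) x@values)
#' @rdname accessors
setMethod("netConfig", "NetworkState", function(x) x@config)
#' @rdname accessors
setMethod("isTrained", "NetworkState", function(x) x@trained)
#' @rdname accessors
setMethod("alphaValue", "UncertaintyThreshold", function(x) x@alpha)
#' @rdname accessors
setMethod("alphaValue", "DecisionThresholds", function(x) x@alpha@alpha)
#' @rdname accessors
setMethod("msiCutoff", "MSIThreshold", function(x) x@d)
#' @rdname accessors
setMethod("msiCutoff", "DecisionThresholds", function(x) x@msiThreshold@d)
#' @rdname accessors
setMethod("selectedDropout", "DropoutCalibration", function(x) x@pStar)
#' @rdname accessors
setMethod("selectedDropout", "DecisionThresholds", function(x) x@pStar)

setMethod("show", "LabeledImage", function(object) {
  cat(sprintf(
    "LabeledImage '%s': %dx%d, label=%s, lesion pixels=%d\n",
    object@sourceId, nrow(object@pixels), ncol(object@pixels),
    object@label, sum(object@lesionMask != 0)
  ))
})

setMethod("show", "PhantomDataset", function(object) {
  m <- object@manifest
  cat(sprintf("PhantomDataset: %d images (seed %d)\n", nrow(m), object@seed))
  print(table(split = m$split, label = m$label))
})

setMethod("show", "NetworkState", function(object) {
  cfg <- object@config
  cat(sprintf(
    "NetworkState: %d residual block(s) [%s], latent %d, %d classes\n",
    length(cfg@blockChannels), paste(cfg@blockChannels, collapse = ","),
    cfg@latentDim, cfg@numClasses
  ))
  cat(sprintf(
    "  trainable parameters: %s | trained: %s\n",
    format(countParameters(object), big.mark = ","), object@trained
  ))
})

setMethod("show", "MCPrediction", function(object) {
  cat(sprintf(
    "MCPrediction: label=%s, mean p=[%s], H=%.4f (N=%d, p=%g)\n",
    object@predictedLabel,
    paste(sprintf("%.3f", object@meanProbs), collapse = ", "),
    object@entropy, object@nPasses, object@dropoutRate
  ))
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf(
    "SaliencyMap (%s, %s): %dx%d, class=%s, MSI=%.4f\n",
    object@method, object@mode, nrow(object@values), ncol(object@values),
    object@explainedClass, mean(object@values)
  ))
})

setMethod("show", "DropoutCalibration", function(object) {
  cat("DropoutCalibration\n")
  print(data.frame(p = object@grid, separation = round(object@separation, 4)))
  cat(sprintf("selected p* = %g%s\n", object@pStar,
              if (nzchar(object@note)) paste0(" (", object@note, ")") else ""))
})

setMethod("show", "DecisionThresholds", function(object) {
  cat(sprintf(
    "DecisionThresholds: p*=%g, alpha=%.4f, D=%.4f, N=%d\n",
    object@pStar, object@alpha@alpha, object@msiThreshold@d, object@nPasses
  ))
})
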