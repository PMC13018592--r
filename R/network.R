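#' Create a network architecture configuration
#'
#' Defaults pin the reference architecture: five residual blocks of 128
#' channels (1x1 projection only at the first block, where the channel count
#' changes), 3x3 convolutions, dropout 0.1 after the residual addition,
#' adaptive average pooling to 2x2, a 128-dimensional linear latent layer,
#' and a 2-class softmax head. This configuration has 659,074 trainable
#' parameters (0.66 million to two decimals).
#'
#' @param inChannels input image channels (grayscale CT: 1).
#' @param blockChannels integer vector of residual-block output channels.
#' @param kernelSize odd convolution kernel size.
#' @param dropoutRate train-time dropout probability.
#' @param poolOutput side of the adaptive average pool output.
#' @param latentDim latent layer width.
#' @param numClasses output classes.
#' @return a [NetworkConfig-class] object.
#' @examples
#' cfg <- networkConfig()
#' countParameters(buildNetwork(cfg))
#' @export
networkConfig <- function(inChannels = 1, blockChannels = rep(128, 5),
                          kernelSize = 3, dropoutRate = 0.1, poolOutput = 2,
                          latentDim = 128, numClasses = 2) {
  stopIf(length(blockChannels) < 1, "blockChannels must be non-empty",
         "configError")
  new("NetworkConfig",
      inChannels = as.integer(inChannels),
      blockChannels = as.integer(blockChannels),
      kernelSize = as.integer(kernelSize),
      dropoutRate = as.numeric(dropoutRate),
      poolOutput = as.integer(poolOutput),
      latentDim = as.integer(latentDim),
      numClasses = as.integer(numClasses))
}

#' Build an untrained network
#'
#' Allocates and seeds all trainable arrays (He-uniform convolution and
#' linear weights, unit batch-norm scale, zero biases) and the batch-norm
#' running statistics.
#'
#' @param config a [NetworkConfig-class].
#' @param seed integer initialization seed.
#' @return an untrained [NetworkState-class].
#' @export
buildNetwork <- function(config, seed = 1L) {
  stopIf(!methods::is(config, "NetworkConfig"), "config must be a NetworkConfig",
         "configError")
  methods::validObject(config)
  ini <- initParams(config, seed)
  new("NetworkState", config = config, params = ini$params,
      buffers = ini$buffers, trained = FALSE, seed = as.integer(seed),
      history = data.frame(), classes = c("stroke", "normal"))
}

#' Count trainable parameters
#'
#' Sums the entries of every trainable array: convolution and linear weights
#' and biases, batch-norm scale and shift. Batch-norm running statistics are
#' buffers, not parameters, and are excluded.
#'
#' @param x a [NetworkState-class].
#' @return integer parameter count.
#' @examples
#' countParameters(buildNetwork(networkConfig())) # 659074
#' @export
countParameters <- function(x) {
  stopIf(!methods::is(x, "NetworkState"), "x must be a NetworkState", "stateError")
  sum(vapply(x@params, length, integer(1)))
}

#' Create a training configuration
#'
#' @param epochs maximum training epochs.
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param optimizer optimizer name; only `"adam"` is implemented.
#' @param patience early-stopping patience on validation loss (epochs).
#' @param seed integer training seed; fixes shuffling, dropout, and thus the
#'   final weights exactly.
#' @return a [TrainingConfig-class].
#' @export
trainingConfig <- function(epochs = 30, learningRate = 1e-3, batchSize = 32,
                           optimizer = "adam", patience = 10, seed = 1L) {
  stopIf(!identical(optimizer, "adam"), "only the adam optimizer is implemented",
         "configError")
  new("TrainingConfig", epochs = as.integer(epochs),
      learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), optimizer = optimizer,
      patience = as.integer(patience), seed = as.integer(seed))
}

splitImages <- function(dataset, split) {
  m <- dataset@manifest
  ids <- m$source_id[m$split == split]
  list(images = dataset@images[ids],
       labels = m$label[m$split == split])
}

labelsToOnehot <- function(labels, classes) {
  y <- matrix(0, length(labels), length(classes))
  y[cbind(seq_along(labels), match(labels, classes))] <- 1
  y
}

#' Train the network
#'
#' Minimizes softmax cross-entropy with Adam; dropout is active during
#' training at the configured rate and batch normalization uses minibatch
#' statistics. After every epoch the validation split is scored in inference
#' mode; the weights with the best validation loss are retained and training
#' stops early when the loss has not improved for `patience` epochs. Fully
#' deterministic given the training seed.
#'
#' @param state an untrained or trained [NetworkState-class].
#' @param dataset a [PhantomDataset-class] with non-empty train and
#'   validation splits containing both labels in the train split.
#' @param tc a [TrainingConfig-class].
#' @return a trained [NetworkState-class]; `@history` holds the per-epoch
#'   train loss, validation loss, and validation accuracy.
#' @export
trainNetwork <- function(state, dataset, tc = trainingConfig()) {
  cfg <- state@config
  tr <- splitImages(dataset, "train")
  va <- splitImages(dataset, "validation")
  stopIf(length(tr$images) == 0, "empty training split", "dataError")
  stopIf(length(unique(tr$labels)) < 2,
         "training split must contain both labels", "dataError")
  stopIf(length(va$images) == 0, "empty validation split", "dataError")
  classes <- state@classes
  trTn <- imagesToTensor(tr$images)
  checkSpatial(trTn$h, trTn$w, cfg)
  yTr <- labelsToOnehot(tr$labels, classes)
  vaMats <- lapply(va$images, pixels)
  yVa <- labelsToOnehot(va$labels, classes)

  set.seed(tc@seed)
  params <- state@params
  buffers <- state@buffers
  opt <- adamInit(params)
  n <- length(tr$images)
  h <- trTn$h
  w <- trTn$w
  hw <- h * w
  best <- list(loss = Inf, params = params, buffers = buffers, epoch = 0L)
  hist <- vector("list", tc@epochs)
  sinceBest <- 0L
  for (epoch in seq_len(tc@epochs)) {
    ord <- sample.int(n)
    lossSum <- 0
    nBatch <- 0L
    for (start in seq(1L, n, by = tc@batchSize)) {
      take <- ord[start:min(start + tc@batchSize - 1L, n)]
      rows <- as.vector(vapply(take, function(i) ((i - 1L) * hw + 1L):(i * hw),
                               integer(hw)))
      btn <- nnTensor(trTn$x[rows, , drop = FALSE], length(take), h, w)
      fw <- netForward(params, buffers, cfg, btn, mode = "train",
                       keepCache = TRUE)
      buffers <- fw$buffers
      yb <- yTr[take, , drop = FALSE]
      lossSum <- lossSum + crossEntropy(fw$probs, yb)
      nBatch <- nBatch + 1L
      dLogits <- (fw$probs - yb) / nrow(yb)
      bw <- netBackward(fw, dLogits, params, cfg)
      upd <- adamStep(params, bw$grads, opt, tc@learningRate)
      params <- upd$params
      opt <- upd$st
    }
    vfw <- netForward(params, buffers, cfg, imagesToTensor(vaMats), mode = "eval")
    vloss <- crossEntropy(vfw$probs, yVa)
    vacc <- mean(classes[max.col(vfw$probs, ties.method = "first")] == va$labels)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = lossSum / nBatch,
                                val_loss = vloss, val_acc = vacc)
    if (vloss < best$loss - 1e-9) {
      best <- list(loss = vloss, params = params, buffers = buffers,
                   epoch = epoch)
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= tc@patience) break
    }
  }
  new("NetworkState", config = cfg, params = best$params,
      buffers = best$buffers, trained = TRUE, seed = tc@seed,
      history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
      classes = classes)
}

#' Deterministic class probabilities
#'
#' Inference with dropout disabled and batch normalization in running-stats
#' mode: repeated calls are identical and the output is invariant to
#' batching.
#'
#' @param state a [NetworkState-class].
#' @param imgs a [LabeledImage-class], matrix in \[0, 1\], or list of them.
#' @return for one image a named probability vector; for several, a matrix
#'   with one row per image (columns in `state@classes` order).
#' @export
predictProbs <- function(state, imgs) {
  probs <- softmaxRows(predictLogits(state, imgs))
  colnames(probs) <- state@classes
  if (nrow(probs) == 1L) probs[1L, ] else probs
}

#' Deterministic logits (pre-softmax scores)
#'
#' The raw class scores used by temperature scaling; same inference mode as
#' [predictProbs()].
#'
#' @inheritParams predictProbs
#' @return matrix of logits, one row per image.
#' @export
predictLogits <- function(state, imgs) {
  tn <- imagesToTensor(imgs)
  checkSpatial(tn$h, tn$w, state@config)
  fw <- netForward(state@params, state@buffers, state@config, tn, mode = "eval")
  fw$logits
}

#' Save / load a network checkpoint
#'
#' Single-file checkpoint holding the architecture, weights, buffers and
#' training history; the round-trip is exact.
#'
#' @param state a [NetworkState-class].
#' @param path checkpoint file path (`.rds`).
#' @return `saveCheckpoint` the path, invisibly; `loadCheckpoint` the
#'   restored [NetworkState-class].
#' @export
saveCheckpoint <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  stopIf(!file.exists(path), sprintf("checkpoint not found: %s", path),
         "notFoundError")
  st <- readRDS(path)
  stopIf(!methods::is(st, "NetworkState"), "file is not a network checkpoint",
         "integrityError")
  st
}
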