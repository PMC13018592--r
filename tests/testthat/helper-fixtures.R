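# Shared fixtures. Models are trained once per test run and memoized; all
# data are generated in code at a reduced problem size (32 px phantoms,
# narrow networks) so the full suite stays fast on one CPU.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtureEnv[[name]])) assign(name, maker(), envir = .fixtureEnv)
  .fixtureEnv[[name]]
}

easyMix32 <- function() {
  list(easy = list(params = phantomParams(imageSize = 32,
                                          lesionContrast = c(0.15, 0.25)),
                   weight = 1))
}

mixedMix32 <- function() defaultDifficultyMix(imageSize = 32)

# 280 easy phantoms: 200 train / 39 validation / 41 test
easyDataset <- function() {
  fixture("easyDs", function() {
    generateDataset(280, seed = 101, difficultyMix = easyMix32(),
                    splitFractions = c(train = 0.715, validation = 0.14,
                                       test = 0.145))
  })
}

# the well-trained reference model (easy task)
easyModel <- function() {
  fixture("easyModel", function() {
    trainNetwork(
      buildNetwork(networkConfig(blockChannels = c(8, 16, 32)), seed = 7),
      easyDataset(),
      trainingConfig(epochs = 80, batchSize = 8, learningRate = 3e-3,
                     seed = 7, patience = 80)
    )
  })
}

# mixed-difficulty data and a deliberately imperfect model: the rejection
# and flip stages only have work when errors occur
mixedDataset <- function() {
  fixture("mixedDs", function() {
    generateDataset(160, seed = 202, difficultyMix = mixedMix32(),
                    splitFractions = c(train = 0.625, validation = 0.175,
                                       test = 0.2))
  })
}

mixedModel <- function() {
  fixture("mixedModel", function() {
    trainNetwork(
      buildNetwork(networkConfig(blockChannels = c(6, 12)), seed = 5),
      mixedDataset(),
      trainingConfig(epochs = 40, batchSize = 8, learningRate = 3e-3,
                     seed = 5, patience = 40)
    )
  })
}

classOf <- function(state, probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1)
  state@classes[max.col(probs, ties.method = "first")]
}

accuracyOn <- function(state, imgs, labels) {
  probs <- predictProbs(state, lapply(imgs, function(im) {
    if (methods::is(im, "LabeledImage")) pixels(im) else im
  }))
  mean(classOf(state, probs) == labels)
}

strokePhantoms <- function(n, contrast = c(0.15, 0.25), seed = 900,
                           size = 32) {
  lapply(seq_len(n), function(i) {
    generatePhantom(phantomParams(imageSize = size, lesionContrast = contrast,
                                  seed = seed + i), "stroke",
                    sourceId = sprintf("stroke%03d", i))
  })
}
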