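test_that("normalized entropy matches hand-computed values and rejects bad input", {
  expect_identical(normalizedEntropy(c(0.5, 0.5)), 1)
  expect_identical(normalizedEntropy(c(1, 0)), 0)
  # -(0.9 log2 0.9 + 0.1 log2 0.1) = 0.46900
  expect_equal(normalizedEntropy(c(0.9, 0.1)), 0.4690, tolerance = 1e-4 / 0.469)
  expect_error(normalizedEntropy(c(0.7, 0.7)), class = "inputError")
  expect_error(normalizedEntropy(c(-0.2, 1.2)), class = "inputError")
})

test_that("entropy is bounded in [0,1] and maximal only at the uniform vector", {
  set.seed(31)
  for (i in seq_len(10000)) {
    k <- sample(2:5, 1)
    p <- runif(k)
    p <- p / sum(p)
    h <- normalizedEntropy(p)
    if (h < 0 || h > 1) fail("entropy out of bounds")
    if (max(abs(p - 1 / k)) > 1e-3 && h >= 1) fail("non-uniform vector reached H = 1")
  }
  expect_identical(normalizedEntropy(rep(1 / 4, 4)), 1)
})

test_that("MC prediction averages passes, nests seeds, and degenerates at p = 0", {
  st <- mixedModel()
  img <- images(mixedDataset())[[1]]
  pr <- mcPredict(st, img, nPasses = 8, p = 0.1, seed = 3)
  expect_equal(meanProbs(pr), colMeans(perPassProbs(pr)))
  expect_equal(unname(rowSums(perPassProbs(pr))), rep(1, 8), tolerance = 1e-6)
  expect_identical(predictedLabel(pr), st@classes[which.max(meanProbs(pr))])
  # pass-stream nesting: first N passes identical across different totals
  pr20 <- mcPredict(st, img, nPasses = 20, p = 0.1, seed = 3)
  expect_identical(perPassProbs(pr20)[1:8, ], perPassProbs(pr))
  # permutation invariance of the mean
  expect_equal(colMeans(perPassProbs(pr20)[sample(20), ]), meanProbs(pr20))

  det <- predictProbs(st, img)
  pr0 <- mcPredict(st, img, nPasses = 5, p = 0, seed = 1)
  expect_identical(unname(perPassProbs(pr0)[1, ]), unname(det))
  expect_true(all(apply(perPassProbs(pr0), 2, function(col) length(unique(col)) == 1)))
  pr1 <- mcPredict(st, img, nPasses = 1, p = 0.2, seed = 9)
  expect_identical(meanProbs(pr1), unname(perPassProbs(pr1)[1, ]))

  expect_error(mcPredict(buildNetwork(networkConfig(blockChannels = 4)), img),
               class = "stateError")
})

test_that("forward-pass sweep reuses pass streams and handles p = 0", {
  st <- mixedModel()
  ds <- mixedDataset()
  sw0 <- sweepForwardPasses(st, ds, nGrid = c(1, 4, 8), p = 0,
                            seed = 2, split = "test")
  expect_identical(length(unique(sw0$accuracy)), 1L)
  sw <- sweepForwardPasses(st, ds, nGrid = c(1, 4, 8), p = 0.1,
                           seed = 2, split = "test")
  # the N = 1 row equals single-pass accuracy computed directly
  sp <- CascadeCT:::splitImages(ds, "test")
  one <- vapply(seq_along(sp$images), function(i) {
    pr <- mcPredict(st, sp$images[[i]], nPasses = 1, p = 0.1,
                    seed = CascadeCT:::childSeed(2, i))
    predictedLabel(pr) == sp$labels[i]
  }, logical(1))
  expect_equal(sw$accuracy[1], mean(one))
  expect_error(sweepForwardPasses(st, ds, nGrid = c(0, 2)),
               class = "inputError")
})

test_that("accuracy saturates as the number of passes grows (majority of seeds)", {
  st <- mixedModel()
  ds <- mixedDataset()
  ok <- vapply(1:5, function(s) {
    sw <- sweepForwardPasses(st, ds, nGrid = c(1, 10, 20), p = 0.1,
                             seed = 100 + s, split = "test")
    abs(sw$accuracy[3] - sw$accuracy[2]) <= abs(sw$accuracy[2] - sw$accuracy[1])
  }, logical(1))
  expect_gte(sum(ok), 3)
})

test_that("separation score equals a brute-force pairwise oracle", {
  bruteForce <- function(h, correct) {
    hw <- h[!correct]
    hr <- h[correct]
    if (!length(hw) || !length(hr)) return(NA_real_)
    tot <- 0
    for (a in hw) for (b in hr) {
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    }
    tot / (length(hw) * length(hr))
  }
  set.seed(8)
  for (i in 1:25) {
    n <- sample(2:20, 1)
    h <- round(runif(n), 2)   # rounding forces ties
    correct <- runif(n) > 0.4
    expect_equal(separationScore(h, correct), bruteForce(h, correct))
  }
  expect_identical(separationScore(c(0.9, 0.1), c(FALSE, TRUE)), 1)
  expect_true(is.na(separationScore(c(0.1, 0.2), c(TRUE, TRUE))))
})

test_that("rate selection takes the argmax with ties toward smaller p", {
  sel <- CascadeCT:::selectRate(c(0.01, 0.05, 0.1), c(0.7, 0.9, 0.9))
  expect_identical(sel$pStar, 0.05)
  expect_identical(sel$note, "")
  selTie <- CascadeCT:::selectRate(c(0.01, 0.05), c(0.8, 0.8))
  expect_identical(selTie$pStar, 0.01)
  fallback <- CascadeCT:::selectRate(c(0.01, 0.5), c(NA_real_, NA_real_))
  expect_identical(fallback$pStar, 0.01)
  expect_match(fallback$note, "smallest rate")
})

test_that("dropout calibration falls back to the smallest rate when no errors occur", {
  # a constant-headed model (zeroed classifier weights, strong stroke bias)
  # is right on every stroke-only validation image at every dropout rate
  st <- mixedModel()
  st@params[["fc2.W"]][] <- 0
  st@params[["fc2.bias"]] <- c(10, -10)
  ds <- mixedDataset()
  strokeOnly <- ds
  keep <- ds@manifest$label == "stroke"
  strokeOnly@manifest <- ds@manifest[keep, ]
  strokeOnly@manifest$split <- "validation"
  strokeOnly@images <- ds@images[strokeOnly@manifest$source_id]
  expect_warning(
    cal <- calibrateDropout(st, strokeOnly, pGrid = c(0.01, 0.05),
                            nPasses = 3, seed = 1),
    "smallest rate"
  )
  expect_identical(selectedDropout(cal), 0.01)
})

test_that("dropout calibration scores separation on a fallible model", {
  st <- mixedModel()
  cal <- calibrateDropout(st, mixedDataset(), pGrid = c(0.01, 0.1, 0.3),
                          nPasses = 10, seed = 6)
  expect_true(selectedDropout(cal) %in% c(0.01, 0.1, 0.3))
  defined <- !is.na(cal@separation)
  expect_true(any(defined))
  expect_true(all(cal@separation[defined] >= 0 & cal@separation[defined] <= 1))
  expect_identical(nrow(cal@summaries), 3L)
})

test_that("alpha is the mean entropy and the rejection rule is inclusive", {
  expect_equal(alphaValue(computeAlpha(c(0.2, 0.4))), 0.3)
  expect_identical(alphaValue(computeAlpha(0.7)), 0.7)
  expect_identical(alphaValue(computeAlpha(c(0, 0, 0))), 0)
  expect_error(computeAlpha(numeric(0)), class = "dataError")

  st <- mixedModel()
  img <- images(mixedDataset())[[2]]
  pr <- mcPredict(st, img, nPasses = 5, p = 0.1, seed = 2)
  atH <- new("UncertaintyThreshold", alpha = entropyValue(pr), source = "test")
  expect_identical(uqFilter(pr, atH), "reliable")
  below <- new("UncertaintyThreshold",
               alpha = max(entropyValue(pr) - 1e-9, 0), source = "test")
  if (entropyValue(pr) > 1e-9) expect_identical(uqFilter(pr, below), "flagged")
  expect_identical(uqFilter(pr, new("UncertaintyThreshold", alpha = 1,
                                    source = "test")), "reliable")
})

test_that("entropy rejection does not hurt accuracy on mixed data (majority of seeds)", {
  st <- mixedModel()
  ds <- mixedDataset()
  sp <- CascadeCT:::splitImages(ds, "test")
  ok <- vapply(1:5, function(s) {
    ents <- numeric(length(sp$images))
    corr <- logical(length(sp$images))
    for (i in seq_along(sp$images)) {
      pr <- mcPredict(st, sp$images[[i]], nPasses = 10, p = 0.1,
                      seed = CascadeCT:::childSeed(300 + s, i))
      ents[i] <- entropyValue(pr)
      corr[i] <- predictedLabel(pr) == sp$labels[i]
    }
    alpha <- mean(ents)
    keep <- ents <= alpha
    mean(corr[keep]) >= mean(corr)
  }, logical(1))
  expect_gte(sum(ok), 3)
})
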