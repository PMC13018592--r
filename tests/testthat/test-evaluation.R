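countsToVectors <- function(tp, fn, tn, fp) {
  list(labels = c(rep("stroke", tp + fn), rep("normal", tn + fp)),
       predictions = c(rep("stroke", tp), rep("normal", fn),
                       rep("normal", tn), rep("stroke", fp)))
}

test_that("metrics from confusion counts match the balanced-test benchmark", {
  v <- countsToVectors(tp = 93, fn = 7, tn = 100, fp = 0)
  res <- confusionAndMetrics(v$labels, v$predictions)
  expect_identical(res$counts[c("tp", "fn", "tn", "fp")],
                   list(tp = 93L, fn = 7L, tn = 100L, fp = 0L))
  m <- res$metrics
  val <- function(x) m$value[m$metric == x]
  expect_equal(val("accuracy"), 96.5)
  expect_equal(val("sensitivity"), 93)
  expect_equal(val("specificity"), 100)
  expect_equal(val("precision"), 100)
  # a sensitivity of 83.08% at 100% precision gives F1 = 90.76%
  v2 <- countsToVectors(tp = 54, fn = 11, tn = 35, fp = 0)
  m2 <- confusionAndMetrics(v2$labels, v2$predictions)$metrics
  expect_equal(round(m2$value[m2$metric == "sensitivity"], 2), 83.08)
  expect_equal(round(m2$value[m2$metric == "f1"], 2), 90.76)
  # all-correct degenerates to 100 across the board
  v3 <- countsToVectors(tp = 5, fn = 0, tn = 5, fp = 0)
  m3 <- confusionAndMetrics(v3$labels, v3$predictions)$metrics
  expect_true(all(m3$value == 100))
})

test_that("abstentions are excluded from counts and zero denominators give NA", {
  labels <- c("stroke", "stroke", "normal", "normal")
  preds <- c("stroke", NA, "normal", NA)
  res <- confusionAndMetrics(labels, preds)
  expect_identical(res$counts$abstained, 2L)
  expect_identical(res$counts$tp + res$counts$fn + res$counts$tn + res$counts$fp, 2L)
  # no predicted strokes at all -> precision undefined, not zero
  res2 <- confusionAndMetrics(c("normal", "normal"), c("normal", "normal"))
  m2 <- res2$metrics
  expect_true(is.na(m2$value[m2$metric == "precision"]))
  expect_true(is.na(m2$value[m2$metric == "sensitivity"]))
  expect_false(is.na(m2$value[m2$metric == "accuracy"]))
})

test_that("Wilson intervals reproduce the reference bounds and contain p-hat", {
  expect_equal(round(100 * wilsonCI(100, 100)[["lower"]], 2), 96.30)
  expect_identical(wilsonCI(100, 100)[["upper"]], 1)
  expect_equal(round(100 * wilsonCI(93, 93)[["lower"]], 2), 96.03)
  ci0 <- wilsonCI(0, 100)
  expect_identical(ci0[["lower"]], 0)
  expect_equal(round(ci0[["upper"]], 4), 0.037)
  ci50 <- wilsonCI(50, 100)
  expect_equal(unname(ci50), c(0.4038, 0.5962), tolerance = 1e-3 / 0.4)
  set.seed(20)
  for (i in 1:100) {
    n <- sample(1:200, 1)
    s <- sample(0:n, 1)
    ci <- wilsonCI(s, n)
    expect_gte(s / n, ci[["lower"]] - 1e-12)
    expect_lte(s / n, ci[["upper"]] + 1e-12)
  }
  expect_error(wilsonCI(1, 0), class = "inputError")
})

test_that("F1 from precision and sensitivity equals the count form exactly", {
  set.seed(9)
  for (i in 1:50) {
    tp <- sample(1:40, 1); fn <- sample(0:20, 1)
    tn <- sample(1:40, 1); fp <- sample(0:20, 1)
    v <- countsToVectors(tp, fn, tn, fp)
    m <- confusionAndMetrics(v$labels, v$predictions)$metrics
    expect_equal(m$value[m$metric == "f1"],
                 100 * 2 * tp / (2 * tp + fp + fn))
  }
})

test_that("the perturbation curve starts at the unperturbed confidence and ends fully replaced", {
  st <- mixedModel()
  imgs <- strokePhantoms(4, seed = 7700)
  maps <- lapply(imgs, function(im) {
    saliencyMap(st, im, method = "gradcam", mode = "deterministic")
  })
  mc <- morfCurve(st, imgs, maps, step = 0.25, replacement = 0.5)
  for (i in seq_along(imgs)) {
    p0 <- predictProbs(st, pixels(imgs[[i]]))
    expect_identical(mc$perImage[i, 1], unname(p0[which.max(p0)]))
    pFull <- predictProbs(st, matrix(0.5, 32, 32))
    expect_equal(mc$perImage[i, ncol(mc$perImage)],
                 unname(pFull[which.max(p0)]))
  }
  expect_identical(mc$curve$fraction[1], 0)
  expect_identical(mc$curve$fraction[nrow(mc$curve)], 1)
  # a constant-output model yields a flat curve for any map
  stConst <- st
  stConst@params[["fc2.W"]][] <- 0
  stConst@params[["fc2.bias"]][] <- 0
  mcFlat <- morfCurve(stConst, imgs, maps, step = 0.25)
  expect_true(all(abs(mcFlat$perImage - 0.5) < 1e-12))
  expect_error(morfCurve(st, imgs, maps[-1]), class = "inputError")
  expect_error(morfCurve(st, imgs[[1]], matrix(0.5, 8, 8)),
               class = "inputError")
})

test_that("AUPC is the trapezoidal area with ties resolved toward gradcam", {
  grid <- seq(0, 1, 0.1)
  flat1 <- data.frame(fraction = grid, mean_conf = 1)
  linear <- data.frame(fraction = grid, mean_conf = 1 - grid)
  sel <- aupcAndSelect(list(gradcam = flat1, scorecam = linear))
  expect_identical(unname(sel$aupc[["gradcam"]]), 1)
  expect_equal(unname(sel$aupc[["scorecam"]]), 0.5)
  expect_identical(sel$selected, "scorecam")
  tie <- aupcAndSelect(list(scorecam = linear, gradcam = linear))
  expect_identical(tie$selected, "gradcam")
  # refinement of a piecewise-linear curve leaves the trapezoid area unchanged
  fine <- seq(0, 1, 0.05)
  linFine <- data.frame(fraction = fine, mean_conf = 1 - fine)
  expect_equal(unname(aupcAndSelect(list(gradcam = linFine))$aupc[["gradcam"]]),
               0.5)
  expect_error(aupcAndSelect(list(a = flat1,
                                  b = data.frame(fraction = c(0, 1),
                                                 mean_conf = c(1, 0)))),
               class = "inputError")
})

test_that("saliency-ordered removal collapses confidence faster than random removal", {
  st <- easyModel()
  imgs <- strokePhantoms(50, seed = 8100)
  maps <- lapply(imgs, function(im) {
    saliencyMap(st, im, method = "gradcam", mode = "deterministic")
  })
  set.seed(55)
  randomMaps <- lapply(imgs, function(im) {
    matrix(runif(length(pixels(im))), nrow(pixels(im)), ncol(pixels(im)))
  })
  aupcSal <- morfCurve(st, imgs, maps, step = 0.1)$aupc
  aupcRnd <- morfCurve(st, imgs, randomMaps, step = 0.1)$aupc
  expect_lt(aupcSal, aupcRnd)
})

test_that("calibration metrics match single-bin arithmetic and ECE <= MCE", {
  perfect <- calibrationMetrics(rep(1, 5), rep(TRUE, 5), c(1, 1, 1, 0, 0),
                                c("stroke", "stroke", "stroke", "normal",
                                  "normal"))
  expect_identical(perfect$ece, 0)
  expect_identical(perfect$mce, 0)
  expect_identical(perfect$brier, 0)
  one <- calibrationMetrics(0.7, TRUE, 0.7, "stroke", bins = 1)
  expect_equal(one$ece, 0.3)
  expect_equal(one$mce, 0.3)
  half <- calibrationMetrics(0.5, TRUE, 0.5, "stroke")
  expect_equal(half$brier, 0.25)
  set.seed(17)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    conf <- runif(n, 0.5, 1)
    corr <- runif(n) < conf
    pPos <- runif(n)
    lab <- sample(c("stroke", "normal"), n, replace = TRUE)
    cm <- calibrationMetrics(conf, corr, pPos, lab)
    expect_lte(cm$ece, cm$mce + 1e-12)
    expect_gte(cm$brier, 0)
    expect_lte(cm$brier, 1)
  }
  expect_error(calibrationMetrics(numeric(0), logical(0), numeric(0),
                                  character(0)),
               class = "dataError")
})

test_that("temperature scaling recovers known temperatures and keeps decisions", {
  set.seed(23)
  n <- 20000
  z <- rnorm(n, 0, 2)                       # calibrated log-odds of stroke
  pStroke <- 1 / (1 + exp(-z))
  labels <- ifelse(runif(n) < pStroke, "stroke", "normal")
  logits <- cbind(z / 2, -z / 2)
  fit1 <- fitTemperature(logits, labels)
  expect_equal(fit1$temperature, 1, tolerance = 0.02)
  fit3 <- fitTemperature(3 * logits, labels)
  expect_equal(fit3$temperature, 3, tolerance = 0.05)
  # argmax predictions invariant to the scale
  p1 <- max.col(CascadeCT:::softmaxRows(logits))
  p3 <- max.col(CascadeCT:::softmaxRows(3 * logits / fit3$temperature))
  expect_identical(p1, p3)
  expect_error(fitTemperature(logits[1:5, ], rep("stroke", 5)),
               class = "fittingError")
})

test_that("risk-coverage sweeps thresholds with non-decreasing coverage", {
  rcPerfect <- riskCoverageCurve(c(0.1, 0.2, 0.3), c(TRUE, TRUE, TRUE))
  expect_true(all(rcPerfect$risk[rcPerfect$coverage > 0] == 0))
  ents <- c(0.05, 0.1, 0.2, 0.4, 0.9)
  corr <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  rc <- riskCoverageCurve(ents, corr)
  expect_identical(rc$coverage[nrow(rc)], 1)
  expect_equal(rc$risk[nrow(rc)], 1 - mean(corr))
  expect_true(all(diff(rc$coverage) >= 0))
  # perfectly ordered errors: risk non-increasing as coverage shrinks,
  # verified against a brute-force enumeration
  brute <- t(vapply(sort(unique(c(0, 1, ents))), function(t) {
    sel <- ents <= t
    c(cov = mean(sel), risk = if (any(sel)) 1 - mean(corr[sel]) else NA_real_)
  }, numeric(2)))
  expect_equal(rc$coverage, unname(brute[, "cov"]))
  expect_equal(rc$risk, unname(brute[, "risk"]))
  covered <- !is.na(rc$risk)
  expect_true(all(diff(rc$risk[covered]) >= 0))
  expect_error(riskCoverageCurve(numeric(0), logical(0)), class = "dataError")
})
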