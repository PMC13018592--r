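# Classification, faithfulness, and calibration evaluation.

#' Confusion counts and classification metrics with Wilson intervals
#'
#' Positive class is stroke. Abstained samples (`NA` predictions, e.g.
#' flagged-for-review cases) are excluded from the counts but tallied. Each
#' metric is reported as a percentage with its 95% Wilson interval; a metric
#' with a zero denominator is `NA` (undefined), never 0.
#'
#' @param labels true labels (`"stroke"`/`"normal"`).
#' @param predictions predicted labels, `NA` for abstentions.
#' @param level confidence level of the Wilson intervals.
#' @return list with `counts` (tp, fn, tn, fp, abstained) and `metrics`
#'   (data.frame: metric, value, lower, upper, in percent).
#' @export
confusionAndMetrics <- function(labels, predictions, level = 0.95) {
  stopIf(length(labels) != length(predictions),
         "labels and predictions must align", "inputError")
  keep <- !is.na(predictions)
  abstained <- sum(!keep)
  lab <- labels[keep]
  pred <- predictions[keep]
  tp <- sum(lab == "stroke" & pred == "stroke")
  fn <- sum(lab == "stroke" & pred == "normal")
  tn <- sum(lab == "normal" & pred == "normal")
  fp <- sum(lab == "normal" & pred == "stroke")
  pct <- function(succ, tot) {
    if (tot == 0) return(c(NA_real_, NA_real_, NA_real_))
    ci <- wilsonCI(succ, tot, level)
    c(100 * succ / tot, 100 * ci[1], 100 * ci[2])
  }
  acc <- pct(tp + tn, tp + tn + fp + fn)
  sens <- pct(tp, tp + fn)
  spec <- pct(tn, tn + fp)
  prec <- pct(tp, tp + fp)
  f1 <- if (is.na(sens[1]) || is.na(prec[1]) || (sens[1] + prec[1]) == 0) {
    c(NA_real_, NA_real_, NA_real_)
  } else {
    c(2 * prec[1] * sens[1] / (prec[1] + sens[1]), NA_real_, NA_real_)
  }
  metrics <- data.frame(
    metric = c("accuracy", "sensitivity", "specificity", "precision", "f1"),
    value = c(acc[1], sens[1], spec[1], prec[1], f1[1]),
    lower = c(acc[2], sens[2], spec[2], prec[2], f1[2]),
    upper = c(acc[3], sens[3], spec[3], prec[3], f1[3])
  )
  list(counts = list(tp = tp, fn = fn, tn = tn, fp = fp, abstained = abstained),
       metrics = metrics)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' `(p + z^2/2n +- z * sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)` with the
#' exact two-sided normal quantile; well behaved at 0 and n successes.
#'
#' @param successes number of successes (0..trials).
#' @param trials number of trials (>= 1).
#' @param level confidence level.
#' @return numeric `c(lower, upper)` on the proportion scale.
#' @examples
#' round(wilsonCI(100, 100) * 100, 2) # 96.30 100.00
#' @export
wilsonCI <- function(successes, trials, level = 0.95) {
  stopIf(trials < 1, "trials must be >= 1", "inputError")
  stopIf(successes < 0 || successes > trials,
         "successes must be within 0..trials", "inputError")
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2))
  ctr <- p + z^2 / (2 * trials)
  denom <- 1 + z^2 / trials
  c(lower = max(0, (ctr - half) / denom), upper = min(1, (ctr + half) / denom))
}

#' Most-relevant-first (MoRF) perturbation curve
#'
#' Per image, pixels are ranked by saliency (descending, ties in row-major
#' order); at each removal fraction f the top-f pixels are replaced by
#' `replacement` and the deterministic softmax confidence of the originally
#' predicted class is recorded. Confidence is aggregated as mean with a 95%
#' normal band across images, and the area under the mean curve (AUPC,
#' trapezoidal, unit square) is attached. A faithful saliency method makes
#' the curve drop fast, giving low AUPC.
#'
#' @param state a trained [NetworkState-class].
#' @param imgs list of images (matrices or [LabeledImage-class]).
#' @param maps aligned list of [SaliencyMap-class] (or matrices).
#' @param step fraction grid step (grid is `seq(0, 1, step)`).
#' @param replacement replacement intensity; default the mean intensity of
#'   the supplied images.
#' @return list with `curve` (data.frame fraction, mean_conf, lo, hi),
#'   `aupc`, `aupcStepSum` (the plain sum of mean confidences over the grid,
#'   a scale sometimes used for reporting), and `perImage` confidences.
#' @export
morfCurve <- function(state, imgs, maps, step = 0.05, replacement = NULL) {
  if (methods::is(imgs, "LabeledImage") || is.matrix(imgs)) imgs <- list(imgs)
  if (methods::is(maps, "SaliencyMap") || is.matrix(maps)) maps <- list(maps)
  stopIf(length(imgs) != length(maps), "one saliency map per image required",
         "inputError")
  mats <- lapply(imgs, function(im) if (methods::is(im, "LabeledImage")) im@pixels else im)
  vals <- lapply(maps, function(mp) if (methods::is(mp, "SaliencyMap")) mp@values else mp)
  for (i in seq_along(mats)) {
    stopIf(!identical(dim(mats[[i]]), dim(vals[[i]])),
           "saliency/image shape mismatch", "inputError")
  }
  if (is.null(replacement)) replacement <- mean(vapply(mats, mean, numeric(1)))
  fracs <- seq(0, 1, by = step)
  if (fracs[length(fracs)] < 1) fracs <- c(fracs, 1)
  conf <- matrix(0, length(mats), length(fracs))
  for (i in seq_along(mats)) {
    img <- mats[[i]]
    np <- length(img)
    # row-major flattening so ties resolve in row-major order
    salRM <- as.vector(t(vals[[i]]))
    ordRM <- order(-salRM)                      # stable: ties keep row-major order
    p0 <- predictProbs(state, img)
    cls <- which.max(p0)
    pert <- img
    prevK <- 0L
    for (fi in seq_along(fracs)) {
      k <- floor(fracs[fi] * np)
      if (k > prevK) {
        sel <- ordRM[(prevK + 1L):k]
        rows <- (sel - 1L) %/% ncol(img) + 1L
        cols <- (sel - 1L) %% ncol(img) + 1L
        pert[cbind(rows, cols)] <- replacement
        prevK <- k
      }
      conf[i, fi] <- if (k == 0) p0[cls] else predictProbs(state, pert)[cls]
    }
  }
  meanC <- colMeans(conf)
  se <- apply(conf, 2, sd) / sqrt(nrow(conf))
  curve <- data.frame(fraction = fracs, mean_conf = meanC,
                      lo = meanC - 1.96 * se, hi = meanC + 1.96 * se)
  aupc <- sum(diff(fracs) * (head(meanC, -1) + meanC[-1]) / 2)
  list(curve = curve, aupc = aupc, aupcStepSum = sum(meanC), perImage = conf)
}

#' AUPC per saliency method and method selection
#'
#' Trapezoidal area of each mean-confidence curve over the unit fraction
#' grid; the method with the lowest AUPC (fastest confidence collapse, i.e.
#' most faithful attribution) is selected, ties broken toward `gradcam`.
#'
#' @param curves named list of results from [morfCurve()] (or of data.frames
#'   with `fraction` and `mean_conf`), one per method, on a common grid.
#' @return list with `aupc` (named numeric) and `selected` (method name).
#' @export
aupcAndSelect <- function(curves) {
  getCurve <- function(x) if (is.data.frame(x)) x else x$curve
  grids <- lapply(curves, function(x) getCurve(x)$fraction)
  for (g in grids) {
    stopIf(!isTRUE(all.equal(g, grids[[1]])), "curves must share the fraction grid",
           "inputError")
  }
  aupc <- vapply(curves, function(x) {
    cv <- getCurve(x)
    sum(diff(cv$fraction) * (head(cv$mean_conf, -1) + cv$mean_conf[-1]) / 2)
  }, numeric(1))
  best <- min(aupc)
  cand <- names(aupc)[aupc <= best + 1e-12]
  selected <- if ("gradcam" %in% cand) "gradcam" else cand[1]
  list(aupc = aupc, selected = selected)
}

#' Calibration metrics: ECE, MCE, Brier
#'
#' ECE is the bin-weighted mean absolute gap between confidence and
#' accuracy over `bins` equal-width confidence bins on \[0, 1\]; MCE is the
#' maximum gap over non-empty bins; the Brier score is the mean squared
#' error between the positive-class (stroke) probability and the binary
#' outcome.
#'
#' @param confidences confidence of the predicted class per sample.
#' @param correct logical correctness flags per sample.
#' @param pPositive positive-class (stroke) probability per sample.
#' @param labels true labels (`"stroke"`/`"normal"`).
#' @param bins number of equal-width bins (>= 1).
#' @return list with `ece`, `mce`, `brier`, and the reliability-diagram
#'   table `binTable` (bin, conf, acc, count).
#' @export
calibrationMetrics <- function(confidences, correct, pPositive, labels,
                               bins = 10L) {
  stopIf(length(confidences) == 0, "empty input", "dataError")
  stopIf(bins < 1, "bins must be >= 1", "inputError")
  n <- length(confidences)
  binId <- pmin(pmax(ceiling(confidences * bins), 1L), bins)
  ece <- 0
  mce <- 0
  tab <- list()
  for (b in seq_len(bins)) {
    sel <- binId == b
    nb <- sum(sel)
    if (nb == 0) next
    accB <- mean(correct[sel])
    confB <- mean(confidences[sel])
    gap <- abs(accB - confB)
    ece <- ece + nb / n * gap
    mce <- max(mce, gap)
    tab[[length(tab) + 1L]] <- data.frame(bin = b, conf = confB, acc = accB,
                                          count = nb)
  }
  y <- as.numeric(labels == "stroke")
  brier <- mean((pPositive - y)^2)
  list(ece = ece, mce = mce, brier = brier, binTable = do.call(rbind, tab))
}

#' Fit a temperature for post-hoc probability calibration
#'
#' Finds the scalar T in \[0.05, 20\] minimizing the negative log-likelihood
#' of `softmax(logits / T)` on validation data. Monotone scaling leaves the
#' argmax predictions unchanged. The calibration metrics are recomputed
#' after scaling.
#'
#' @param logits matrix of pre-softmax scores (one row per sample; stroke
#'   column first, as produced by [predictLogits()]).
#' @param labels true labels aligned with the rows.
#' @param bins bins for the recomputed ECE/MCE.
#' @return list with `temperature`, `nll`, and `report` (the post-scaling
#'   [calibrationMetrics()] output).
#' @export
fitTemperature <- function(logits, labels, bins = 10L) {
  stopIf(length(unique(labels)) < 2, "temperature fitting needs both classes",
         "fittingError")
  classes <- c("stroke", "normal")
  yIdx <- match(labels, classes)
  stopIf(anyNA(yIdx), "labels must be stroke/normal", "inputError")
  nll <- function(tt) {
    p <- softmaxRows(logits / tt)
    -mean(log(pmax(p[cbind(seq_len(nrow(p)), yIdx)], 1e-12)))
  }
  opt <- optimize(nll, interval = c(0.05, 20), tol = 1e-4)
  tt <- opt$minimum
  p <- softmaxRows(logits / tt)
  pred <- classes[max.col(p, ties.method = "first")]
  rep <- calibrationMetrics(
    confidences = p[cbind(seq_len(nrow(p)), max.col(p, ties.method = "first"))],
    correct = pred == labels, pPositive = p[, 1], labels = labels, bins = bins
  )
  list(temperature = tt, nll = opt$objective, report = rep)
}

#' Risk-coverage curve of the entropy rejection rule
#'
#' Sweeps the entropy threshold over the sorted unique entropy values (plus
#' 0 and 1); at each threshold t, coverage is the fraction of samples with
#' H <= t and risk is 1 - accuracy among the covered samples (undefined,
#' `NA`, at coverage 0). Coverage is non-decreasing in t.
#'
#' @param entropies per-sample entropies in \[0, 1\].
#' @param correct aligned logical correctness flags.
#' @return data.frame with `threshold`, `coverage`, `risk`.
#' @export
riskCoverageCurve <- function(entropies, correct) {
  stopIf(length(entropies) == 0, "empty input", "dataError")
  stopIf(length(entropies) != length(correct), "inputs must align", "inputError")
  ts <- sort(unique(c(0, 1, entropies)))
  n <- length(entropies)
  res <- lapply(ts, function(t) {
    sel <- entropies <= t
    cov <- mean(sel)
    risk <- if (any(sel)) 1 - mean(correct[sel]) else NA_real_
    data.frame(threshold = t, coverage = cov, risk = risk)
  })
  do.call(rbind, res)
}
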