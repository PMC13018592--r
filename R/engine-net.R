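# Network assembly: flat parameter lists, forward/backward passes, Adam.
#
# Trainable parameters live in a flat named list ("b1.W", "b1.gamma", ...,
# "fc1.W", "fc2.bias"); batch-norm running statistics live in a parallel
# `buffers` list and are never counted as trainable.

initParams <- function(cfg, seed) {
  set.seed(seed)
  heUniform <- function(nr, nc, fanIn) {
    lim <- sqrt(6 / fanIn)
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  params <- list()
  buffers <- list()
  k2 <- cfg@kernelSize^2
  cin <- cfg@inChannels
  for (b in seq_along(cfg@blockChannels)) {
    cout <- cfg@blockChannels[b]
    pre <- paste0("b", b, ".")
    params[[paste0(pre, "W")]] <- heUniform(k2 * cin, cout, k2 * cin)
    params[[paste0(pre, "bias")]] <- numeric(cout)
    params[[paste0(pre, "gamma")]] <- rep(1, cout)
    params[[paste0(pre, "beta")]] <- numeric(cout)
    if (cin != cout) {
      params[[paste0(pre, "projW")]] <- heUniform(cin, cout, cin)
      params[[paste0(pre, "projb")]] <- numeric(cout)
    }
    buffers[[paste0(pre, "rmean")]] <- numeric(cout)
    buffers[[paste0(pre, "rvar")]] <- rep(1, cout)
    cin <- cout
  }
  dFlat <- cfg@poolOutput^2 * cin
  params[["fc1.W"]] <- heUniform(dFlat, cfg@latentDim, dFlat)
  params[["fc1.bias"]] <- numeric(cfg@latentDim)
  params[["fc2.W"]] <- heUniform(cfg@latentDim, cfg@numClasses, cfg@latentDim)
  params[["fc2.bias"]] <- numeric(cfg@numClasses)
  list(params = params, buffers = buffers)
}

imagesToTensor <- function(imgs, checkRange = TRUE) {
  if (methods::is(imgs, "LabeledImage")) imgs <- list(imgs)
  if (is.matrix(imgs)) imgs <- list(imgs)
  mats <- lapply(imgs, function(im) if (methods::is(im, "LabeledImage")) im@pixels else im)
  d <- dim(mats[[1]])
  if (any(!vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stopIf(TRUE, "all images in a batch must share dimensions", "shapeError")
  if (checkRange) {
    rng <- range(vapply(mats, min, 0), vapply(mats, max, 0))
    stopIf(rng[1] < 0 || rng[2] > 1,
           "image values must lie in [0, 1]", "inputRangeError")
  }
  n <- length(mats)
  h <- d[1]
  w <- d[2]
  x <- matrix(0, n * h * w, 1)
  for (i in seq_len(n)) {
    x[((i - 1L) * h * w + 1L):(i * h * w), 1L] <- as.vector(t(mats[[i]]))
  }
  nnTensor(x, n, h, w)
}

checkSpatial <- function(h, w, cfg) {
  nb <- length(cfg@blockChannels)
  hh <- h
  ww <- w
  for (b in seq_len(nb)) {
    hh <- hh %/% 2L
    ww <- ww %/% 2L
  }
  stopIf(hh < 1L || ww < 1L || hh < cfg@poolOutput || ww < cfg@poolOutput,
         sprintf("image %dx%d too small for %d pooling stages (adaptive pool %d)",
                 h, w, nb, cfg@poolOutput),
         "shapeError")
}

# Full forward pass. mode: "eval" (no dropout, running BN stats),
# "train" (dropout at config rate, batch BN stats), "mc" (dropout at rate
# `p`, running BN stats). Dropout masks are drawn from the current RNG
# stream, so callers control determinism with set.seed().
netForward <- function(params, buffers, cfg, tn, mode = "eval", p = 0,
                       keepCache = FALSE) {
  training <- identical(mode, "train")
  rate <- if (training) cfg@dropoutRate else if (identical(mode, "mc")) p else 0
  nB <- length(cfg@blockChannels)
  caches <- if (keepCache) vector("list", nB) else NULL
  targetA <- NULL
  for (b in seq_len(nB)) {
    pre <- paste0("b", b, ".")
    inTn <- tn
    cv <- convForward(tn, params[[paste0(pre, "W")]],
                      params[[paste0(pre, "bias")]], cfg@kernelSize)
    bn <- bnForward(cv$out$x, params[[paste0(pre, "gamma")]],
                    params[[paste0(pre, "beta")]],
                    buffers[[paste0(pre, "rmean")]],
                    buffers[[paste0(pre, "rvar")]], training)
    if (training) {
      buffers[[paste0(pre, "rmean")]] <- bn$rmean
      buffers[[paste0(pre, "rvar")]] <- bn$rvar
    }
    relu <- bn$y
    relu[relu < 0] <- 0
    hasProj <- !is.null(params[[paste0(pre, "projW")]])
    skip <- if (hasProj) {
      inTn$x %*% params[[paste0(pre, "projW")]] +
        rep(params[[paste0(pre, "projb")]], each = nrow(inTn$x))
    } else {
      inTn$x
    }
    added <- relu + skip
    mask <- dropoutMask(nrow(added), ncol(added), rate)
    dropped <- if (is.null(mask)) added else added * mask
    mp <- maxPoolForward(nnTensor(dropped, tn$n, tn$h, tn$w))
    if (b == nB) targetA <- nnTensor(relu, tn$n, tn$h, tn$w)
    if (keepCache) {
      caches[[b]] <- list(inTn = inTn, conv = cv, bn = bn, mask = mask,
                          preTn = nnTensor(dropped, tn$n, tn$h, tn$w),
                          mp = mp, hasProj = hasProj)
    }
    tn <- mp$out
  }
  ap <- adaptPoolForward(tn, cfg@poolOutput)
  flat <- flattenForward(ap$out)
  latent <- denseForward(flat, params[["fc1.W"]], params[["fc1.bias"]])
  logits <- denseForward(latent, params[["fc2.W"]], params[["fc2.bias"]])
  list(logits = logits, probs = softmaxRows(logits), caches = caches,
       ap = ap, poolTn = tn, flat = flat, latent = latent,
       targetA = targetA, buffers = buffers, mode = mode)
}

# Backward pass from a gradient at the logits. Returns the flat gradient
# list plus the gradient at the last block's ReLU feature maps (`dTargetA`),
# which Grad-CAM variants consume.
netBackward <- function(fw, dLogits, params, cfg) {
  training <- identical(fw$mode, "train")
  grads <- list()
  grads[["fc2.W"]] <- crossprod(fw$latent, dLogits)
  grads[["fc2.bias"]] <- colSums(dLogits)
  dLatent <- dLogits %*% t(params[["fc2.W"]])
  grads[["fc1.W"]] <- crossprod(fw$flat, dLatent)
  grads[["fc1.bias"]] <- colSums(dLatent)
  dFlat <- dLatent %*% t(params[["fc1.W"]])
  k <- cfg@poolOutput
  Clast <- ncol(fw$poolTn$x)
  dPool <- flattenBackward(dFlat, fw$poolTn$n, k * k, Clast)
  dX <- adaptPoolBackward(dPool, fw$ap, fw$poolTn, k)
  nB <- length(cfg@blockChannels)
  dTargetA <- NULL
  for (b in rev(seq_len(nB))) {
    pre <- paste0("b", b, ".")
    cache <- fw$caches[[b]]
    dPre <- maxPoolBackward(dX, cache$mp, cache$preTn)
    dAdded <- if (is.null(cache$mask)) dPre else dPre * cache$mask
    if (b == nB) dTargetA <- nnTensor(dAdded, cache$preTn$n, cache$preTn$h, cache$preTn$w)
    dBnY <- dAdded * (cache$bn$y > 0)
    bnb <- bnBackward(dBnY, cache$bn, params[[paste0(pre, "gamma")]], training)
    grads[[paste0(pre, "gamma")]] <- bnb$dgamma
    grads[[paste0(pre, "beta")]] <- bnb$dbeta
    cvb <- convBackward(bnb$dx, cache$conv, params[[paste0(pre, "W")]],
                        cache$inTn, cfg@kernelSize)
    grads[[paste0(pre, "W")]] <- cvb$dW
    grads[[paste0(pre, "bias")]] <- cvb$db
    dIn <- cvb$dx
    if (cache$hasProj) {
      grads[[paste0(pre, "projW")]] <- crossprod(cache$inTn$x, dAdded)
      grads[[paste0(pre, "projb")]] <- colSums(dAdded)
      dIn <- dIn + dAdded %*% t(params[[paste0(pre, "projW")]])
    } else {
      dIn <- dIn + dAdded
    }
    dX <- dIn
  }
  list(grads = grads, dTargetA = dTargetA)
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}

crossEntropy <- function(probs, onehot) {
  eps <- 1e-12
  -mean(log(pmax(rowSums(probs * onehot), eps)))
}
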