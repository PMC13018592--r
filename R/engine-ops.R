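# Low-level minibatch tensor operations.
#
# A feature tensor is a list(x, n, h, w) where `x` is an (n*h*w) x channels
# matrix whose rows are ordered image-major, then row-major within an image:
# row((img, i, j)) = (img-1)*h*w + (i-1)*w + j. All convolutions are done as
# im2col + one BLAS matrix product; index maps are cached per shape.

.idxCache <- new.env(parent = emptyenv())

nnTensor <- function(x, n, h, w) list(x = x, n = n, h = h, w = w)

# index maps for same-padding k x k convolution at a given batch shape
convIdx <- function(n, h, w, k) {
  key <- paste("c", n, h, w, k, sep = "_")
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p
  wp <- w + 2L * p
  i <- rep(seq_len(h), each = w)
  j <- rep(seq_len(w), times = h)
  k2 <- k * k
  idx1 <- matrix(0L, h * w, k2)
  o <- 0L
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      o <- o + 1L
      idx1[, o] <- (i + di - 2L) * wp + (j + dj - 1L)
    }
  }
  off <- rep((seq_len(n) - 1L) * hp * wp, each = h * w)
  idx <- idx1[rep(seq_len(h * w), times = n), , drop = FALSE] + off
  pidx <- rep((i - 1L + p) * wp + (j + p), times = n) + off
  res <- list(idx = idx, pidx = pidx, hp = hp, wp = wp, k2 = k2)
  assign(key, res, envir = .idxCache)
  res
}

# weight layout: rows indexed (channel-major, offset-minor): row (c-1)*k2 + o
convForward <- function(tn, W, b, k) {
  ci <- convIdx(tn$n, tn$h, tn$w, k)
  C <- ncol(tn$x)
  nhw <- nrow(tn$x)
  xp <- matrix(0, tn$n * ci$hp * ci$wp, C)
  xp[ci$pidx, ] <- tn$x
  cols <- xp[as.vector(ci$idx), , drop = FALSE]
  dim(cols) <- c(nhw, ci$k2, C)
  X <- matrix(cols, nhw, ci$k2 * C)
  y <- X %*% W
  y <- y + rep(b, each = nhw)
  list(out = nnTensor(y, tn$n, tn$h, tn$w), X = X, Cin = C)
}

convBackward <- function(dY, cache, W, tn, k) {
  ci <- convIdx(tn$n, tn$h, tn$w, k)
  nhw <- nrow(dY)
  dW <- crossprod(cache$X, dY)
  db <- colSums(dY)
  dcol <- dY %*% t(W)
  Cin <- cache$Cin
  dxp <- matrix(0, tn$n * ci$hp * ci$wp, Cin)
  for (o in seq_len(ci$k2)) {
    colsO <- seq.int(o, by = ci$k2, length.out = Cin)
    ix <- ci$idx[, o]
    dxp[ix, ] <- dxp[ix, ] + dcol[, colsO, drop = FALSE]
  }
  list(dx = dxp[ci$pidx, , drop = FALSE], dW = dW, db = db)
}

bnForward <- function(x, gamma, beta, rmean, rvar, training,
                      momentum = 0.1, eps = 1e-5) {
  m <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu * mu
    v <- pmax(v, 0)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean
    v <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (x - rep(mu, each = m)) * rep(invstd, each = m)
  y <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  list(y = y, xhat = xhat, invstd = invstd, rmean = rmean, rvar = rvar)
}

bnBackward <- function(dY, cache, gamma, training) {
  m <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = m)
  if (training) {
    t1 <- colSums(dxhat)
    t2 <- colSums(dxhat * cache$xhat)
    dx <- (dxhat - rep(t1 / m, each = m) -
             cache$xhat * rep(t2 / m, each = m)) * rep(cache$invstd, each = m)
  } else {
    dx <- dxhat * rep(cache$invstd, each = m)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

poolIdx <- function(n, h, w) {
  key <- paste("p", n, h, w, sep = "_")
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  h2 <- h %/% 2L
  w2 <- w %/% 2L
  i <- rep(seq_len(h2), each = w2)
  j <- rep(seq_len(w2), times = h2)
  off <- rep((seq_len(n) - 1L) * h * w, each = h2 * w2)
  mk <- function(di, dj) rep((2L * i + di - 3L) * w + (2L * j + dj - 2L), times = n) + off
  res <- list(h2 = h2, w2 = w2, ix = list(mk(1L, 1L), mk(1L, 2L), mk(2L, 1L), mk(2L, 2L)))
  assign(key, res, envir = .idxCache)
  res
}

maxPoolForward <- function(tn) {
  pi <- poolIdx(tn$n, tn$h, tn$w)
  cur <- tn$x[pi$ix[[1]], , drop = FALSE]
  winner <- matrix(1L, nrow(cur), ncol(cur))
  for (kq in 2:4) {
    cand <- tn$x[pi$ix[[kq]], , drop = FALSE]
    upd <- cand > cur
    cur[upd] <- cand[upd]
    winner[upd] <- kq
  }
  list(out = nnTensor(cur, tn$n, pi$h2, pi$w2), winner = winner, pi = pi)
}

maxPoolBackward <- function(dY, cache, tn) {
  dx <- matrix(0, nrow(tn$x), ncol(tn$x))
  for (kq in 1:4) {
    sel <- cache$winner == kq
    if (!any(sel)) next
    sub <- dx[cache$pi$ix[[kq]], , drop = FALSE]
    sub[sel] <- sub[sel] + dY[sel]
    dx[cache$pi$ix[[kq]], ] <- sub
  }
  dx
}

adaptBins <- function(h, w, k) {
  key <- paste("a", h, w, k, sep = "_")
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  rowBin <- function(i, len) (floor((i - 1) * len / k) + 1L):ceiling(i * len / k)
  bins <- vector("list", k * k)
  for (bi in seq_len(k)) {
    ri <- rowBin(bi, h)
    for (bj in seq_len(k)) {
      cj <- rowBin(bj, w)
      grid <- expand.grid(j = cj, i = ri)
      bins[[(bi - 1L) * k + bj]] <- as.integer((grid$i - 1L) * w + grid$j)
    }
  }
  assign(key, bins, envir = .idxCache)
  bins
}

adaptPoolForward <- function(tn, k) {
  bins <- adaptBins(tn$h, tn$w, k)
  n <- tn$n
  k2 <- k * k
  out <- matrix(0, n * k2, ncol(tn$x))
  for (b in seq_len(k2)) {
    mem <- bins[[b]]
    allm <- rep(mem, times = n) + rep((seq_len(n) - 1L) * tn$h * tn$w, each = length(mem))
    grp <- rep(seq_len(n), each = length(mem))
    out[(seq_len(n) - 1L) * k2 + b, ] <-
      rowsum(tn$x[allm, , drop = FALSE], grp, reorder = FALSE) / length(mem)
  }
  list(out = nnTensor(out, n, k, k), bins = bins)
}

adaptPoolBackward <- function(dY, cache, tn, k) {
  n <- tn$n
  k2 <- k * k
  dx <- matrix(0, nrow(tn$x), ncol(tn$x))
  for (b in seq_len(k2)) {
    mem <- cache$bins[[b]]
    allm <- rep(mem, times = n) + rep((seq_len(n) - 1L) * tn$h * tn$w, each = length(mem))
    rows <- (seq_len(n) - 1L) * k2 + b
    dx[allm, ] <- dx[allm, ] +
      dY[rep(rows, each = length(mem)), , drop = FALSE] / length(mem)
  }
  dx
}

# (n*k2) x C pooled rows -> n x (k2*C) feature matrix, feature (c-1)*k2+pos
flattenForward <- function(tn) {
  k2 <- tn$h * tn$w
  C <- ncol(tn$x)
  a <- array(tn$x, dim = c(k2, tn$n, C))
  t(matrix(aperm(a, c(1, 3, 2)), k2 * C, tn$n))
}

flattenBackward <- function(dFlat, n, k2, C) {
  a <- array(t(dFlat), dim = c(k2, C, n))
  matrix(aperm(a, c(1, 3, 2)), n * k2, C)
}

denseForward <- function(x, W, b) x %*% W + rep(b, each = nrow(x))

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# inverted dropout; draws length(x) uniforms from the current RNG stream
dropoutMask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}
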