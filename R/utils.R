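#' @importFrom methods new validObject is slot
#' @importFrom stats runif rnorm qnorm optimize sd cor
#' @importFrom utils read.csv write.csv head
NULL

# Deterministic child seed derivation. Keeps every derived seed a valid
# 32-bit integer so set.seed() never overflows.
childSeed <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 16807) %% 2147483629)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

isProbVector <- function(p, tol = 1e-6) {
  is.numeric(p) && length(p) >= 2 && all(p >= -tol) && abs(sum(p) - 1) <= tol
}

stopIf <- function(cond, msg, class) {
  if (cond) stop(errorCondition(msg, class = c(class, "cascadectError")))
}

# min-max normalization with the all-zeros convention for constant maps
minMaxNormalize <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) {
    m[] <- 0
    return(m)
  }
  (m - rng[1]) / (rng[2] - rng[1])
}
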