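#' Phantom generation parameters
#'
#' @param imageSize pixels per side of the square phantom.
#' @param lesionContrast intensity decrement of the hypodense lesion; either
#'   a single value or an increasing length-2 band to sample from uniformly,
#'   each in \[0.02, 0.3\].
#' @param lesionRadiusFrac lesion radius as a fraction of the brain radius,
#'   in (0, 0.5\].
#' @param noiseSigma additive Gaussian noise standard deviation, \[0, 0.1\].
#' @param textureScale Gaussian smoothing length (pixels) of the parenchymal
#'   texture field.
#' @param seed integer seed; same parameters and seed give bit-identical
#'   phantoms.
#' @return a [PhantomParams-class] object.
#' @examples
#' p <- phantomParams(imageSize = 64, lesionContrast = 0.2, seed = 7)
#' img <- generatePhantom(p, "stroke")
#' range(pixels(img))
#' @export
phantomParams <- function(imageSize = 224, lesionContrast = 0.2,
                          lesionRadiusFrac = 0.25, noiseSigma = 0.02,
                          textureScale = 3, seed = 1L) {
  obj <- try(new("PhantomParams",
                 imageSize = as.integer(imageSize),
                 lesionContrast = as.numeric(lesionContrast),
                 lesionRadiusFrac = as.numeric(lesionRadiusFrac),
                 noiseSigma = as.numeric(noiseSigma),
                 textureScale = as.numeric(textureScale),
                 seed = as.integer(seed)), silent = TRUE)
  stopIf(inherits(obj, "try-error"),
         sprintf("invalid phantom parameters: %s", attr(obj, "condition")$message),
         "parameterError")
  obj
}

#' Generate one synthetic head phantom
#'
#' The phantom emulates a normalized axial CT slice: a bright skull annulus
#' (intensity 0.95 before noise), textured parenchyma around intensity 0.5
#' (Gaussian-blurred noise field), a dark background, and -- for the stroke
#' class -- a single connected smooth-edged hypodense blob fully inside the
#' brain. Within the binary ground-truth mask the intensity decrement equals
#' `lesionContrast` exactly (the cosine edge taper lies outside the mask), so
#' a matched normal phantom generated with the same seed differs from the
#' stroke phantom only by the lesion. Pixels are clipped to \[0, 1\].
#'
#' @param params a [PhantomParams-class].
#' @param label `"stroke"` or `"normal"`.
#' @param sourceId optional identifier; defaults to label plus seed.
#' @return a [LabeledImage-class] with ground-truth lesion mask (all zero
#'   for normal phantoms).
#' @export
generatePhantom <- function(params, label = c("stroke", "normal"),
                            sourceId = NULL) {
  stopIf(!methods::is(params, "PhantomParams"), "params must be PhantomParams",
         "parameterError")
  methods::validObject(params)
  label <- match.arg(label)
  S <- params@imageSize
  ctr <- (S + 1) / 2
  Rs <- 0.47 * S      # skull outer radius
  Rb <- 0.40 * S      # brain (parenchyma) radius
  xs <- matrix(rep(seq_len(S), each = S), S, S)    # column index
  ys <- matrix(rep(seq_len(S), times = S), S, S)   # row index
  d <- sqrt((xs - ctr)^2 + (ys - ctr)^2)
  brain <- d <= Rb
  skull <- d > Rb & d <= Rs

  img <- matrix(0.02, S, S)
  img[skull] <- 0.95
  img[brain] <- 0.5

  set.seed(params@seed)
  # parenchymal texture: blurred white noise, rescaled to a fixed amplitude
  field <- matrix(rnorm(S * S), S, S)
  field <- matrix(EBImage::imageData(EBImage::gblur(field, sigma = params@textureScale)), S, S)
  field <- (field - mean(field)) / max(sd(field), 1e-12) * 0.035
  img[brain] <- img[brain] + field[brain]

  # lesion geometry is drawn for both labels so that matched stroke/normal
  # pairs with the same seed share every other pixel
  r <- params@lesionRadiusFrac * Rb
  taper <- max(1.5, 0.25 * r)
  maxOff <- max(Rb - r - taper, 0)
  ang <- runif(1, 0, 2 * pi)
  rho <- sqrt(runif(1)) * maxOff
  lx <- ctr + rho * cos(ang)
  ly <- ctr + rho * sin(ang)
  contrast <- if (length(params@lesionContrast) == 2L) {
    runif(1, params@lesionContrast[1], params@lesionContrast[2])
  } else {
    params@lesionContrast
  }

  mask <- matrix(0, S, S)
  if (label == "stroke") {
    dd <- sqrt((xs - lx)^2 + (ys - ly)^2)
    prof <- matrix(0, S, S)
    prof[dd <= r] <- 1
    edge <- dd > r & dd < r + taper
    prof[edge] <- 0.5 * (1 + cos(pi * (dd[edge] - r) / taper))
    img <- img - contrast * prof
    mask[dd <= r] <- 1
  }
  if (params@noiseSigma > 0) {
    img <- img + matrix(rnorm(S * S, 0, params@noiseSigma), S, S)
  }
  img <- clamp01(img)
  if (is.null(sourceId)) sourceId <- sprintf("%s_seed%d", label, params@seed)
  new("LabeledImage", pixels = img, label = label, lesionMask = mask,
      sourceId = sourceId)
}

#' Default mixed-difficulty phantom conditions
#'
#' 60% easy cases (lesion contrast sampled in 0.15-0.25) and 40% hard cases
#' (contrast 0.03-0.08), so that both confident and genuinely ambiguous
#' predictions occur and the rejection/flip stages have work to do.
#'
#' @param imageSize pixels per side for every component.
#' @param noiseSigma noise level shared by the components.
#' @return list of components, each `list(params = PhantomParams, weight)`.
#' @export
defaultDifficultyMix <- function(imageSize = 224, noiseSigma = 0.02) {
  list(
    easy = list(params = phantomParams(imageSize = imageSize,
                                       lesionContrast = c(0.15, 0.25),
                                       noiseSigma = noiseSigma),
                weight = 0.6),
    hard = list(params = phantomParams(imageSize = imageSize,
                                       lesionContrast = c(0.03, 0.08),
                                       noiseSigma = noiseSigma),
                weight = 0.4)
  )
}

roundCounts <- function(n, fractions) {
  counts <- round(n * fractions)
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  counts
}

#' Generate a labelled phantom dataset with train/validation/test splits
#'
#' @param n number of images (>= 4).
#' @param strokeFraction proportion of stroke images; the stroke count is
#'   `round(n * strokeFraction)`.
#' @param difficultyMix list of components `list(params, weight)` (see
#'   [defaultDifficultyMix()]); one component is drawn per image by weight.
#' @param splitFractions named or ordered numeric triple (train, validation,
#'   test) summing to 1.
#' @param seed master seed; image seeds are derived per index, so the whole
#'   dataset is reproducible.
#' @return a [PhantomDataset-class].
#' @export
generateDataset <- function(n, strokeFraction = 0.5,
                            difficultyMix = defaultDifficultyMix(),
                            splitFractions = c(train = 0.7, validation = 0.15,
                                               test = 0.15),
                            seed = 1L) {
  stopIf(n < 4, "n must be at least 4", "sizingError")
  stopIf(abs(sum(splitFractions) - 1) > 1e-8 || any(splitFractions <= 0),
         "split fractions must be positive and sum to 1", "sizingError")
  nStroke <- round(n * strokeFraction)
  splitN <- roundCounts(n, splitFractions)
  stopIf(any(splitN < 1), "n too small to populate every split", "sizingError")

  set.seed(seed)
  labels <- sample(c(rep("stroke", nStroke), rep("normal", n - nStroke)))
  splits <- sample(rep(c("train", "validation", "test"), times = splitN))
  weights <- vapply(difficultyMix, function(cp) cp$weight, numeric(1))
  comp <- sample.int(length(difficultyMix), n, replace = TRUE,
                     prob = weights / sum(weights))

  imgs <- vector("list", n)
  ids <- sprintf("img%04d", seq_len(n))
  for (i in seq_len(n)) {
    base <- difficultyMix[[comp[i]]]$params
    p <- new("PhantomParams", imageSize = base@imageSize,
             lesionContrast = base@lesionContrast,
             lesionRadiusFrac = base@lesionRadiusFrac,
             noiseSigma = base@noiseSigma, textureScale = base@textureScale,
             seed = childSeed(seed, i))
    imgs[[i]] <- generatePhantom(p, labels[i], sourceId = ids[i])
  }
  names(imgs) <- ids
  man <- data.frame(source_id = ids,
                    path = sprintf("images/%s.png", ids),
                    label = labels, split = splits,
                    stringsAsFactors = FALSE)
  new("PhantomDataset", manifest = man, images = imgs,
      params = list(n = n, strokeFraction = strokeFraction,
                    splitFractions = as.list(splitFractions),
                    components = lapply(difficultyMix, function(cp) {
                      list(weight = cp$weight,
                           imageSize = cp$params@imageSize,
                           lesionContrast = cp$params@lesionContrast,
                           lesionRadiusFrac = cp$params@lesionRadiusFrac,
                           noiseSigma = cp$params@noiseSigma,
                           textureScale = cp$params@textureScale)
                    })),
      seed = as.integer(seed))
}
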