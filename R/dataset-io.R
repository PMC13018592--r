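#' Persist a phantom dataset to disk
#'
#' Writes lossless 8-bit grayscale PNGs (`pixel = round(value * 255)`) under
#' `images/`, binary lesion masks under `masks/`, the split manifest as CSV
#' (`source_id,path,label,split`), a JSON sidecar of generation parameters,
#' and an exact double-precision array bundle (`pixels.rds`) so that
#' bit-exact round trips are possible alongside the codec-quantized PNGs.
#'
#' @param dataset a [PhantomDataset-class].
#' @param directory output directory (created if missing).
#' @return the directory, invisibly.
#' @export
persistDataset <- function(dataset, directory) {
  methods::validObject(dataset)
  dir.create(file.path(directory, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(directory, "masks"), showWarnings = FALSE)
  m <- dataset@manifest
  for (i in seq_len(nrow(m))) {
    im <- dataset@images[[m$source_id[i]]]
    png::writePNG(round(im@pixels * 255) / 255, file.path(directory, m$path[i]))
    png::writePNG(im@lesionMask,
                  file.path(directory, "masks", basename(m$path[i])))
  }
  write.csv(m, file.path(directory, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(c(dataset@params, list(seed = dataset@seed)),
                       file.path(directory, "params.json"), auto_unbox = TRUE,
                       digits = NA)
  exact <- lapply(dataset@images, function(im) {
    list(pixels = im@pixels, mask = im@lesionMask, label = im@label)
  })
  saveRDS(exact, file.path(directory, "pixels.rds"))
  invisible(directory)
}

#' Load a persisted phantom dataset
#'
#' Restores the manifest, parameters, images and masks. When the exact array
#' bundle (`pixels.rds`) is present it is used (bit-exact round trip);
#' otherwise images are decoded from the PNGs (exact to 8-bit codec
#' precision). A missing manifest raises a not-found error; a manifest row
#' whose image file is absent raises an integrity error.
#'
#' @param directory dataset directory written by [persistDataset()].
#' @return a [PhantomDataset-class].
#' @export
loadDataset <- function(directory) {
  manPath <- file.path(directory, "manifest.csv")
  stopIf(!file.exists(manPath),
         sprintf("manifest not found in %s", directory), "notFoundError")
  m <- read.csv(manPath, stringsAsFactors = FALSE)
  missing <- !file.exists(file.path(directory, m$path))
  stopIf(any(missing),
         sprintf("manifest/file mismatch: %d image file(s) missing (e.g. %s)",
                 sum(missing), m$path[which(missing)[1]]),
         "integrityError")
  params <- if (file.exists(file.path(directory, "params.json"))) {
    jsonlite::read_json(file.path(directory, "params.json"), simplifyVector = TRUE)
  } else {
    list()
  }
  seed <- if (!is.null(params$seed)) as.integer(params$seed) else NA_integer_
  exactPath <- file.path(directory, "pixels.rds")
  exact <- if (file.exists(exactPath)) readRDS(exactPath) else NULL
  imgs <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    id <- m$source_id[i]
    if (!is.null(exact) && !is.null(exact[[id]])) {
      e <- exact[[id]]
      imgs[[i]] <- new("LabeledImage", pixels = e$pixels, label = e$label,
                       lesionMask = e$mask, sourceId = id)
    } else {
      px <- png::readPNG(file.path(directory, m$path[i]))
      if (length(dim(px)) == 3L) px <- px[, , 1L]
      maskPath <- file.path(directory, "masks", basename(m$path[i]))
      mk <- if (file.exists(maskPath)) {
        mp <- png::readPNG(maskPath)
        if (length(dim(mp)) == 3L) mp <- mp[, , 1L]
        (mp > 0.5) * 1
      } else {
        matrix(0, nrow(px), ncol(px))
      }
      imgs[[i]] <- new("LabeledImage", pixels = px, label = m$label[i],
                       lesionMask = mk, sourceId = id)
    }
  }
  names(imgs) <- m$source_id
  params$seed <- NULL
  new("PhantomDataset", manifest = m, images = imgs, params = params,
      seed = if (is.na(seed)) 0L else seed)
}
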