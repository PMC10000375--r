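#' @include metrics.R
NULL

#' Default pipeline configuration
#'
#' Nested list mirroring the YAML config layout, one section per stage.
#' The `profile = "desk"` defaults run the whole pipeline on a single CPU
#' in minutes (64 x 64 images, width-scale 0.125, 15 epochs); the `"full"`
#' profile holds the native configuration (224 x 224 inputs, full-width
#' architecture, 235 epochs, batch 32).
#'
#' @param profile `"desk"` or `"full"`.
#' @return nested configuration list.
#' @export
defaultConfig <- function(profile = c("desk", "full")) {
  profile <- match.arg(profile)
  desk <- profile == "desk"
  list(
    simulate = list(nPerClass = if (desk) 30L else 200L,
                    height = if (desk) 64L else 224L,
                    width = if (desk) 64L else 224L,
                    noiseDensity = 0, illuminationStrength = 0, blurSigma = 0,
                    baseSeed = 0L),
    preprocess = list(
      denoise = list(enabled = TRUE, window = 5L, thresholdK = 6),
      diffusion = list(enabled = TRUE, iters = 10L, dt = 0.2, kappa = 0.1),
      enhance = list(enabled = TRUE, PS = 15L, Tm = 50L, seed = 0L)),
    hho = list(PS = 20L, Tm = 200L, seed = 0L),
    segment = list(MinPts = 5L, eps = 0.08, extractionThreshold = 0.06,
                   maxSamples = 3000L, vesselnessThreshold = 0.08),
    features = list(darkPercentile = 0.1, darkAbs = 0.1,
                    brightPercentile = 0.97, brightAbs = 0.72,
                    maSizeGate = 30),
    ensemble = list(L = 3L, rFraction = 0.8,
                    scale = if (desk) 0.125 else 1,
                    epochs = if (desk) 15L else 235L, batchSize = 32L,
                    lr = 1e-3, weighting = "uniform",
                    augmentation = list(rotation = 0, widthShift = 0,
                                        heightShift = 0, shear = 0,
                                        zoom = 0, hflip = FALSE)),
    severity = list(sigma = 1),
    io = list(outDir = "retinopipe-out"),
    seed = 0L)
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML configuration, merged over the defaults
#' @param path YAML file path (or `NULL` for pure defaults).
#' @param profile base profile passed to [defaultConfig()].
#' @return nested configuration list.
#' @export
readConfig <- function(path = NULL, profile = "desk") {
  cfg <- defaultConfig(profile)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- mergeConfig(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Load a labeled image dataset from disk
#'
#' Reads the CSV manifest written by [generateDataset()] (columns
#' `filename,class_label,severity,ma_count,he_count,ex_count,seed`) and the
#' referenced PNG images.  Unreadable or missing images are skipped with a
#' warning and counted; a folder-per-class layout (subdirectories named by
#' class, no manifest) is also supported.
#'
#' @param dir dataset directory.
#' @param manifest manifest filename within `dir`.
#' @return list with `records` (data.frame), `images` (list of RGB arrays),
#'   `skipped` (count).
#' @export
loadDataset <- function(dir, manifest = "manifest.csv") {
  mpath <- file.path(dir, manifest)
  if (file.exists(mpath)) {
    rec <- read.csv(mpath, stringsAsFactors = FALSE)
  } else {
    classes <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
    if (!length(classes)) stop("missing manifest and no class folders: ", mpath)
    rec <- do.call(rbind, lapply(classes, function(cl) {
      fn <- list.files(file.path(dir, cl), pattern = "\\.png$")
      if (!length(fn)) return(NULL)
      data.frame(filename = file.path(cl, fn), class_label = cl,
                 severity = NA, ma_count = NA, he_count = NA, ex_count = NA,
                 seed = NA, stringsAsFactors = FALSE)
    }))
  }
  images <- vector("list", nrow(rec))
  ok <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    f <- file.path(dir, rec$filename[i])
    img <- tryCatch(png::readPNG(f), error = function(e) NULL)
    if (is.null(img)) {
      warning("skipping unreadable image: ", rec$filename[i])
      next
    }
    if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
    images[[i]] <- img
    ok[i] <- TRUE
  }
  list(records = rec[ok, , drop = FALSE], images = images[ok],
       skipped = sum(!ok))
}

#' Write feature vectors as a schema-versioned CSV
#' @param feats matrix (rows = images) whose columns follow
#'   [featureSchema()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeFeatureCSV <- function(feats, path) {
  df <- as.data.frame(feats)
  attr(df, "schema") <- "retinopipe-features-v1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# schema: retinopipe-features-v1", con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
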