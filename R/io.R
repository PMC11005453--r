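# Image/mask I/O, run configuration (YAML), and heatmap export.
#
# Conventions: 0-based pixel reasoning with (row, col) order and origin at
# the top-left; masks are 255 = foreground on disk, 1 = foreground in
# memory; images are scaled to [0, 1] on read.

#' Read a grayscale image
#'
#' PNG or TIFF, scaled to \[0, 1\]. Multi-channel inputs are converted to
#' luminance (0.299 R + 0.587 G + 0.114 B) with a warning.
#'
#' @param path File path (.png, .tif, .tiff).
#' @return Numeric matrix in \[0, 1\].
#' @export
readImageGray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s' (PNG/TIFF expected): %s",
                 ext, path), call. = FALSE))
  if (length(dim(img)) == 3L) {
    warning(sprintf("multi-channel image converted to luminance: %s", path))
    ch <- dim(img)[3]
    img <- if (ch >= 3) 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
           else img[, , 1]
  }
  img
}

#' Write a grayscale image / a binary mask
#'
#' Images are stored as 8-bit grayscale PNG; masks as 0/255 PNG. An
#' 8-bit write/read round trip of a 0/1 mask is lossless.
#'
#' @param img Matrix in \[0, 1\].
#' @param mask Binary 0/1 matrix.
#' @param path Output path (.png).
#' @return Invisibly, the path.
#' @export
writeImageGray <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname writeImageGray
#' @export
writeMask <- function(mask, path) {
  stopShape(all(mask %in% c(0, 1)), "mask must be binary 0/1")
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Export a probability map as a cold-to-warm heatmap
#'
#' Probabilities map monotonically from cold (dark blue) through cyan and
#' yellow to warm (red), the usual reading of segmentation confidence
#' heatmaps. Values outside \[0, 1\] are clipped with a warning.
#'
#' @param prob Numeric matrix of probabilities.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
exportHeatmap <- function(prob, path) {
  if (any(prob < 0 | prob > 1)) {
    warning("probabilities outside [0, 1] clipped for heatmap export")
    prob <- pmin(pmax(prob, 0), 1)
  }
  ramp <- grDevices::colorRamp(c("#0000FF", "#00FFFF", "#FFFF00", "#FF0000"))
  rgb <- ramp(as.vector(prob)) / 255
  arr <- array(rgb, dim = c(dim(prob), 3L))
  png::writePNG(arr, path)
  invisible(path)
}

## ---- run configuration ----

#' Default run configuration
#'
#' The full nested configuration (model, training, data) with every field
#' at its default; the schema against which files are validated.
#' @return Nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    model = list(depth = 5L, widths = c(32L, 64L, 128L, 256L, 512L),
                 tokenWidths = c(484L, 484L, 484L, 256L), tokenGrid = 22L,
                 encodingStrategy = "concatenation", useGnconv = TRUE,
                 useTransformer = TRUE, gnN = 3L, padPolicy = "pad",
                 ffnHidden = 2048L, dropout = 0.1, alpha = 0.3,
                 heads = 1L, normMode = "pre"),
    train = list(steps = 1000L, batchSize = 2L, lr = 0.01, momentum = 0.99,
                 clipNorm = 12, seed = 1L, folds = 5L, valFraction = 0.2,
                 evalEvery = 50L,
                 augment = list(rotate = TRUE, contrast = TRUE, noise = TRUE,
                                translate = TRUE, flip = TRUE)),
    data = list(size = 384L, n = 40L, mix = c(24L, 10L, 6L), seed = 7L))
}

.validateKeys <- function(x, ref, path = "") {
  for (nm in names(x)) {
    if (!nm %in% names(ref))
      stop(sprintf("unknown configuration key '%s%s'", path, nm),
           call. = FALSE)
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(x[[nm]]))
      .validateKeys(x[[nm]], ref[[nm]], paste0(path, nm, "."))
  }
  invisible(TRUE)
}

.mergeConfig <- function(defaults, override) {
  for (nm in names(override)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(override[[nm]]))
      .mergeConfig(defaults[[nm]], override[[nm]]) else override[[nm]]
  }
  defaults
}

#' Read / write a run configuration (YAML)
#'
#' Unknown keys are rejected; missing keys take their defaults, so the
#' resolved configuration always carries every field and round-trips
#' through serialisation unchanged.
#'
#' @param path YAML file path.
#' @param cfg Nested configuration list.
#' @return `readRunConfig` returns the resolved nested list.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- defaultRunConfig()
  .validateKeys(raw, defaults)
  .mergeConfig(defaults, raw)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build typed configurations from a run configuration
#' @param cfg Nested list as returned by [readRunConfig()].
#' @return A [BackboneConfig-class] / [TrainConfig-class].
#' @export
runModelConfig <- function(cfg) do.call(backboneConfig, cfg$model)

#' @rdname runModelConfig
#' @export
runTrainConfig <- function(cfg) {
  tc <- cfg$train
  tc$augment <- unlist(tc$augment)
  do.call(trainConfig, tc)
}
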