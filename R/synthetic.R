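# Seeded generator of corneal-stromal-cell-like scenes: bright elongated
# elliptical cell bodies on a dark, unevenly illuminated background, in
# three imaging regimes — clear, vessel-occluded (dark curvilinear
# streaks crossing the field) and blurred (defocus plus contrast loss).
# Masks always record the analytic cell extent before any corruption.

#' Scene configuration for the synthetic generator
#'
#' @slot imageSize Canvas side in pixels.
#' @slot nCells Number of cells to place (non-overlapping).
#' @slot axisRange Major semi-axis range in pixels.
#' @slot minorFrac Minor/major axis ratio range (elongation).
#' @slot cellIntensity Peak cell intensity range.
#' @slot bgIntensity Background base intensity range.
#' @slot illumAmp Illumination-gradient amplitude.
#' @slot noiseSd Additive Gaussian noise sd.
#' @slot regime "clear", "occluded" or "blurred".
#' @slot nVessels,vesselWidth Vessel count and width (occluded regime).
#' @slot blurSigma Gaussian blur sigma (blurred regime).
#' @slot contrastFactor Contrast retained in the blurred regime.
#' @slot seed Integer seed; fully determines the scene.
#' @export
setClass("SceneConfig", representation(
  imageSize = "integer", nCells = "integer", axisRange = "numeric",
  minorFrac = "numeric", cellIntensity = "numeric", bgIntensity = "numeric",
  illumAmp = "numeric", noiseSd = "numeric", regime = "character",
  nVessels = "integer", vesselWidth = "numeric", blurSigma = "numeric",
  contrastFactor = "numeric", seed = "integer"))

setValidity("SceneConfig", function(object) {
  msgs <- character()
  if (!object@regime %in% c("clear", "occluded", "blurred"))
    msgs <- c(msgs, "regime must be clear, occluded or blurred")
  if (2 * max(object@axisRange) + 2 >= object@imageSize)
    msgs <- c(msgs, "cells do not fit inside the canvas")
  if (length(msgs)) msgs else TRUE
})

#' Construct a scene configuration
#'
#' Defaults emulate a 384 x 384 confocal field with 40 elongated bright
#' keratocyte-like bodies; cell density scales with canvas area when
#' `nCells` is omitted.
#'
#' @param imageSize Canvas side (default 384).
#' @param nCells Cell count (default scales as `40 * (imageSize/384)^2`).
#' @param axisRange,minorFrac,cellIntensity,bgIntensity,illumAmp,noiseSd
#'   See [SceneConfig-class].
#' @param regime Imaging regime.
#' @param nVessels,vesselWidth,blurSigma,contrastFactor Regime settings.
#' @param seed Integer seed.
#' @return A [SceneConfig-class].
#' @export
sceneConfig <- function(imageSize = 384L,
                        nCells = max(1L, round(40 * (imageSize / 384)^2)),
                        axisRange = c(8, 16) * imageSize / 384,
                        minorFrac = c(0.35, 0.6),
                        cellIntensity = c(0.55, 0.9),
                        bgIntensity = c(0.08, 0.16), illumAmp = 0.12,
                        noiseSd = 0.03,
                        regime = c("clear", "occluded", "blurred"),
                        nVessels = 3L, vesselWidth = 5 * imageSize / 384,
                        blurSigma = 2.5 * imageSize / 384,
                        contrastFactor = 0.45, seed = 1L) {
  axisRange <- pmax(axisRange, 2)
  new("SceneConfig", imageSize = as.integer(imageSize),
      nCells = as.integer(nCells), axisRange = axisRange,
      minorFrac = minorFrac, cellIntensity = cellIntensity,
      bgIntensity = bgIntensity, illumAmp = illumAmp, noiseSd = noiseSd,
      regime = match.arg(regime), nVessels = as.integer(nVessels),
      vesselWidth = max(1, vesselWidth), blurSigma = max(0.5, blurSigma),
      contrastFactor = contrastFactor, seed = as.integer(seed))
}

# Elliptical squared radius of pixel offsets (dr, dc) for axes (a, b)
# rotated by phi.
.ellipseR2 <- function(dr, dc, a, b, phi) {
  u <- dr * cos(phi) + dc * sin(phi)
  v <- -dr * sin(phi) + dc * cos(phi)
  (u / a)^2 + (v / b)^2
}

.drawVessel <- function(S, width) {
  # Random walk across the field, dilated to the configured width.
  pts <- matrix(0, 0, 2)
  edge <- sample.int(4L, 1L)
  pos <- switch(edge,
    c(1, stats::runif(1, 1, S)), c(S, stats::runif(1, 1, S)),
    c(stats::runif(1, 1, S), 1), c(stats::runif(1, 1, S), S))
  ang <- switch(edge, 0, pi, pi / 2, -pi / 2) + stats::rnorm(1, 0, 0.3)
  repeat {
    pts <- rbind(pts, pos)
    ang <- ang + stats::rnorm(1, 0, 0.18)
    pos <- pos + c(cos(ang), sin(ang))
    if (pos[1] < 1 || pos[1] > S || pos[2] < 1 || pos[2] > S) break
    if (nrow(pts) > 4 * S) break
  }
  m <- matrix(0, S, S)
  m[cbind(pmin(pmax(round(pts[, 1]), 1), S),
          pmin(pmax(round(pts[, 2]), 1), S))] <- 1
  brush <- EBImage::makeBrush(2L * floor(width / 2) + 1L, shape = "disc")
  matrix(EBImage::imageData(EBImage::dilate(m, brush)), S, S)
}

#' Generate one synthetic scene
#'
#' Places `nCells` rotated ellipses with edge-ward intensity falloff on a
#' noisy, illumination-graded background. The mask is the union of the
#' analytic ellipse extents and is never corrupted; the occluded regime
#' overlays dark vessel streaks and the blurred regime applies Gaussian
#' blur and contrast loss to the image only.
#'
#' @param cfg A [SceneConfig-class].
#' @return A [segmentationSample()] with the regime as tag.
#' @export
generateScene <- function(cfg) {
  methods::validObject(cfg)
  withSeed(cfg@seed, {
    S <- cfg@imageSize
    rc <- matrix(rep(seq_len(S), S), S, S)         # row coordinate
    cc <- t(rc)
    theta <- stats::runif(1, 0, 2 * pi)
    base <- stats::runif(1, cfg@bgIntensity[1], cfg@bgIntensity[2])
    ramp <- (cos(theta) * (rc - S / 2) + sin(theta) * (cc - S / 2)) / S
    img <- base + cfg@illumAmp * ramp
    mask <- matrix(0, S, S)
    placed <- 0L; tries <- 0L
    maxTries <- 60L * max(1L, cfg@nCells)
    while (placed < cfg@nCells) {
      tries <- tries + 1L
      if (tries > maxTries)
        stop(sprintf(
          "could not place %d cells of size %.0f-%.0f px on a %d px canvas",
          cfg@nCells, cfg@axisRange[1], cfg@axisRange[2], S), call. = FALSE)
      a <- stats::runif(1, cfg@axisRange[1], cfg@axisRange[2])
      b <- a * stats::runif(1, cfg@minorFrac[1], cfg@minorFrac[2])
      phi <- stats::runif(1, 0, pi)
      m <- ceiling(a) + 1
      ctr <- stats::runif(2, 1 + m, S - m)
      lo <- pmax(floor(ctr - a), 1); hi <- pmin(ceiling(ctr + a), S)
      rs <- lo[1]:hi[1]; cs <- lo[2]:hi[2]
      r2 <- .ellipseR2(outer(rs - ctr[1], rep(1, length(cs))),
                       outer(rep(1, length(rs)), cs - ctr[2]), a, b, phi)
      inside <- r2 <= 1
      if (!any(inside)) next
      if (any(mask[rs, cs][inside] == 1)) next
      sub <- mask[rs, cs]; sub[inside] <- 1; mask[rs, cs] <- sub
      peak <- stats::runif(1, cfg@cellIntensity[1], cfg@cellIntensity[2])
      cell <- peak * (1 - 0.45 * r2)
      imgSub <- img[rs, cs]
      img[rs, cs] <- ifelse(inside, pmax(imgSub, cell), imgSub)
      placed <- placed + 1L
    }
    img <- img + stats::rnorm(S * S, 0, cfg@noiseSd)
    if (cfg@regime == "occluded" && cfg@nVessels > 0L) {
      vm <- matrix(0, S, S)
      for (v in seq_len(cfg@nVessels))
        vm <- pmax(vm, .drawVessel(S, cfg@vesselWidth))
      vs <- matrix(EBImage::imageData(EBImage::gblur(vm, sigma = max(0.8, cfg@vesselWidth / 4))), S, S)
      img <- img * (1 - 0.75 * pmin(vs, 1))
    }
    if (cfg@regime == "blurred") {
      img <- matrix(EBImage::imageData(EBImage::gblur(img, sigma = cfg@blurSigma)), S, S)
      mu <- mean(img)
      img <- mu + cfg@contrastFactor * (img - mu)
    }
    img <- matrix(pmin(pmax(img, 0), 1), S, S)
    segmentationSample(img, mask, cfg@regime)
  })
}

.defaultMix <- function(n) {
  # Largest-remainder apportionment of the 24:10:6 clear/occluded/blurred
  # test-field distribution.
  pr <- c(clear = 24, occluded = 10, blurred = 6) / 40
  base <- floor(pr * n)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(pr * n - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Generate a synthetic dataset
#'
#' Produces `n` scenes split across the three regimes (default mix
#' proportional to 24 clear : 10 occluded : 6 blurred per 40 fields),
#' optionally writing 8-bit grayscale PNG images, 0/255 PNG masks and a
#' CSV manifest with regime tags and per-scene seeds.
#'
#' @param n Number of images.
#' @param mix Named or positional counts (clear, occluded, blurred)
#'   summing to `n`.
#' @param size Canvas side.
#' @param seed Master seed; per-scene seeds are derived from it.
#' @param outDir Optional output directory.
#' @param ... Further arguments to [sceneConfig()] (e.g. `nCells`).
#' @return List with `samples` (list of [segmentationSample()]) and
#'   `manifest` (data.frame).
#' @export
generateDataset <- function(n, mix = .defaultMix(n), size = 384L, seed = 1L,
                            outDir = NULL, ...) {
  if (length(mix) != 3L || sum(mix) != n || any(mix < 0))
    stop(sprintf("regime mix (%s) must be three non-negative counts summing to %d",
                 paste(mix, collapse = ","), n), call. = FALSE)
  regimes <- rep(c("clear", "occluded", "blurred"), times = mix)
  seeds <- (as.numeric(seed) * 1009 + 7919 * seq_len(n)) %% 2147483647
  samples <- vector("list", n)
  manifest <- data.frame(id = seq_len(n),
                         image = sprintf("img_%03d.png", seq_len(n)),
                         mask = sprintf("mask_%03d.png", seq_len(n)),
                         regime = regimes, seed = as.integer(seeds))
  for (i in seq_len(n)) {
    cfg <- sceneConfig(imageSize = size, regime = regimes[i],
                       seed = as.integer(seeds[i]), ...)
    samples[[i]] <- generateScene(cfg)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      writeImageGray(samples[[i]]$image, file.path(outDir, manifest$image[i]))
      writeMask(samples[[i]]$mask, file.path(outDir, manifest$mask[i]))
    }
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}

#' Load a dataset written by [generateDataset()]
#' @param dir Directory containing `manifest.csv`, images and masks.
#' @return List of [segmentationSample()]s.
#' @export
loadDataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    segmentationSample(readImageGray(file.path(dir, manifest$image[i])),
                       readImageGray(file.path(dir, manifest$mask[i])),
                       manifest$regime[i])
  })
}
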