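# Training pipeline: paired augmentation, k-fold splitting, and an SGD
# loop with soft-Dice + cross-entropy loss following nnUNet conventions
# (momentum 0.99, polynomial learning-rate decay from 0.01, gradient-norm
# clipping at 12).

#' A segmentation sample
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param mask Binary matrix (0/1) of the same size.
#' @param tag Condition tag, e.g. "clear", "occluded", "blurred".
#' @return List with class `SegmentationSample`.
#' @export
segmentationSample <- function(image, mask, tag = "clear") {
  stopShape(all(dim(image) == dim(mask)), "image and mask sizes differ")
  stopShape(all(mask %in% c(0, 1)), "mask must be binary 0/1")
  structure(list(image = image, mask = mask, tag = tag),
            class = "SegmentationSample")
}

#' Training configuration
#'
#' @slot steps Number of optimisation steps.
#' @slot batchSize Samples per step.
#' @slot lr Initial learning rate (polynomial decay, power 0.9).
#' @slot momentum SGD momentum.
#' @slot clipNorm Global gradient-norm clip.
#' @slot seed Seed fixing every stochastic choice (splits, augmentation,
#'   initialisation, batching).
#' @slot folds Cross-validation folds k.
#' @slot valFraction Validation fraction of each training split.
#' @slot augment Named logical vector with entries rotate, contrast,
#'   noise, translate, flip.
#' @slot evalEvery Validation cadence in steps.
#' @export
setClass("TrainConfig", representation(
  steps = "integer", batchSize = "integer", lr = "numeric",
  momentum = "numeric", clipNorm = "numeric", seed = "integer",
  folds = "integer", valFraction = "numeric", augment = "logical",
  evalEvery = "integer"
))

setValidity("TrainConfig", function(object) {
  msgs <- character()
  if (object@folds < 2L) msgs <- c(msgs, "folds must be >= 2")
  if (object@valFraction <= 0 || object@valFraction >= 1)
    msgs <- c(msgs, "valFraction must lie in (0, 1)")
  need <- c("rotate", "contrast", "noise", "translate", "flip")
  if (!all(need %in% names(object@augment)))
    msgs <- c(msgs, "augment must name rotate, contrast, noise, translate, flip")
  if (length(msgs)) msgs else TRUE
})

#' Construct a training configuration
#' @param steps,batchSize,lr,momentum,clipNorm,seed,folds,valFraction,evalEvery
#'   See [TrainConfig-class]; defaults are 1000 steps, batch 2, lr 0.01,
#'   momentum 0.99, clip 12, 5 folds, 0.2 validation fraction.
#' @param augment Named logical vector of augmentation toggles (all on by
#'   default).
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(steps = 1000L, batchSize = 2L, lr = 0.01,
                        momentum = 0.99, clipNorm = 12, seed = 1L,
                        folds = 5L, valFraction = 0.2,
                        augment = c(rotate = TRUE, contrast = TRUE,
                                    noise = TRUE, translate = TRUE,
                                    flip = TRUE),
                        evalEvery = 50L) {
  new("TrainConfig", steps = as.integer(steps),
      batchSize = as.integer(batchSize), lr = lr, momentum = momentum,
      clipNorm = clipNorm, seed = as.integer(seed), folds = as.integer(folds),
      valFraction = valFraction, augment = augment,
      evalEvery = as.integer(evalEvery))
}

## ---- augmentation ----

.rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

.shiftMat <- function(m, dr, dc) {
  out <- matrix(0, nrow(m), ncol(m))
  srcR <- seq_len(nrow(m)) - dr; srcC <- seq_len(ncol(m)) - dc
  okR <- srcR >= 1 & srcR <= nrow(m); okC <- srcC >= 1 & srcC <= ncol(m)
  out[okR, okC] <- m[srcR[okR], srcC[okC]]
  out
}

#' Paired augmentation of image and mask
#'
#' Geometric transforms (quarter-turn rotation, flips, integer
#' translation) are applied identically to image and mask so the mask
#' stays binary and registered; photometric transforms (contrast scaling,
#' additive Gaussian noise) touch the image only. Draws come from the
#' current RNG state; each toggled transform is applied with
#' probability 1/2.
#'
#' @param sample A [segmentationSample()].
#' @param toggles Named logical vector (rotate, contrast, noise,
#'   translate, flip).
#' @return An augmented `SegmentationSample`.
#' @export
augmentSample <- function(sample, toggles = c(rotate = TRUE, contrast = TRUE,
                                              noise = TRUE, translate = TRUE,
                                              flip = TRUE)) {
  img <- sample$image; msk <- sample$mask
  if (isTRUE(toggles[["rotate"]]) && stats::runif(1) < 0.5) {
    k <- sample.int(3L, 1L)
    for (q in seq_len(k)) { img <- .rot90(img); msk <- .rot90(msk) }
  }
  if (isTRUE(toggles[["flip"]]) && stats::runif(1) < 0.5) {
    if (stats::runif(1) < 0.5) {
      img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
      msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
    } else {
      img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
      msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
    }
  }
  if (isTRUE(toggles[["translate"]]) && stats::runif(1) < 0.5) {
    mx <- max(1L, round(0.1 * nrow(img)))
    dr <- sample.int(2L * mx + 1L, 1L) - mx - 1L
    dc <- sample.int(2L * mx + 1L, 1L) - mx - 1L
    img <- .shiftMat(img, dr, dc); msk <- .shiftMat(msk, dr, dc)
  }
  if (isTRUE(toggles[["contrast"]]) && stats::runif(1) < 0.5) {
    f <- stats::runif(1, 0.7, 1.3)
    mu <- mean(img)
    img <- pmin(pmax(mu + f * (img - mu), 0), 1)
  }
  if (isTRUE(toggles[["noise"]]) && stats::runif(1) < 0.5) {
    img <- pmin(pmax(img + stats::rnorm(length(img), 0,
                                        stats::runif(1, 0.01, 0.04)), 0), 1)
    img <- matrix(img, nrow(msk), ncol(msk))
  }
  segmentationSample(img, msk, sample$tag)
}

## ---- splits ----

#' k-fold cross-validation split
#'
#' Partitions `1..nItems` into `k` disjoint validation folds covering all
#' indices; each fold's training set is the complement, giving the
#' 80:20 train/validation division at k = 5.
#'
#' @param nItems Number of items (>= k).
#' @param k Folds.
#' @param seed Integer seed for the shuffling.
#' @return List of `k` lists with elements `train` and `val`.
#' @export
kfoldSplit <- function(nItems, k = 5L, seed = 1L) {
  if (nItems < k)
    stop(sprintf("cannot split %d items into %d folds", nItems, k),
         call. = FALSE)
  perm <- withSeed(seed, sample.int(nItems))
  fold <- rep_len(seq_len(k), nItems)
  lapply(seq_len(k), function(i) {
    val <- sort(perm[fold == i])
    list(train = sort(perm[fold != i]), val = val)
  })
}

## ---- optimisation ----

.gradGlobalNorm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

.assembleBatch <- function(dataset, idx, augment = NULL) {
  n <- length(idx)
  d <- dim(dataset[[idx[1]]]$image)
  x <- array(0, dim = c(n, 1, d[1], d[2]))
  y <- array(0, dim = c(n, d[1], d[2]))
  for (b in seq_len(n)) {
    s <- dataset[[idx[b]]]
    if (!is.null(augment)) s <- augmentSample(s, augment)
    x[b, 1, , ] <- s$image
    y[b, , ] <- s$mask
  }
  list(x = x, y = y)
}

#' Mean per-image Dice of model predictions over a dataset
#' @param model A [UNTCAModel-class].
#' @param dataset List of samples.
#' @return Mean Dice in \[0, 1\].
#' @export
evaluateDice <- function(model, dataset) {
  mean(vapply(dataset, function(s) {
    diceScore(predictMask(model, s$image)$mask, s$mask)
  }, numeric(1)))
}

#' Train a model
#'
#' Stochastic gradient descent with momentum on the equally weighted
#' soft-Dice + cross-entropy loss; the learning rate decays
#' polynomially, `lr * (1 - step/steps)^0.9`. Every stochastic choice
#' (initialisation, batching, augmentation) is derived from the seed in
#' the training configuration, so runs are bit-for-bit reproducible.
#'
#' @param dataset Non-empty list of [segmentationSample()]s.
#' @param modelCfg A [BackboneConfig-class].
#' @param cfg A [TrainConfig-class].
#' @param valDataset Optional validation samples; when given, the
#'   checkpoint with the best validation Dice is kept.
#' @param checkpointPath Optional path; the checkpoint (weights, both
#'   configurations, seed, history) is saved there with [saveRDS()].
#' @param verbose Print progress.
#' @return List of class `untcaFit`: `model`, `history` (data.frame of
#'   step, loss, softDice, lr), `bestValDice`, `valHistory`, `seed`.
#' @export
trainModel <- function(dataset, modelCfg, cfg, valDataset = NULL,
                       checkpointPath = NULL, verbose = FALSE) {
  stopShape(length(dataset) > 0L, "dataset is empty")
  methods::validObject(cfg)
  model <- buildModel(modelCfg, seed = cfg@seed)
  params <- model@params
  vel <- lapply(params, function(p) p * 0)
  hist <- data.frame(step = integer(), loss = numeric(),
                     softDice = numeric(), lr = numeric())
  valHist <- data.frame(step = integer(), valDice = numeric())
  best <- list(dice = -Inf, params = params)
  withSeed(cfg@seed, {
    for (step in seq_len(cfg@steps)) {
      idx <- sample.int(length(dataset), cfg@batchSize, replace = TRUE)
      batch <- .assembleBatch(dataset, idx, cfg@augment)
      pn <- lapply(params, agLeaf)
      out <- .forwardNode(pn, agLeaf(batch$x), modelCfg, training = TRUE)
      loss <- agSegLoss(out$logits, batch$y)
      if (!is.finite(loss$node$value))
        stop(sprintf("loss became non-finite at step %d", step), call. = FALSE)
      agBackward(loss$node)
      grads <- lapply(pn, function(n) if (is.null(n$grad)) n$value * 0 else n$grad)
      gn <- .gradGlobalNorm(grads)
      sc <- if (gn > cfg@clipNorm) cfg@clipNorm / gn else 1
      lrt <- cfg@lr * (1 - (step - 1) / cfg@steps)^0.9
      for (nm in names(params)) {
        vel[[nm]] <- cfg@momentum * vel[[nm]] - lrt * sc * grads[[nm]]
        params[[nm]] <- params[[nm]] + vel[[nm]]
      }
      hist[nrow(hist) + 1L, ] <- list(step, loss$node$value, loss$dice, lrt)
      doEval <- !is.null(valDataset) &&
        (step %% cfg@evalEvery == 0L || step == cfg@steps)
      if (doEval) {
        model@params <- params
        vd <- evaluateDice(model, valDataset)
        valHist[nrow(valHist) + 1L, ] <- list(step, vd)
        if (vd > best$dice) best <- list(dice = vd, params = params)
        if (verbose) message(sprintf(
          "step %d  loss %.4f  soft-Dice %.4f  val Dice %.4f",
          step, loss$node$value, loss$dice, vd))
      } else if (verbose && step %% 25L == 0L) {
        message(sprintf("step %d  loss %.4f  soft-Dice %.4f",
                        step, loss$node$value, loss$dice))
      }
    }
  })
  model@params <- if (is.null(valDataset)) params else best$params
  fit <- structure(list(model = model, history = hist,
                        valHistory = valHist,
                        bestValDice = if (is.null(valDataset)) NA_real_
                                      else best$dice,
                        trainConfig = cfg, seed = cfg@seed),
                   class = "untcaFit")
  if (!is.null(checkpointPath)) saveCheckpoint(fit, checkpointPath)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a training checkpoint
#'
#' The checkpoint is a single RDS file containing the weights, the model
#' and training configurations, the seed and the loss history, so a run
#' can be reproduced or resumed from it.
#' @param fit An `untcaFit` (or a [UNTCAModel-class] for `saveCheckpoint`).
#' @param path File path.
#' @return `loadCheckpoint` returns an `untcaFit`.
#' @export
saveCheckpoint <- function(fit, path) {
  if (methods::is(fit, "UNTCAModel"))
    fit <- structure(list(model = fit, history = NULL, valHistory = NULL,
                          bestValDice = NA_real_, trainConfig = NULL,
                          seed = fit@seed), class = "untcaFit")
  cfg <- fit$model@config
  payload <- list(
    params = fit$model@params,
    modelConfig = .configToList(cfg),
    trainConfig = if (!is.null(fit$trainConfig)) {
      tc <- fit$trainConfig
      list(steps = tc@steps, batchSize = tc@batchSize, lr = tc@lr,
           momentum = tc@momentum, clipNorm = tc@clipNorm, seed = tc@seed,
           folds = tc@folds, valFraction = tc@valFraction,
           augment = tc@augment, evalEvery = tc@evalEvery)
    },
    seed = fit$seed, history = fit$history, valHistory = fit$valHistory,
    bestValDice = fit$bestValDice)
  saveRDS(payload, path)
  invisible(path)
}

.configToList <- function(cfg) {
  list(depth = cfg@depth, widths = cfg@widths, tokenWidths = cfg@tokenWidths,
       tokenGrid = cfg@tokenGrid, encodingStrategy = cfg@encodingStrategy,
       useGnconv = cfg@useGnconv, useTransformer = cfg@useTransformer,
       inChannels = cfg@inChannels, nClasses = cfg@nClasses, gnN = cfg@gnN,
       padPolicy = cfg@padPolicy, ffnHidden = cfg@ffnHidden,
       dropout = cfg@dropout, alpha = cfg@alpha, heads = cfg@heads,
       normMode = cfg@normMode)
}

.configFromList <- function(x) do.call(backboneConfig, x)

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  payload <- readRDS(path)
  cfg <- .configFromList(payload$modelConfig)
  model <- new("UNTCAModel", config = cfg, params = payload$params,
               seed = as.integer(payload$seed %||% 1L))
  structure(list(model = model, history = payload$history,
                 valHistory = payload$valHistory,
                 bestValDice = payload$bestValDice,
                 trainConfig = if (!is.null(payload$trainConfig))
                   do.call(trainConfig, payload$trainConfig),
                 seed = payload$seed), class = "untcaFit")
}
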