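# U-shaped encoder-decoder backbone hosting the nested transformer blocks
# and the bottom-up recursive transmission of multi-scale features.
#
# Levels are numbered 1 (full resolution) .. depth (bottleneck). Decoder
# junctions are numbered by the bottom-up index i = 1 (deepest, at the
# bottleneck) .. depth-1 (full resolution). At every junction the
# up-sampled feature x_u and the encoder skip x_d are projected to the
# junction's token width, resampled to a common token grid, and run
# through the nested block; the junction then emits the multi-scale
# bundle x_c^(i+1) = H(x_d, x_hat_u, x_c, gn(x_u)) (at the deepest
# junction the phi_in intermediates of gnConv stand in for x_hat_u, x_c).

#' Backbone configuration
#'
#' @slot depth Number of resolution levels (>= 2).
#' @slot inChannels Image channels (1 for grayscale).
#' @slot nClasses Output classes (2: background/foreground).
#' @slot widths Per-level convolution widths, length `depth`.
#' @slot tokenWidths Per-junction token widths, length `depth - 1`,
#'   ordered bottom-up (junction 1 is the deepest).
#' @slot tokenGrid Side length of the shared token grid all junction
#'   features are resampled to before attention (22 by default, so the
#'   484-channel token width re-grids onto a 22 x 22 channel plane).
#' @slot encodingStrategy "concatenation" or "interpolation" fusion in
#'   the multi-scale aggregation H.
#' @slot useGnconv,useTransformer Ablation switches.
#' @slot gnN gnConv interaction order.
#' @slot padPolicy gnConv channel-grid pad policy.
#' @slot ffnHidden,dropout,alpha,heads,normMode Nested-block settings.
#' @export
setClass("BackboneConfig", representation(
  depth = "integer", inChannels = "integer", nClasses = "integer",
  widths = "integer", tokenWidths = "integer", tokenGrid = "integer",
  encodingStrategy = "character", useGnconv = "logical",
  useTransformer = "logical", gnN = "integer", padPolicy = "character",
  ffnHidden = "integer", dropout = "numeric", alpha = "numeric",
  heads = "integer", normMode = "character"
))

setValidity("BackboneConfig", function(object) {
  msgs <- character()
  if (object@depth < 2L) msgs <- c(msgs, "depth must be >= 2")
  if (length(object@widths) != object@depth)
    msgs <- c(msgs, "widths must have length depth")
  if (length(object@tokenWidths) != object@depth - 1L)
    msgs <- c(msgs, "tokenWidths must have length depth - 1")
  if (!object@encodingStrategy %in% c("concatenation", "interpolation"))
    msgs <- c(msgs, "encodingStrategy must be 'concatenation' or 'interpolation'")
  C <- object@tokenGrid^2
  if (C %% 2L^(object@gnN - 1L) != 0L)
    msgs <- c(msgs, sprintf(
      "tokenGrid^2 = %d must be divisible by 2^(gnN-1) = %d",
      C, 2L^(object@gnN - 1L)))
  if (length(msgs)) msgs else TRUE
})

#' Construct a backbone configuration
#'
#' Defaults follow the 2-D nnUNet convention for a 384 x 384 input:
#' five levels with widths 32..512, token widths 484/484/484/256 at the
#' four decoder junctions, a 22 x 22 token grid, gnConv order 3,
#' concatenation encoding, dropout 0.1, FFN width 2048 and fusion weight
#' alpha = 0.3.
#'
#' @param depth Resolution levels.
#' @param widths Integer vector of per-level channel widths.
#' @param tokenWidths Integer vector of per-junction token widths
#'   (bottom-up); recycled/truncated to `depth - 1`.
#' @param tokenGrid Shared token grid side.
#' @param encodingStrategy "concatenation" (default) or "interpolation".
#' @param useGnconv,useTransformer Ablation switches (default both on).
#' @param inChannels,nClasses Image channels / output classes.
#' @param gnN gnConv order (default 3).
#' @param padPolicy gnConv pad policy.
#' @param ffnHidden,dropout,alpha,heads,normMode Nested-block settings.
#' @return A [BackboneConfig-class].
#' @export
backboneConfig <- function(depth = 5L, widths = c(32L, 64L, 128L, 256L, 512L),
                           tokenWidths = c(484L, 484L, 484L, 256L),
                           tokenGrid = 22L,
                           encodingStrategy = c("concatenation", "interpolation"),
                           useGnconv = TRUE, useTransformer = TRUE,
                           inChannels = 1L, nClasses = 2L, gnN = 3L,
                           padPolicy = "pad", ffnHidden = 2048L,
                           dropout = 0.1, alpha = 0.3, heads = 1L,
                           normMode = "pre") {
  depth <- as.integer(depth)
  tw <- rep_len(as.integer(tokenWidths), depth - 1L)
  new("BackboneConfig", depth = depth, inChannels = as.integer(inChannels),
      nClasses = as.integer(nClasses), widths = as.integer(widths),
      tokenWidths = tw, tokenGrid = as.integer(tokenGrid),
      encodingStrategy = match.arg(encodingStrategy),
      useGnconv = useGnconv, useTransformer = useTransformer,
      gnN = as.integer(gnN), padPolicy = padPolicy,
      ffnHidden = as.integer(ffnHidden), dropout = dropout, alpha = alpha,
      heads = as.integer(heads), normMode = normMode)
}

#' Reduced desk-scale configuration
#'
#' A small model for 64 x 64 inputs: depth 3, base width 8 (widths
#' 8/16/32), token width 64 at both junctions, token grid 16 and a
#' 256-wide FFN. Used throughout the test-scale experiments.
#' @param ... Overrides passed to [backboneConfig()].
#' @return A [BackboneConfig-class].
#' @export
reducedConfig <- function(...) {
  args <- list(depth = 3L, widths = c(8L, 16L, 32L),
               tokenWidths = c(64L, 64L), tokenGrid = 16L,
               ffnHidden = 256L, ...)
  do.call(backboneConfig, args[!duplicated(names(args), fromLast = TRUE)])
}

.nestedCfg <- function(cfg, i) {
  nestedBlockConfig(cfg@tokenWidths[i], ffnHidden = cfg@ffnHidden,
                    dropout = cfg@dropout, alpha = cfg@alpha,
                    heads = cfg@heads, normMode = cfg@normMode)
}

.gnCfg <- function(cfg, i) {
  gnConvConfig(cfg@gnN, inChannels = cfg@tokenWidths[i],
               inHeight = cfg@tokenGrid, inWidth = cfg@tokenGrid,
               padPolicy = cfg@padPolicy)
}

# Widths of the four bundle parts emitted at junction i.
.bundlePartWidths <- function(cfg, i) {
  d <- cfg@tokenWidths[i]
  if (i == 1L && cfg@useGnconv) {
    g2 <- cfg@tokenGrid^2
    c0 <- g2 %/% 2L^(cfg@gnN - 1L)
    c(d, c0, 2L * g2 - c0, d)
  } else c(d, d, d, d)
}

## ---- parameter construction ----

.initConvUnit <- function(p, prefix, cin, cout, k = 3L) {
  p[[paste0(prefix, ".W")]] <- initArray(c(cout, cin, k, k))
  p[[paste0(prefix, ".b")]] <- numeric(cout)
  p[[paste0(prefix, ".g")]] <- rep(1, cout)
  p[[paste0(prefix, ".beta")]] <- numeric(cout)
  p
}

#' Initialise parameters for one convolution stage
#'
#' @param inChannels,width Input/output channel widths.
#' @param direction "down" or "up".
#' @param seed Integer seed.
#' @param prefix Name prefix.
#' @return Named list of arrays.
#' @export
initConvStageParams <- function(inChannels, width, direction, seed = 1L,
                                prefix = "") {
  withSeed(seed, {
    p <- list()
    if (direction == "down") {
      p <- .initConvUnit(p, paste0(prefix, "c1"), inChannels, width)
    } else {
      p[[paste0(prefix, "t.W")]] <- initArray(c(inChannels, width, 2L, 2L))
      p[[paste0(prefix, "t.b")]] <- numeric(width)
      p[[paste0(prefix, "t.g")]] <- rep(1, width)
      p[[paste0(prefix, "t.beta")]] <- numeric(width)
    }
    .initConvUnit(p, paste0(prefix, "c2"), width, width)
  })
}

.initBackboneParams <- function(cfg, seed) {
  withSeed(seed, {
    L <- cfg@depth; w <- cfg@widths
    p <- list()
    p <- .initConvUnit(p, "stem.c1", cfg@inChannels, w[1])
    p <- .initConvUnit(p, "stem.c2", w[1], w[1])
    for (l in 2:L) {
      p <- .initConvUnit(p, paste0("down", l, ".c1"), w[l - 1], w[l])
      p <- .initConvUnit(p, paste0("down", l, ".c2"), w[l], w[l])
    }
    for (j in seq_len(L - 1L)) {
      p[[paste0("up", j, ".t.W")]] <- initArray(c(w[j + 1], w[j], 2L, 2L))
      p[[paste0("up", j, ".t.b")]] <- numeric(w[j])
      p[[paste0("up", j, ".t.g")]] <- rep(1, w[j])
      p[[paste0("up", j, ".t.beta")]] <- numeric(w[j])
      p <- .initConvUnit(p, paste0("up", j, ".c1"), w[j], w[j])
      p <- .initConvUnit(p, paste0("dec", j, ".c1"), 2L * w[j], w[j])
      p <- .initConvUnit(p, paste0("dec", j, ".c2"), w[j], w[j])
    }
    p[["head.W"]] <- initArray(c(cfg@nClasses, w[1]))
    p[["head.b"]] <- numeric(cfg@nClasses)
    tokens <- cfg@useGnconv || cfg@useTransformer
    if (tokens) for (i in seq_len(L - 1L)) {
      j <- L - i              # junction i sits at level j
      d <- cfg@tokenWidths[i]
      pref <- paste0("jn", i, ".")
      p[[paste0(pref, "projU.W")]] <- initArray(c(d, w[j]))
      p[[paste0(pref, "projU.b")]] <- numeric(d)
      p[[paste0(pref, "back.W")]] <- initArray(c(w[j], d))
      p[[paste0(pref, "back.b")]] <- numeric(w[j])
      if (cfg@useGnconv)
        p <- c(p, initGnConvParams(.gnCfg(cfg, i), seed = seed + i,
                                   prefix = paste0(pref, "gn.")))
      if (cfg@useTransformer) {
        p[[paste0(pref, "projD.W")]] <- initArray(c(d, w[j]))
        p[[paste0(pref, "projD.b")]] <- numeric(d)
        p <- c(p, initNestedBlockParams(.nestedCfg(cfg, i),
                                        seed = seed + 100L + i,
                                        prefix = pref))
        if (i == 1L) {
          # the deepest junction has no incoming bundle: its nested block
          # runs only the encoder attention, so no decoder/FFN weights
          drop <- grepl(paste0("^", pref, "(dec|ffn)\\."), names(p))
          p <- p[!drop]
        }
        dn <- if (i < L - 1L) cfg@tokenWidths[i + 1L] else cfg@tokenWidths[i]
        pw <- .bundlePartWidths(cfg, i)
        if (cfg@encodingStrategy == "concatenation") {
          p[[paste0(pref, "bundle.proj.W")]] <- initArray(c(dn, sum(pw)))
          p[[paste0(pref, "bundle.proj.b")]] <- numeric(dn)
        } else {
          for (k in seq_along(pw)) {
            p[[paste0(pref, "bundle.p", k, ".W")]] <- initArray(c(dn, pw[k]))
            p[[paste0(pref, "bundle.p", k, ".b")]] <- numeric(dn)
          }
          p[[paste0(pref, "bundle.proj.W")]] <- initArray(c(dn, dn))
          p[[paste0(pref, "bundle.proj.b")]] <- numeric(dn)
        }
      }
    }
    if (tokens && cfg@useTransformer) {
      dtop <- cfg@tokenWidths[L - 1L]
      p[["bundleHead.W"]] <- initArray(c(w[1], dtop))
      p[["bundleHead.b"]] <- numeric(w[1])
    }
    p
  })
}

#' The U-NTCA model
#'
#' Holds the configuration, the flat named parameter list and the build
#' seed. Two builds from the same configuration and seed are identical.
#' @slot config A [BackboneConfig-class].
#' @slot params Named list of numeric arrays.
#' @slot seed Integer build seed.
#' @export
setClass("UNTCAModel", representation(
  config = "BackboneConfig", params = "list", seed = "integer"))

#' Build a model from a backbone configuration
#'
#' Weights are truncated-normal (sd 0.02), biases zero, normalisation
#' gains one; the parameter set is a pure function of the configuration
#' and seed.
#' @param cfg A [BackboneConfig-class].
#' @param seed Integer seed.
#' @return A [UNTCAModel-class].
#' @export
buildModel <- function(cfg, seed = 1L) {
  methods::validObject(cfg)
  new("UNTCAModel", config = cfg, params = .initBackboneParams(cfg, seed),
      seed = as.integer(seed))
}

#' Number of trainable parameters
#' @param model A [UNTCAModel-class].
#' @return Integer count.
#' @export
parameterCount <- function(model) {
  sum(vapply(model@params, length, numeric(1)))
}

setMethod("show", "UNTCAModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "UNTCAModel: depth %d, widths [%s], token widths [%s], grid %d\n  gnConv %s (n = %d), transformer %s, encoding '%s'\n  %d parameter arrays, %s parameters, seed %d\n",
    cfg@depth, paste(cfg@widths, collapse = ","),
    paste(cfg@tokenWidths, collapse = ","), cfg@tokenGrid,
    if (cfg@useGnconv) "on" else "off", cfg@gnN,
    if (cfg@useTransformer) "on" else "off", cfg@encodingStrategy,
    length(object@params), format(parameterCount(object), big.mark = ","),
    object@seed))
})

## ---- node-level forward ----

.convUnit <- function(x, pn, prefix, stride = 1L) {
  y <- agConv2d(x, pn[[paste0(prefix, ".W")]], pn[[paste0(prefix, ".b")]],
                stride = stride, pad = 1L)
  y <- agInstanceNorm(y, pn[[paste0(prefix, ".g")]],
                      pn[[paste0(prefix, ".beta")]])
  agLeakyRelu(y, 0.01)
}

.upUnit <- function(x, pn, prefix) {
  y <- agConvTranspose2(x, pn[[paste0(prefix, "t.W")]],
                        pn[[paste0(prefix, "t.b")]])
  y <- agInstanceNorm(y, pn[[paste0(prefix, "t.g")]],
                      pn[[paste0(prefix, "t.beta")]])
  agLeakyRelu(y, 0.01)
}

.convStageNode <- function(x, pn, prefix, direction) {
  if (direction == "down") {
    d <- dim(x$value)
    if (d[3] %% 2L != 0L || d[4] %% 2L != 0L)
      stop(sprintf("cannot halve a %d x %d feature; spatial size must be even",
                   d[3], d[4]), call. = FALSE)
    y <- .convUnit(x, pn, paste0(prefix, "c1"), stride = 2L)
  } else {
    y <- .upUnit(x, pn, prefix)
  }
  .convUnit(y, pn, paste0(prefix, "c2"))
}

#' One encoder/decoder convolution stage
#'
#' Two convolution-instance-norm-leaky-ReLU units; "down" halves the
#' spatial size with a strided convolution, "up" doubles it with a
#' transposed convolution.
#'
#' @param x 4-D array (batch, channel, row, col).
#' @param width Output channel width.
#' @param direction "down" or "up".
#' @param params Parameters from [initConvStageParams()] (created
#'   automatically from `seed` when omitted).
#' @param seed Seed for automatic parameter creation.
#' @return 4-D array.
#' @export
convStage <- function(x, width, direction = c("down", "up"), params = NULL,
                      seed = 1L) {
  direction <- match.arg(direction)
  if (is.null(params))
    params <- initConvStageParams(dim(x)[2], width, direction, seed)
  .convStageNode(agLeaf(x), .asParamNodes(params), "", direction)$value
}

# Project a map to token width d and resample onto the shared token grid;
# returns list(tokens = node (N, g^2, d), map = the projected g x g map).
.toTokens <- function(x, pn, wKey, bKey, g) {
  # Resample first, then project: both maps are linear and commute, and
  # the pointwise projection is far cheaper on the small token grid.
  y <- agBilinearResize(x, g, g)
  y <- agChannelLinear(y, pn[[wKey]], pn[[bKey]])
  list(tokens = agMapToTokens(y), map = y)
}

.aggregateHNode <- function(parts, grids, strategy, targetWidth, targetGrid,
                            pn = NULL, prefix = "") {
  stopShape(length(parts) >= 2L, "aggregate_H needs at least two parts")
  aligned <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    m <- agTokensToMap(parts[[k]], grids[[k]][1], grids[[k]][2])
    m <- agBilinearResize(m, targetGrid, targetGrid)
    aligned[[k]] <- agMapToTokens(m)
  }
  if (strategy == "concatenation") {
    out <- agConcat(aligned, 3L)
    if (!is.null(pn) && !is.null(pn[[paste0(prefix, "bundle.proj.W")]]))
      out <- agTokenLinear(out, pn[[paste0(prefix, "bundle.proj.W")]],
                           pn[[paste0(prefix, "bundle.proj.b")]])
    out
  } else {
    proj <- vector("list", length(aligned))
    for (k in seq_along(aligned)) {
      wk <- if (!is.null(pn)) pn[[paste0(prefix, "bundle.p", k, ".W")]]
      proj[[k]] <- if (is.null(wk)) aligned[[k]]
        else agTokenLinear(aligned[[k]], wk, pn[[paste0(prefix, "bundle.p", k, ".b")]])
    }
    acc <- proj[[1]]
    for (k in seq_along(proj)[-1]) acc <- agAdd(acc, proj[[k]])
    out <- agScale(acc, 1 / length(proj))
    if (!is.null(pn) && !is.null(pn[[paste0(prefix, "bundle.proj.W")]]))
      out <- agTokenLinear(out, pn[[paste0(prefix, "bundle.proj.W")]],
                           pn[[paste0(prefix, "bundle.proj.b")]])
    out
  }
}

#' Multi-scale aggregation H
#'
#' Fuses the four bundle parts (down-sampled feature, enhanced up-sampled
#' feature, transmitted multi-scale feature, gnConv feature) into the
#' bundle handed to the next junction. Under "concatenation" the
#' token-grid-aligned parts are concatenated along the feature axis and
#' linearly projected; under "interpolation" they are projected to a
#' common width, averaged with fixed equal weights, and projected again.
#'
#' @param parts List of >= 2 token sequences (batch, token, feature).
#' @param strategy "concatenation" or "interpolation".
#' @param targetWidth Output feature width.
#' @param params Optional named list with `bundle.proj.W/b` (and
#'   `bundle.p<k>.W/b` for interpolation); `NULL` applies identity
#'   projections (requires matching widths).
#' @param grids Optional list of c(rows, cols) token grids per part;
#'   square grids inferred from token counts when omitted.
#' @param targetGrid Output token grid side; defaults to the first part's.
#' @return Token sequence (batch, targetGrid^2, width).
#' @export
aggregateH <- function(parts, strategy = c("concatenation", "interpolation"),
                       targetWidth, params = NULL, grids = NULL,
                       targetGrid = NULL) {
  strategy <- match.arg(strategy)
  if (length(parts) < 2L) stop("aggregate_H needs at least two parts", call. = FALSE)
  if (is.null(grids))
    grids <- lapply(parts, function(p) rep(as.integer(round(sqrt(dim(p)[2]))), 2))
  if (is.null(targetGrid)) targetGrid <- grids[[1]][1]
  pn <- if (!is.null(params)) .asParamNodes(params)
  .aggregateHNode(lapply(parts, agLeaf), grids, strategy, targetWidth,
                  targetGrid, pn)$value
}

# Full forward pass on nodes. Returns logits plus per-junction artefacts.
.forwardNode <- function(pn, x, cfg, training = FALSE) {
  L <- cfg@depth; g <- cfg@tokenGrid
  tokens <- cfg@useGnconv || cfg@useTransformer
  d0 <- dim(x$value)
  div <- 2L^(L - 1L)
  if (d0[3] %% div != 0L || d0[4] %% div != 0L)
    stop(sprintf(
      "input %d x %d not divisible by 2^(depth-1) = %d; minimal valid size is %d x %d",
      d0[3], d0[4], div, div, div), call. = FALSE)
  e <- vector("list", L)
  e[[1]] <- .convUnit(.convUnit(x, pn, "stem.c1"), pn, "stem.c2")
  for (l in 2:L)
    e[[l]] <- .convStageNode(e[[l - 1]], pn, paste0("down", l, "."), "down")
  bundles <- list(); blockCalls <- 0L; bundleArity <- integer(0)
  fused <- vector("list", L - 1L)
  prev <- e[[L]]
  xc <- NULL                 # incoming bundle tokens for the next junction
  for (i in seq_len(L - 1L)) {
    j <- L - i
    pref <- paste0("jn", i, ".")
    u <- .upUnit(prev, pn, paste0("up", j, "."))
    u <- .convUnit(u, pn, paste0("up", j, ".c1"))
    if (tokens) {
      d <- cfg@tokenWidths[i]
      tu <- .toTokens(u, pn, paste0(pref, "projU.W"), paste0(pref, "projU.b"), g)
      xuTok <- tu$tokens
      gnRes <- NULL
      if (cfg@useGnconv) {
        gnRes <- .gnconvNode(tu$map, .gnCfg(cfg, i), pn,
                             prefix = paste0(pref, "gn."),
                             intermediates = (i == 1L && cfg@useTransformer))
        gnOut <- if (is.list(gnRes) && !agIs(gnRes)) gnRes$out else gnRes
        gTok <- agMapToTokens(gnOut)
      } else gTok <- xuTok
      if (cfg@useTransformer) {
        ncfg <- .nestedCfg(cfg, i)
        td <- .toTokens(e[[j]], pn, paste0(pref, "projD.W"),
                        paste0(pref, "projD.b"), g)
        xdTok <- td$tokens
        xhatU <- .encodeUpsampleNode(xuTok, xdTok, gTok, ncfg, pn, pref, training)
        blockCalls <- blockCalls + 1L
        if (!is.null(xc)) {
          xhatC <- .decodeMultiscaleNode(xc, xhatU, xdTok, ncfg, pn, pref, training)
          xtildeC <- .ffnUpdateNode(xhatC, ncfg, pn, pref, training)
          xtildeU <- .fuseAlphaNode(xuTok, xtildeC, cfg@alpha)
        } else {
          xtildeU <- xhatU
        }
        fused[[i]] <- xtildeU
        # bundle for junction i+1
        s <- if (cfg@useGnconv) .gnCfg(cfg, i)@gridSide else g
        if (i == 1L && cfg@useGnconv) {
          parts <- list(xdTok, agMapToTokens(gnRes$p0),
                        agMapToTokens(gnRes$qcat), gTok)
          grids <- list(c(g, g), c(s, s), c(s, s), c(g, g))
        } else if (i == 1L) {
          parts <- list(xdTok, xuTok, xuTok, gTok)
          grids <- rep(list(c(g, g)), 4)
        } else {
          parts <- list(xdTok, xhatU, xc, gTok)
          grids <- rep(list(c(g, g)), 4)
        }
        bundleArity <- c(bundleArity, length(parts))
        xc <- .aggregateHNode(parts, grids, cfg@encodingStrategy,
                              targetWidth = NA, targetGrid = g,
                              pn = pn, prefix = pref)
        bundles[[i]] <- xc
        # fold the refined tokens back into the convolutional stream
        back <- agTokensToMap(xtildeU, g, g)
        back <- agChannelLinear(back, pn[[paste0(pref, "back.W")]],
                                pn[[paste0(pref, "back.b")]])
        back <- agBilinearResize(back, dim(u$value)[3], dim(u$value)[4])
        u <- agAdd(u, back)
      } else if (cfg@useGnconv) {
        back <- agTokensToMap(gTok, g, g)
        back <- agChannelLinear(back, pn[[paste0(pref, "back.W")]],
                                pn[[paste0(pref, "back.b")]])
        back <- agBilinearResize(back, dim(u$value)[3], dim(u$value)[4])
        u <- agAdd(u, back)
        fused[[i]] <- xuTok
      }
    }
    cat0 <- agConcat(list(u, e[[j]]), 2L)
    prev <- .convUnit(.convUnit(cat0, pn, paste0("dec", j, ".c1")), pn,
                      paste0("dec", j, ".c2"))
  }
  if (tokens && cfg@useTransformer && !is.null(xc)) {
    top <- agTokensToMap(xc, g, g)
    top <- agChannelLinear(top, pn[["bundleHead.W"]], pn[["bundleHead.b"]])
    top <- agBilinearResize(top, dim(prev$value)[3], dim(prev$value)[4])
    prev <- agAdd(prev, top)
  }
  logits <- agChannelLinear(prev, pn[["head.W"]], pn[["head.b"]])
  list(logits = logits, bundles = bundles, blockCalls = blockCalls,
       bundleArity = bundleArity, fused = fused)
}

.softmaxChannel <- function(z) {
  # (N, C, H, W) softmax over channels, numerically stable
  d <- dim(z)
  zmax <- array(z[, 1, , ], dim = d[c(1, 3, 4)])
  for (cix in seq_len(d[2])[-1])
    zmax <- pmax(zmax, array(z[, cix, , ], dim = d[c(1, 3, 4)]))
  e <- array(0, dim = d); s <- array(0, dim = d[c(1, 3, 4)])
  for (cix in seq_len(d[2])) {
    e[, cix, , ] <- exp(array(z[, cix, , ], dim = d[c(1, 3, 4)]) - zmax)
    s <- s + array(e[, cix, , ], dim = d[c(1, 3, 4)])
  }
  for (cix in seq_len(d[2])) e[, cix, , ] <- array(e[, cix, , ], dim = d[c(1, 3, 4)]) / s
  e
}

#' Forward pass of the full network
#'
#' @param model A [UNTCAModel-class].
#' @param image 4-D array (batch, channel, row, col), or a plain matrix
#'   for a single grayscale image; spatial size must be divisible by
#'   `2^(depth-1)`.
#' @param details If `TRUE`, also return the multi-scale bundles, the
#'   nested-block invocation count and the bundle arities.
#' @return The per-pixel class probability array (batch, nClasses, row,
#'   col), channels summing to one; or a list when `details = TRUE`.
#' @export
untcaForward <- function(model, image, details = FALSE) {
  if (is.matrix(image)) image <- array(image, dim = c(1, 1, dim(image)))
  pn <- .asParamNodes(model@params)
  r <- .forwardNode(pn, agLeaf(image), model@config, training = FALSE)
  prob <- .softmaxChannel(r$logits$value)
  if (!details) return(prob)
  list(prob = prob, bundles = lapply(r$bundles, agVal),
       blockCalls = r$blockCalls, bundleArity = r$bundleArity)
}

#' Recursive bottom-up transmission of multi-scale features
#'
#' Runs the encoder and the decoder path, returning the per-junction
#' fused token features and the multi-scale bundles produced by the
#' aggregation H (exactly `depth - 1` bundles, four parts each).
#'
#' @param model A [UNTCAModel-class] (transformer enabled).
#' @param image Input image array or matrix.
#' @return List with `fused` (per-junction token sequences, bottom-up),
#'   `bundles`, `blockCalls` and `bundleArity`.
#' @export
recursiveTransmit <- function(model, image) {
  if (is.matrix(image)) image <- array(image, dim = c(1, 1, dim(image)))
  pn <- .asParamNodes(model@params)
  r <- .forwardNode(pn, agLeaf(image), model@config, training = FALSE)
  list(fused = lapply(r$fused, agVal), bundles = lapply(r$bundles, agVal),
       blockCalls = r$blockCalls, bundleArity = r$bundleArity)
}

#' Segment an image
#'
#' @param model A [UNTCAModel-class].
#' @param image Matrix in \[0, 1\] or 4-D array.
#' @return List with `prob` (foreground probability map(s)) and `mask`
#'   (argmax binary mask(s)), as matrices for a single image.
#' @export
predictMask <- function(model, image) {
  single <- is.matrix(image)
  prob <- untcaForward(model, image)
  fg <- prob[, 2, , , drop = FALSE]
  bg <- prob[, 1, , , drop = FALSE]
  mask <- (fg > bg) * 1
  if (single) {
    list(prob = array(fg, dim = dim(fg)[3:4]),
         mask = array(mask, dim = dim(mask)[3:4]))
  } else {
    list(prob = array(fg, dim = dim(fg)[c(1, 3, 4)]),
         mask = array(mask, dim = dim(mask)[c(1, 3, 4)]))
  }
}
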