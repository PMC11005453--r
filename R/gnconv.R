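# Recursive gated convolution (gnConv) high-order channel attention.
#
# The operator first re-interprets the channel axis of a feature map as a
# small spatial grid: a map with C0 channels over an H0 x W0 extent becomes
# a map with H0*W0 channels over a sqrt(C0) x sqrt(C0) grid. On the
# re-gridded feature a pointwise projection doubles the width, the result
# is split into a seed group p0 and n gating groups q_0..q_{n-1} whose
# widths double along the schedule C_k = C / 2^(n-k-1), and n elementwise
# gating steps p_{k+1} = f_k(q_k) * g_k(p_k) mix them; f_k is a shared
# depthwise convolution over the concatenated q groups, g_k a pointwise
# width-raising projection (identity at the first step, where p0 and q0
# share the width C_0).

#' Configuration for the gnConv operator
#'
#' @slot n Interaction order (number of gating steps).
#' @slot inChannels Channel count of the incoming feature map (C0).
#' @slot inHeight,inWidth Spatial extent of the incoming feature map.
#' @slot gridSide Side length of the channel grid after the reshape
#'   (sqrt of the padded channel count).
#' @slot baseChannels Width C of the re-gridded feature (= inHeight*inWidth).
#' @slot schedule Integer vector of per-order widths C_0..C_{n-1}.
#' @slot padPolicy Either "pad" (zero-pad channels up to the next perfect
#'   square) or "strict" (error on non-square channel counts).
#' @export
setClass("GnConvConfig", representation(
  n = "integer", inChannels = "integer", inHeight = "integer",
  inWidth = "integer", gridSide = "integer", baseChannels = "integer",
  schedule = "integer", padPolicy = "character"
))

setValidity("GnConvConfig", function(object) {
  msgs <- character()
  if (object@n < 1L) msgs <- c(msgs, "interaction order n must be >= 1")
  if (!object@padPolicy %in% c("pad", "strict"))
    msgs <- c(msgs, "padPolicy must be 'pad' or 'strict'")
  C <- object@baseChannels
  if (C %% 2L^(object@n - 1L) != 0L)
    msgs <- c(msgs, sprintf(
      "base width C = %d is not divisible by 2^(n-1) = %d (n = %d)",
      C, 2L^(object@n - 1L), object@n))
  if (length(object@schedule) != object@n)
    msgs <- c(msgs, "schedule length must equal n")
  if (length(msgs)) msgs else TRUE
})

#' Per-order channel schedule of gnConv
#'
#' Computes the channel width of each interaction order,
#' `C_k = C / 2^(n-k-1)` for `k = 0..n-1`: widths double at each order and
#' the final order has the full width `C`.
#'
#' @param C Base channel width (must be divisible by `2^(n-1)`).
#' @param n Interaction order, a positive integer.
#' @return Integer vector of `n` widths, strictly doubling, ending at `C`.
#' @examples
#' channelSchedule(484, 3)  # 121 242 484
#' @export
channelSchedule <- function(C, n) {
  stopifnot(is.numeric(C), is.numeric(n), length(C) == 1L, length(n) == 1L)
  n <- as.integer(n); C <- as.integer(C)
  if (n < 1L) stop("interaction order n must be >= 1", call. = FALSE)
  if (C %% 2L^(n - 1L) != 0L)
    stop(sprintf("C = %d is not divisible by 2^(n-1) = %d (n = %d)",
                 C, 2L^(n - 1L), n), call. = FALSE)
  as.integer(C / 2L^(n - seq_len(n)))
}

#' Construct a gnConv configuration
#'
#' @param n Interaction order (default 3).
#' @param inChannels Channels of the feature entering the operator.
#' @param inHeight,inWidth Spatial extent of the feature entering the
#'   operator; the re-gridded width is `inHeight * inWidth`.
#' @param padPolicy "pad" (default) zero-pads channels to the next perfect
#'   square before the grid reshape; "strict" errors on non-square counts.
#' @return A [GnConvConfig-class] object.
#' @export
gnConvConfig <- function(n = 3L, inChannels, inHeight, inWidth,
                         padPolicy = c("pad", "strict")) {
  padPolicy <- match.arg(padPolicy)
  s <- sqrt(inChannels)
  if (padPolicy == "strict" && s != floor(s))
    stop(sprintf("channel count %d is not a perfect square (padPolicy = 'strict')",
                 inChannels), call. = FALSE)
  s <- as.integer(ceiling(s))
  C <- as.integer(inHeight * inWidth)
  new("GnConvConfig", n = as.integer(n), inChannels = as.integer(inChannels),
      inHeight = as.integer(inHeight), inWidth = as.integer(inWidth),
      gridSide = s, baseChannels = C, schedule = channelSchedule(C, n),
      padPolicy = padPolicy)
}

setMethod("show", "GnConvConfig", function(object) {
  cat(sprintf(
    "GnConvConfig: n = %d, input %d x %d x %d (C0 x H0 x W0)\n  grid side %d, base width %d, schedule [%s], padPolicy '%s'\n",
    object@n, object@inChannels, object@inHeight, object@inWidth,
    object@gridSide, object@baseChannels,
    paste(object@schedule, collapse = ", "), object@padPolicy))
})

## ---- channel-grid reshape ----

.gridReshapeNode <- function(x, padPolicy = "pad") {
  d <- dim(x$value)
  N <- d[1]; C0 <- d[2]; H0 <- d[3]; W0 <- d[4]
  s <- sqrt(C0)
  if (s != floor(s)) {
    if (padPolicy == "strict")
      stop(sprintf("channel count %d is not a perfect square (padPolicy = 'strict')",
                   C0), call. = FALSE)
    s <- ceiling(s)
  }
  s <- as.integer(s)
  padded <- if (s * s > C0) {
    z <- agLeaf(array(0, dim = c(N, s * s - C0, H0, W0)))
    agConcat(list(x, z), axis = 2L)
  } else x
  x5 <- agReshape(padded, c(N, s, s, H0, W0))
  y5 <- agPermute(x5, c(1, 4, 5, 2, 3))
  agReshape(y5, c(N, H0 * W0, s, s))
}

.gridReshapeInvNode <- function(y, C0, H0, W0) {
  d <- dim(y$value)
  N <- d[1]; s <- d[3]
  y5 <- agReshape(y, c(N, H0, W0, s, s))
  x5 <- agPermute(y5, c(1, 4, 5, 2, 3))
  xp <- agReshape(x5, c(N, s * s, H0, W0))
  if (s * s > C0) agSlice(xp, 2L, 1L, C0) else xp
}

#' Channel-as-spatial grid reshape
#'
#' Lays the channel axis of a feature map out on a square grid: a map with
#' `C0` channels over `H0 x W0` becomes a map with `H0*W0` channels over a
#' `sqrt(C0) x sqrt(C0)` grid (channels zero-padded to the next perfect
#' square under the default pad policy). The transform is an index
#' bijection and [inverseChannelGridReshape()] undoes it exactly.
#'
#' @param x Numeric 4-D array in (batch, channel, row, col) order.
#' @param padPolicy "pad" or "strict".
#' @return The re-gridded array, with attributes `origChannels`,
#'   `origHeight`, `origWidth` recording the input geometry.
#' @export
channelGridReshape <- function(x, padPolicy = c("pad", "strict")) {
  padPolicy <- match.arg(padPolicy)
  stopShape(length(dim(x)) == 4L, "expected a 4-D (batch, channel, row, col) array")
  d <- dim(x)
  out <- .gridReshapeNode(agLeaf(x), padPolicy)$value
  attr(out, "origChannels") <- d[2]
  attr(out, "origHeight") <- d[3]
  attr(out, "origWidth") <- d[4]
  out
}

#' @rdname channelGridReshape
#' @param y A re-gridded array produced by [channelGridReshape()].
#' @param C0,H0,W0 Original geometry; taken from `y`'s attributes when
#'   omitted.
#' @export
inverseChannelGridReshape <- function(y, C0 = attr(y, "origChannels"),
                                      H0 = attr(y, "origHeight"),
                                      W0 = attr(y, "origWidth")) {
  stopShape(!is.null(C0) && !is.null(H0) && !is.null(W0),
            "original geometry unknown; pass C0, H0, W0")
  .gridReshapeInvNode(agLeaf(unclass(y)), C0, H0, W0)$value
}

## ---- parameters ----

#' Initialise gnConv parameters
#'
#' All projections carry biases; weights are truncated-normal (sd 0.02).
#'
#' @param cfg A [GnConvConfig-class].
#' @param seed Integer seed for reproducible initialisation.
#' @param prefix Name prefix for the returned parameter list.
#' @return Named list of numeric arrays.
#' @export
initGnConvParams <- function(cfg, seed = 1L, prefix = "") {
  withSeed(seed, {
    C <- cfg@baseChannels
    sch <- cfg@schedule
    qWidth <- 2L * C - sch[1]
    p <- list()
    p[[paste0(prefix, "phiIn.W")]] <- initArray(c(2L * C, C))
    p[[paste0(prefix, "phiIn.b")]] <- numeric(2L * C)
    p[[paste0(prefix, "dw.W")]] <- initArray(c(qWidth, 7L, 7L))
    p[[paste0(prefix, "dw.b")]] <- numeric(qWidth)
    if (cfg@n > 1L) for (k in seq_len(cfg@n - 1L)) {
      p[[paste0(prefix, "g", k, ".W")]] <- initArray(c(sch[k + 1], sch[k]))
      p[[paste0(prefix, "g", k, ".b")]] <- numeric(sch[k + 1])
    }
    p[[paste0(prefix, "phiOut.W")]] <- initArray(c(C, C))
    p[[paste0(prefix, "phiOut.b")]] <- numeric(C)
    p
  })
}

## ---- node-level forward pieces ----

# phi_in: pointwise projection C -> 2C, split into p0 (width C_0) and the
# q_k groups (widths C_0..C_{n-1}); total output width 2C.
.phiInNode <- function(x, cfg, pn, prefix = "") {
  C <- cfg@baseChannels
  stopShape(dim(x$value)[2] == C, sprintf(
    "phi_in expects %d channels, got %d", C, dim(x$value)[2]))
  y <- agChannelLinear(x, pn[[paste0(prefix, "phiIn.W")]],
                       pn[[paste0(prefix, "phiIn.b")]])
  sch <- cfg@schedule
  p0 <- agSlice(y, 2L, 1L, sch[1])
  q <- vector("list", cfg@n)
  off <- sch[1]
  for (k in seq_len(cfg@n)) {
    q[[k]] <- agSlice(y, 2L, off + 1L, off + sch[k])
    off <- off + sch[k]
  }
  list(p0 = p0, q = q)
}

# Recursive gating with the shared depthwise convolution over concat(q),
# per-step 1/sqrt(C_k) stabilisation, and the phi_out projection.
.recursiveGateNode <- function(p0, q, cfg, pn, prefix = "") {
  sch <- cfg@schedule
  qcat <- if (length(q) > 1L) agConcat(q, 2L) else q[[1]]
  fall <- agDepthwiseConv(qcat, pn[[paste0(prefix, "dw.W")]],
                          pn[[paste0(prefix, "dw.b")]])
  p <- p0
  off <- 0L
  for (k in seq_len(cfg@n)) {
    fk <- agSlice(fall, 2L, off + 1L, off + sch[k])
    off <- off + sch[k]
    if (k > 1L)
      p <- agChannelLinear(p, pn[[paste0(prefix, "g", k - 1L, ".W")]],
                           pn[[paste0(prefix, "g", k - 1L, ".b")]])
    p <- agScale(agMul(fk, p), 1 / sqrt(sch[k]))
    .untcaState$gateMults <- .untcaState$gateMults + 1L
  }
  agChannelLinear(p, pn[[paste0(prefix, "phiOut.W")]],
                  pn[[paste0(prefix, "phiOut.b")]])
}

# Full operator on a node; optionally returns the phi_in intermediates
# (used by the backbone's lowest-level multi-scale bundle).
.gnconvNode <- function(x, cfg, pn, prefix = "", intermediates = FALSE) {
  d <- dim(x$value)
  stopShape(d[2] == cfg@inChannels && d[3] == cfg@inHeight && d[4] == cfg@inWidth,
            sprintf("gnConv config expects input %d x %d x %d, got %d x %d x %d",
                    cfg@inChannels, cfg@inHeight, cfg@inWidth, d[2], d[3], d[4]))
  xg <- .gridReshapeNode(x, cfg@padPolicy)
  pi <- .phiInNode(xg, cfg, pn, prefix)
  out <- .recursiveGateNode(pi$p0, pi$q, cfg, pn, prefix)
  y <- .gridReshapeInvNode(out, d[2], d[3], d[4])
  if (!intermediates) return(y)
  list(out = y, p0 = pi$p0,
       qcat = if (cfg@n > 1L) agConcat(pi$q, 2L) else pi$q[[1]])
}

## ---- public array-level operations ----

.asParamNodes <- function(params) lapply(params, agLeaf)

#' phi_in expansion of gnConv
#'
#' Projects the re-gridded feature to twice its width and splits it into
#' the seed group `p0` and the gating groups `q_0..q_{n-1}`.
#'
#' @param x Re-gridded 4-D array with `cfg@baseChannels` channels.
#' @param cfg A [GnConvConfig-class].
#' @param params Parameter list from [initGnConvParams()].
#' @return List with `p0` (array) and `q` (list of n arrays).
#' @export
phiInProject <- function(x, cfg, params) {
  r <- .phiInNode(agLeaf(x), cfg, .asParamNodes(params))
  list(p0 = r$p0$value, q = lapply(r$q, agVal))
}

#' Recursive gating of gnConv
#'
#' Performs the `n` gating steps `p_{k+1} = f_k(q_k) * g_k(p_k)` followed
#' by the phi_out projection back to the base width.
#'
#' @param p0 Seed array (width `C_0`).
#' @param q List of `n` gating arrays (widths per the schedule).
#' @param cfg A [GnConvConfig-class].
#' @param params Parameter list.
#' @return Array of base width `C`.
#' @export
recursiveGate <- function(p0, q, cfg, params) {
  sch <- cfg@schedule
  stopShape(dim(p0)[2] == sch[1], "p0 width does not match the schedule")
  for (k in seq_along(q))
    stopShape(dim(q[[k]])[2] == sch[k],
              sprintf("q[[%d]] width %d does not match schedule width %d",
                      k, dim(q[[k]])[2], sch[k]))
  .recursiveGateNode(agLeaf(p0), lapply(q, agLeaf), cfg,
                     .asParamNodes(params))$value
}

#' gnConv forward pass
#'
#' Composition: channel-grid reshape, phi_in expansion, recursive gating,
#' phi_out, inverse reshape. Output shape equals input shape.
#'
#' @param x 4-D array (batch, channel, row, col) matching `cfg`.
#' @param cfg A [GnConvConfig-class].
#' @param params Parameter list from [initGnConvParams()].
#' @return Array with the shape of `x`.
#' @export
gnconvForward <- function(x, cfg, params) {
  .gnconvNode(agLeaf(x), cfg, .asParamNodes(params))$value
}
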