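# Transformer block nested with gnConv channel attention.
#
# Token sequences are 3-D arrays (batch, token, feature). The encoder
# enriches the up-sampled feature x_u with self-attention over the
# down-sampled feature x_d and the gnConv-enhanced feature gn(x_u):
#   x_hat_u = x_u + Attention(x_u, x_d, gn(x_u)).
# The decoder updates the transmitted multi-scale feature x_c by
# cross-attention, x_hat_c = x_c + Attention(x_c, x_hat_u, x_d), a
# position-wise FFN refines it, and a convex alpha-fusion mixes it back
# into the up-sampled stream: x_tilde_u = alpha x_u + (1-alpha) x_tilde_c.

#' Configuration of a nested transformer block
#'
#' @slot tokenWidth Per-token feature width d (the d_k of the attention
#'   scaling when a single head is used).
#' @slot ffnHidden Hidden width of the position-wise FFN (2048 by default).
#' @slot dropout Dropout probability applied after attention and inside
#'   the FFN during training (0.1 by default).
#' @slot alpha Convex fusion weight on the up-sampled feature (0.3: the
#'   up-sampled-to-multi-scale ratio 3:7).
#' @slot heads Attention head count (the formulation is single-head).
#' @slot normMode "pre" (layer normalisation before attention/FFN inputs)
#'   or "none".
#' @export
setClass("NestedBlockConfig", representation(
  tokenWidth = "integer", ffnHidden = "integer", dropout = "numeric",
  alpha = "numeric", heads = "integer", normMode = "character"
))

setValidity("NestedBlockConfig", function(object) {
  msgs <- character()
  if (object@dropout < 0 || object@dropout >= 1)
    msgs <- c(msgs, "dropout must lie in [0, 1)")
  if (object@alpha < 0 || object@alpha > 1)
    msgs <- c(msgs, "alpha must lie in [0, 1]")
  if (object@tokenWidth %% object@heads != 0L)
    msgs <- c(msgs, "tokenWidth must be divisible by heads")
  if (!object@normMode %in% c("pre", "none"))
    msgs <- c(msgs, "normMode must be 'pre' or 'none'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a nested transformer block configuration
#'
#' @param tokenWidth Token feature width d.
#' @param ffnHidden FFN hidden width (default 2048).
#' @param dropout Dropout probability (default 0.1).
#' @param alpha Fusion weight on the up-sampled feature (default 0.3).
#' @param heads Attention heads (default 1).
#' @param normMode "pre" (default) or "none".
#' @return A [NestedBlockConfig-class].
#' @export
nestedBlockConfig <- function(tokenWidth, ffnHidden = 2048L, dropout = 0.1,
                              alpha = 0.3, heads = 1L,
                              normMode = c("pre", "none")) {
  new("NestedBlockConfig", tokenWidth = as.integer(tokenWidth),
      ffnHidden = as.integer(ffnHidden), dropout = dropout, alpha = alpha,
      heads = as.integer(heads), normMode = match.arg(normMode))
}

setMethod("show", "NestedBlockConfig", function(object) {
  cat(sprintf(
    "NestedBlockConfig: d = %d, ffn = %d, dropout = %.2f, alpha = %.2f, heads = %d, norm '%s'\n",
    object@tokenWidth, object@ffnHidden, object@dropout, object@alpha,
    object@heads, object@normMode))
})

## ---- core attention ----

.checkTokens <- function(x, what) {
  stopShape(length(dim(x)) == 3L,
            sprintf("%s must be a 3-D (batch, token, feature) array", what))
}

# Plain scaled-dot attention on nodes; Q (N,Tq,dq), K (N,Tk,dq), V (N,Tk,dv).
.attentionNode <- function(Q, K, V, dk) {
  stopShape(dim(K$value)[2] == dim(V$value)[2], sprintf(
    "key and value token counts differ (%d vs %d)",
    dim(K$value)[2], dim(V$value)[2]))
  stopShape(dim(Q$value)[3] == dim(K$value)[3],
            "query and key feature widths differ")
  scores <- agScale(agBatchMatmul(Q, agTranspose23(K)), 1 / sqrt(dk))
  agBatchMatmul(agSoftmaxLast(scores), V)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V` over token sequences. Every output token
#' is a convex combination of value tokens (attention rows sum to one).
#'
#' @param Q,K,V 3-D arrays (batch, token, feature); K and V must share
#'   their token count and Q/K their feature width.
#' @param dk Scaling width; defaults to the feature width of `K`.
#' @return Array shaped like `Q` with the value width of `V`.
#' @export
scaledDotAttention <- function(Q, K, V, dk = dim(K)[3]) {
  .checkTokens(Q, "Q"); .checkTokens(K, "K"); .checkTokens(V, "V")
  .attentionNode(agLeaf(Q), agLeaf(K), agLeaf(V), dk)$value
}

## ---- learned block pieces ----

#' Initialise parameters of a nested transformer block
#'
#' Creates Q/K/V/output projections for the encoder and decoder attention,
#' the FFN weights, and layer-norm affines (when `normMode = "pre"`).
#' @param cfg A [NestedBlockConfig-class].
#' @param seed Integer seed.
#' @param prefix Name prefix.
#' @return Named list of arrays.
#' @export
initNestedBlockParams <- function(cfg, seed = 1L, prefix = "") {
  withSeed(seed, {
    d <- cfg@tokenWidth; h <- cfg@ffnHidden
    p <- list()
    for (blk in c("enc", "dec")) {
      for (w in c("Wq", "Wk", "Wv", "Wo")) {
        p[[paste0(prefix, blk, ".", w)]] <- initArray(c(d, d))
        p[[paste0(prefix, blk, ".", sub("W", "b", w))]] <- numeric(d)
      }
      if (cfg@normMode == "pre") for (s in c("lnQ", "lnK", "lnV")) {
        p[[paste0(prefix, blk, ".", s, ".g")]] <- rep(1, d)
        p[[paste0(prefix, blk, ".", s, ".b")]] <- numeric(d)
      }
    }
    p[[paste0(prefix, "ffn.W1")]] <- initArray(c(h, d))
    p[[paste0(prefix, "ffn.b1")]] <- numeric(h)
    p[[paste0(prefix, "ffn.W2")]] <- initArray(c(d, h))
    p[[paste0(prefix, "ffn.b2")]] <- numeric(d)
    if (cfg@normMode == "pre") {
      p[[paste0(prefix, "ffn.ln.g")]] <- rep(1, d)
      p[[paste0(prefix, "ffn.ln.b")]] <- numeric(d)
    }
    p
  })
}

.maybeNorm <- function(x, cfg, pn, key) {
  if (cfg@normMode != "pre" || is.null(pn[[paste0(key, ".g")]])) return(x)
  agLayerNorm(x, pn[[paste0(key, ".g")]], pn[[paste0(key, ".b")]])
}

# Learned multi-head attention term (non-residual part) for one block
# ("enc" or "dec"). With pn = NULL the raw formula is used (identity
# projections, no norm, no dropout) so analytic oracles apply directly.
.attnTermNode <- function(q, k, v, cfg, pn, prefix, blk, training = FALSE) {
  if (is.null(pn))
    return(.attentionNode(q, k, v, dim(k$value)[3]))
  key <- function(s) paste0(prefix, blk, ".", s)
  qn <- .maybeNorm(q, cfg, pn, key("lnQ"))
  kn <- .maybeNorm(k, cfg, pn, key("lnK"))
  vn <- .maybeNorm(v, cfg, pn, key("lnV"))
  Q <- agTokenLinear(qn, pn[[key("Wq")]], pn[[key("bq")]])
  K <- agTokenLinear(kn, pn[[key("Wk")]], pn[[key("bk")]])
  V <- agTokenLinear(vn, pn[[key("Wv")]], pn[[key("bv")]])
  d <- cfg@tokenWidth; h <- cfg@heads; dh <- d %/% h
  outs <- vector("list", h)
  for (i in seq_len(h)) {
    sel <- function(x) agSlice(x, 3L, (i - 1L) * dh + 1L, i * dh)
    outs[[i]] <- .attentionNode(sel(Q), sel(K), sel(V), dh)
  }
  att <- if (h > 1L) agConcat(outs, 3L) else outs[[1]]
  att <- agTokenLinear(att, pn[[key("Wo")]], pn[[key("bo")]])
  agDropout(att, cfg@dropout, training)
}

.encodeUpsampleNode <- function(xu, xd, g, cfg, pn = NULL, prefix = "",
                                training = FALSE) {
  agAdd(xu, .attnTermNode(xu, xd, g, cfg, pn, prefix, "enc", training))
}

.decodeMultiscaleNode <- function(xc, xhatU, xd, cfg, pn = NULL, prefix = "",
                                  training = FALSE) {
  agAdd(xc, .attnTermNode(xc, xhatU, xd, cfg, pn, prefix, "dec", training))
}

.ffnUpdateNode <- function(x, cfg, pn, prefix = "", training = FALSE) {
  xin <- .maybeNorm(x, cfg, pn, paste0(prefix, "ffn.ln"))
  h <- agRelu(agTokenLinear(xin, pn[[paste0(prefix, "ffn.W1")]],
                            pn[[paste0(prefix, "ffn.b1")]]))
  h <- agDropout(h, cfg@dropout, training)
  out <- agTokenLinear(h, pn[[paste0(prefix, "ffn.W2")]],
                       pn[[paste0(prefix, "ffn.b2")]])
  agAdd(x, agDropout(out, cfg@dropout, training))
}

.fuseAlphaNode <- function(xu, xcTilde, alpha) {
  agAdd(agScale(xu, alpha), agScale(xcTilde, 1 - alpha))
}

## ---- public array-level operations ----

#' Encoder update of the up-sampled feature
#'
#' `x_hat_u = x_u + Attention(x_u, x_d, gn(x_u))`: the up-sampled tokens
#' query the down-sampled tokens, gathering the gnConv-enhanced values.
#'
#' @param xu,xd,g Token sequences (batch, token, feature); `xd` and `g`
#'   must share their token count.
#' @param cfg Optional [NestedBlockConfig-class]; without `params` the raw
#'   single-head formula with identity projections is used.
#' @param params Optional learned parameters from
#'   [initNestedBlockParams()].
#' @return Token sequence shaped like `xu`.
#' @export
encodeUpsample <- function(xu, xd, g, cfg = NULL, params = NULL) {
  .checkTokens(xu, "xu"); .checkTokens(xd, "xd"); .checkTokens(g, "g")
  stopShape(dim(xu)[3] == dim(xd)[3], "xu and xd feature widths differ")
  pn <- if (!is.null(params)) .asParamNodes(params)
  if (is.null(cfg)) cfg <- nestedBlockConfig(dim(xu)[3], dropout = 0)
  .encodeUpsampleNode(agLeaf(xu), agLeaf(xd), agLeaf(g), cfg, pn)$value
}

#' Decoder cross-attention update of the multi-scale feature
#'
#' `x_hat_c = x_c + Attention(x_c, x_hat_u, x_d)`.
#'
#' @param xc,xhatU,xd Token sequences; `xhatU` and `xd` must share their
#'   token count.
#' @inheritParams encodeUpsample
#' @return Token sequence shaped like `xc`.
#' @export
decodeMultiscale <- function(xc, xhatU, xd, cfg = NULL, params = NULL) {
  .checkTokens(xc, "xc"); .checkTokens(xhatU, "xhatU"); .checkTokens(xd, "xd")
  pn <- if (!is.null(params)) .asParamNodes(params)
  if (is.null(cfg)) cfg <- nestedBlockConfig(dim(xc)[3], dropout = 0)
  .decodeMultiscaleNode(agLeaf(xc), agLeaf(xhatU), agLeaf(xd), cfg, pn)$value
}

#' Position-wise feed-forward refinement
#'
#' `x_tilde_c = x_hat_c + max(0, x_hat_c W1 + b1) W2 + b2` (residual
#' two-layer perceptron with a rectifier).
#'
#' @param x Token sequence.
#' @param cfg A [NestedBlockConfig-class] (norm mode "none" applies the
#'   bare formula).
#' @param params Parameter list containing `ffn.W1/b1/W2/b2` (and
#'   `ffn.ln.*` under pre-norm).
#' @return Token sequence shaped like `x`.
#' @export
ffnUpdate <- function(x, cfg, params) {
  .checkTokens(x, "x")
  stopShape(dim(params[["ffn.W1"]])[2] == dim(x)[3],
            "ffn.W1 width does not match the token width")
  .ffnUpdateNode(agLeaf(x), cfg, .asParamNodes(params))$value
}

#' Convex fusion of up-sampled and refined multi-scale features
#'
#' `x_tilde_u = alpha * x_u + (1 - alpha) * x_tilde_c`; elementwise the
#' output lies between the two inputs.
#'
#' @param xu,xcTilde Equal-shaped arrays.
#' @param alpha Fusion weight in \[0, 1\] on the up-sampled feature
#'   (default 0.3, the 3:7 ratio).
#' @return Array shaped like `xu`.
#' @export
fuseAlpha <- function(xu, xcTilde, alpha = 0.3) {
  stopShape(identical(dim(xu), dim(xcTilde)), "shape mismatch in fuseAlpha")
  stopShape(alpha >= 0 && alpha <= 1, "alpha must lie in [0, 1]")
  .fuseAlphaNode(agLeaf(xu), agLeaf(xcTilde), alpha)$value
}
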