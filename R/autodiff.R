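# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Each node is an environment holding the forward value, the parent nodes
# and a closure computing parent gradients from the node's gradient. The
# tape is implicit: node ids increase with creation order, so reverse-id
# order is a valid topological order for backpropagation.

agNode <- function(value, parents = list(), backfn = NULL) {
  # Force promises before taking an id: node ids must increase from
  # parents to children for reverse-id backpropagation order to be valid.
  force(value); force(parents)
  e <- new.env(parent = emptyenv())
  .untcaState$nodeId <- .untcaState$nodeId + 1
  e$id <- .untcaState$nodeId
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  class(e) <- "agNode"
  e
}

agIs <- function(x) inherits(x, "agNode")
agVal <- function(x) if (agIs(x)) x$value else x

# Wrap a plain array as a leaf node (parameters and inputs).
agLeaf <- function(value) agNode(value)

accumGrad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar loss node. Afterwards every reachable leaf
# carries its gradient in $grad.
agBackward <- function(loss) {
  stopifnot(agIs(loss), length(loss$value) == 1L)
  nodes <- list(); seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  while (length(stack)) {
    nd <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  loss$grad <- 1
  for (nd in nodes[ord]) {
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (i in seq_along(nd$parents)) {
      if (!is.null(gs[[i]])) accumGrad(nd$parents[[i]], gs[[i]])
    }
  }
  invisible(NULL)
}

## ---- elementwise ----

agAdd <- function(a, b) {
  agNode(a$value + b$value, list(a, b), function(g) list(g, g))
}

agMul <- function(a, b) {
  av <- a$value; bv <- b$value
  agNode(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

agScale <- function(a, s) {
  agNode(a$value * s, list(a), function(g) list(g * s))
}

agLeakyRelu <- function(a, slope = 0.01) {
  v <- a$value
  m <- slope + (1 - slope) * (v > 0)
  agNode(v * m, list(a), function(g) list(g * m))
}

agRelu <- function(a) {
  v <- a$value
  m <- (v > 0) * 1
  agNode(v * m, list(a), function(g) list(g * m))
}

agDropout <- function(a, p, training = FALSE) {
  if (!training || p <= 0) return(a)
  keep <- array(stats::runif(length(a$value)) >= p, dim = dim(a$value))
  sc <- 1 / (1 - p)
  agNode(a$value * keep * sc, list(a), function(g) list(g * keep * sc))
}

## ---- shape ----

agReshape <- function(a, dims) {
  old <- dim(a$value)
  agNode(array(a$value, dim = dims), list(a),
         function(g) list(array(g, dim = old)))
}

agPermute <- function(a, perm) {
  inv <- order(perm)
  agNode(aperm(a$value, perm), list(a), function(g) list(aperm(g, inv)))
}

# Concatenate nodes along `axis` (arrays of equal rank and matching other dims).
agConcat <- function(xs, axis) {
  vals <- lapply(xs, agVal)
  d0 <- dim(vals[[1]])
  sizes <- vapply(vals, function(v) dim(v)[axis], numeric(1))
  dout <- d0; dout[axis] <- sum(sizes)
  out <- array(0, dim = dout)
  idx <- lapply(dout, seq_len)
  off <- 0L
  for (v in vals) {
    sel <- idx; sel[[axis]] <- off + seq_len(dim(v)[axis])
    out <- do.call(`[<-`, c(list(out), sel, list(v)))
    off <- off + dim(v)[axis]
  }
  agNode(out, xs, function(g) {
    gs <- vector("list", length(xs)); off <- 0L
    for (i in seq_along(xs)) {
      sel <- idx; sel[[axis]] <- off + seq_len(sizes[i])
      gs[[i]] <- do.call(`[`, c(list(g), sel, list(drop = FALSE)))
      off <- off + sizes[i]
    }
    gs
  })
}

agSlice <- function(a, axis, from, to) {
  d <- dim(a$value)
  sel <- lapply(d, seq_len); sel[[axis]] <- from:to
  v <- do.call(`[`, c(list(a$value), sel, list(drop = FALSE)))
  agNode(v, list(a), function(g) {
    gx <- array(0, dim = d)
    gx <- do.call(`[<-`, c(list(gx), sel, list(g)))
    list(gx)
  })
}

## ---- linear algebra ----

agMatmul <- function(A, B) {
  Av <- A$value; Bv <- B$value
  agNode(Av %*% Bv, list(A, B),
         function(g) list(g %*% t(Bv), t(Av) %*% g))
}

# Batched matmul on 3-D arrays (N, a, b) x (N, b, c) -> (N, a, c).
agBatchMatmul <- function(A, B) {
  Av <- A$value; Bv <- B$value
  N <- dim(Av)[1]
  out <- array(0, dim = c(N, dim(Av)[2], dim(Bv)[3]))
  for (n in seq_len(N)) out[n, , ] <-
    array(Av[n, , ], dim = dim(Av)[2:3]) %*% array(Bv[n, , ], dim = dim(Bv)[2:3])
  agNode(out, list(A, B), function(g) {
    gA <- array(0, dim = dim(Av)); gB <- array(0, dim = dim(Bv))
    for (n in seq_len(N)) {
      gn <- array(g[n, , ], dim = dim(g)[2:3])
      gA[n, , ] <- gn %*% t(array(Bv[n, , ], dim = dim(Bv)[2:3]))
      gB[n, , ] <- t(array(Av[n, , ], dim = dim(Av)[2:3])) %*% gn
    }
    list(gA, gB)
  })
}

# Transpose the last two dims of a 3-D array.
agTranspose23 <- function(A) agPermute(A, c(1, 3, 2))

# Apply a (rows x tokenFeat) weight to the feature axis of tokens (N, T, d):
# out[n,t,] = W %*% x[n,t,] + b. W: (dout, d), b: length dout node or NULL.
agTokenLinear <- function(x, W, b = NULL) {
  xv <- x$value; Wv <- W$value
  d <- dim(xv)
  xm <- matrix(aperm(xv, c(3, 1, 2)), nrow = d[3])   # d x (N*T)
  ym <- Wv %*% xm
  if (!is.null(b)) ym <- ym + b$value
  out <- aperm(array(ym, dim = c(nrow(Wv), d[1], d[2])), c(2, 3, 1))
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  agNode(out, parents, function(g) {
    gm <- matrix(aperm(g, c(3, 1, 2)), nrow = nrow(Wv))  # dout x (N*T)
    gx <- aperm(array(t(Wv) %*% gm, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
    gW <- gm %*% t(xm)
    if (is.null(b)) list(gx, gW) else list(gx, gW, rowSums(gm))
  })
}

# Pointwise (1x1) channel mixing on maps (N, C, H, W) via BLAS:
# out[n,,h,w] = W %*% x[n,,h,w] + b. W: (Cout, Cin) matrix.
agChannelLinear <- function(x, W, b = NULL) {
  xv <- x$value; Wv <- W$value
  d <- dim(xv)
  xm <- matrix(aperm(xv, c(2, 1, 3, 4)), nrow = d[2])    # C x (N*H*W)
  ym <- Wv %*% xm
  if (!is.null(b)) ym <- ym + b$value
  out <- aperm(array(ym, dim = c(nrow(Wv), d[1], d[3], d[4])), c(2, 1, 3, 4))
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  agNode(out, parents, function(g) {
    gm <- matrix(aperm(g, c(2, 1, 3, 4)), nrow = nrow(Wv))
    gx <- aperm(array(t(Wv) %*% gm, dim = c(d[2], d[1], d[3], d[4])),
                c(2, 1, 3, 4))
    gW <- gm %*% t(xm)
    if (is.null(b)) list(gx, gW) else list(gx, gW, rowSums(gm))
  })
}

# Map (N, C, H, W) <-> token sequence (N, H*W, C); token index runs down
# columns first (row index fastest), matching R's column-major order.
agMapToTokens <- function(x) {
  d <- dim(x$value)
  agReshape(agPermute(x, c(1, 3, 4, 2)), c(d[1], d[3] * d[4], d[2]))
}

agTokensToMap <- function(x, H, W) {
  d <- dim(x$value)
  agPermute(agReshape(x, c(d[1], H, W, d[3])), c(1, 4, 2, 3))
}

## ---- convolutions ----

# x: (N, C, H, W); W: (Cout, Cin, K, K); b: length Cout. im2col + BLAS;
# the patch matrix is re-gathered in the backward pass rather than cached.
agConv2d <- function(x, W, b, stride = 1L, pad = 1L) {
  xv <- x$value; Wv <- W$value; bv <- b$value
  d <- dim(xv); dw <- dim(Wv)
  stopShape(d[2] == dw[2], sprintf(
    "conv2d: input has %d channels but weight expects %d", d[2], dw[2]))
  stride <- as.integer(stride); pad <- as.integer(pad)
  K <- dw[3]
  Ho <- (d[3] + 2L * pad - K) %/% stride + 1L
  Wo <- (d[4] + 2L * pad - K) %/% stride + 1L
  xcol <- im2col_cpp(xv, d[1], d[2], d[3], d[4], K, stride, pad)
  Wm <- matrix(Wv, nrow = dw[1])                    # Cout x (C*K*K)
  ym <- tcrossprod(xcol, Wm)
  ym <- ym + rep(bv, each = nrow(ym))
  y <- aperm(array(ym, dim = c(d[1], Ho, Wo, dw[1])), c(1, 4, 2, 3))
  agNode(y, list(x, W, b), function(g) {
    gm <- matrix(aperm(g, c(1, 3, 4, 2)), ncol = dw[1])  # (N*Ho*Wo) x Cout
    gW <- array(crossprod(gm, xcol), dim = dw)
    gx <- col2im_cpp(gm %*% Wm, d[1], d[2], d[3], d[4], K, stride, pad)
    list(gx, gW, colSums(gm))
  })
}

# Depthwise conv, stride 1, same padding. W: (C, K, K).
agDepthwiseConv <- function(x, W, b) {
  xv <- x$value; Wv <- W$value
  d <- dim(xv); K <- dim(Wv)[2]
  stopShape(d[2] == dim(Wv)[1], "depthwise conv: channel mismatch")
  y <- dwconv_fwd_cpp(xv, Wv, b$value, d[1], d[2], d[3], d[4], as.integer(K))
  agNode(y, list(x, W, b), function(g) {
    r <- dwconv_bwd_cpp(xv, Wv, g, d[1], d[2], d[3], d[4], as.integer(K))
    list(r$gx, r$gw, r$gb)
  })
}

# Transposed convolution, kernel 2, stride 2 (exact spatial doubling).
# W: (Cin, Cout, 2, 2). Each output pixel receives exactly one input pixel.
agConvTranspose2 <- function(x, W, b) {
  xv <- x$value; Wv <- W$value; bv <- b$value
  d <- dim(xv); Cin <- d[2]; Cout <- dim(Wv)[2]
  stopShape(Cin == dim(Wv)[1], "conv transpose: channel mismatch")
  N <- d[1]; H <- d[3]; Wd <- d[4]
  xm <- matrix(aperm(xv, c(2, 1, 3, 4)), nrow = Cin)   # Cin x (N*H*W)
  out <- array(0, dim = c(N, Cout, 2 * H, 2 * Wd))
  for (dh in 1:2) for (dw in 1:2) {
    Wm <- matrix(Wv[, , dh, dw], nrow = Cin, ncol = Cout)
    ym <- t(Wm) %*% xm + bv                             # Cout x (N*H*W)
    out[, , seq(dh, 2 * H, by = 2), seq(dw, 2 * Wd, by = 2)] <-
      aperm(array(ym, dim = c(Cout, N, H, Wd)), c(2, 1, 3, 4))
  }
  agNode(out, list(x, W, b), function(g) {
    gx <- array(0, dim = d); gW <- array(0, dim = dim(Wv)); gb <- numeric(Cout)
    for (dh in 1:2) for (dw in 1:2) {
      gsub <- g[, , seq(dh, 2 * H, by = 2), seq(dw, 2 * Wd, by = 2), drop = FALSE]
      gm <- matrix(aperm(gsub, c(2, 1, 3, 4)), nrow = Cout)  # Cout x (N*H*W)
      Wm <- matrix(Wv[, , dh, dw], nrow = Cin, ncol = Cout)
      gx <- gx + aperm(array(Wm %*% gm, dim = c(Cin, N, H, Wd)), c(2, 1, 3, 4))
      gW[, , dh, dw] <- xm %*% t(gm)
      gb <- gb + rowSums(gm)
    }
    list(gx, gW, gb)
  })
}

## ---- normalisation ----

# Instance normalisation: per (sample, channel) over the spatial extent,
# with learned per-channel affine (gamma, beta).
agInstanceNorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value; d <- dim(xv)
  N <- d[1]; C <- d[2]; m <- d[3] * d[4]
  xm <- matrix(aperm(xv, c(3, 4, 1, 2)), nrow = m)        # m x (N*C)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = m)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = m)
  gv <- rep(gamma$value, each = N); bv <- rep(beta$value, each = N)
  ym <- xhat * rep(gv, each = m) + rep(bv, each = m)
  y <- aperm(array(ym, dim = c(d[3], d[4], N, C)), c(3, 4, 1, 2))
  agNode(y, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(g, c(3, 4, 1, 2)), nrow = m)
    dgamma <- colSums(matrix(colSums(gm * xhat), nrow = N))
    dbeta <- colSums(matrix(colSums(gm), nrow = N))
    dxhat <- gm * rep(gv, each = m)
    t1 <- dxhat - rep(colMeans(dxhat), each = m)
    t2 <- xhat * rep(colMeans(dxhat * xhat), each = m)
    gxm <- (t1 - t2) * rep(istd, each = m)
    gx <- aperm(array(gxm, dim = c(d[3], d[4], N, C)), c(3, 4, 1, 2))
    list(gx, dgamma, dbeta)
  })
}

# Layer normalisation over the feature (last) axis of tokens (N, T, d).
agLayerNorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value; d <- dim(xv)
  xm <- matrix(aperm(xv, c(3, 1, 2)), nrow = d[3])        # d x (N*T)
  m <- d[3]
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = m)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = m)
  ym <- xhat * gamma$value + beta$value
  y <- aperm(array(ym, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  agNode(y, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(g, c(3, 1, 2)), nrow = d[3])
    dgamma <- rowSums(gm * xhat)
    dbeta <- rowSums(gm)
    dxhat <- gm * gamma$value
    t1 <- dxhat - rep(colMeans(dxhat), each = m)
    t2 <- xhat * rep(colMeans(dxhat * xhat), each = m)
    gxm <- (t1 - t2) * rep(istd, each = m)
    gx <- aperm(array(gxm, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
    list(gx, dgamma, dbeta)
  })
}

## ---- softmax ----

# Softmax over the last axis of a 3-D array (N, Tq, Tk).
agSoftmaxLast <- function(x) {
  xv <- x$value; d <- dim(xv)
  Tk <- d[3]
  xm <- matrix(aperm(xv, c(3, 1, 2)), nrow = Tk)          # Tk x (N*Tq)
  cmx <- xm[max.col(t(xm), ties.method = "first") + Tk * (seq_len(ncol(xm)) - 1L)]
  e <- exp(xm - rep(cmx, each = Tk))
  p <- e * rep(1 / colSums(e), each = Tk)
  y <- aperm(array(p, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  agNode(y, list(x), function(g) {
    gm <- matrix(aperm(g, c(3, 1, 2)), nrow = d[3])
    s <- colSums(gm * p)
    gxm <- p * (gm - rep(s, each = d[3]))
    list(aperm(array(gxm, dim = c(d[3], d[1], d[2])), c(2, 3, 1)))
  })
}

## ---- resampling ----

# Bilinear spatial resampling of (N, C, H, W) to (N, C, H2, W2) as two
# separable linear maps; the backward pass applies the transposes.
agBilinearResize <- function(x, H2, W2) {
  d <- dim(x$value)
  if (d[3] == H2 && d[4] == W2) return(x)
  L <- bilinearMatrix(d[3], H2)
  R <- bilinearMatrix(d[4], W2)
  y <- tensordotDim(tensordotDim(x$value, L, 3L), R, 4L)
  agNode(y, list(x), function(g)
    list(tensordotDim(tensordotDim(g, t(L), 3L), t(R), 4L)))
}

## ---- loss ----

# Combined soft-Dice + cross-entropy segmentation loss on two-class logits.
# logits: (N, 2, H, W) node; mask: (N, H, W) array in {0, 1}.
# Returns list(node, dice, ce) where node is the scalar loss node.
agSegLoss <- function(logits, mask, smooth = 1e-5) {
  zv <- logits$value; d <- dim(zv)
  stopShape(d[2] == 2L, "segmentation loss expects 2-channel logits")
  z0 <- array(zv[, 1, , ], dim = d[c(1, 3, 4)])
  z1 <- array(zv[, 2, , ], dim = d[c(1, 3, 4)])
  zm <- pmax(z0, z1)
  e0 <- exp(z0 - zm); e1 <- exp(z1 - zm)
  p1 <- e1 / (e0 + e1); p0 <- 1 - p1
  M <- length(mask)
  ce <- -sum(mask * log(pmax(p1, 1e-12)) + (1 - mask) * log(pmax(p0, 1e-12))) / M
  S <- sum(p1 * mask); U <- sum(p1) + sum(mask)
  diceSoft <- (2 * S + smooth) / (U + smooth)
  lossVal <- 0.5 * ce + 0.5 * (1 - diceSoft)
  node <- agNode(lossVal, list(logits), function(g) {
    dce1 <- (p1 - mask) / M                       # d(ce)/dz1; dz0 is negative
    ddice_dp1 <- -(2 * mask * (U + smooth) - (2 * S + smooth)) / (U + smooth)^2
    dd1 <- ddice_dp1 * (p1 * p0)
    gz1 <- g * (0.5 * dce1 + 0.5 * dd1)
    gz <- array(0, dim = d)
    gz[, 1, , ] <- -gz1
    gz[, 2, , ] <- gz1
    list(gz)
  })
  list(node = node, dice = diceSoft, ce = ce)
}
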