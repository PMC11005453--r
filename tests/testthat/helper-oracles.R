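# Independent brute-force oracles, coded without reusing the package's
# internal computation paths (explicit loops and base matrix algebra).

# Explicit softmax-matmul attention: loops over batch and query tokens.
oracleAttention <- function(Q, K, V, dk) {
  N <- dim(Q)[1]; Tq <- dim(Q)[2]; Tk <- dim(K)[2]; dv <- dim(V)[3]
  out <- array(0, dim = c(N, Tq, dv))
  for (n in seq_len(N)) for (t in seq_len(Tq)) {
    s <- numeric(Tk)
    for (u in seq_len(Tk)) s[u] <- sum(Q[n, t, ] * K[n, u, ]) / sqrt(dk)
    w <- exp(s - max(s)); w <- w / sum(w)
    for (u in seq_len(Tk)) out[n, t, ] <- out[n, t, ] + w[u] * V[n, u, ]
  }
  out
}

# Hand-coded two-layer perceptron with rectifier, applied per token.
oracleMLP <- function(x, W1, b1, W2, b2) {
  N <- dim(x)[1]; Tn <- dim(x)[2]
  out <- array(0, dim = dim(x))
  for (n in seq_len(N)) for (t in seq_len(Tn)) {
    h <- pmax(0, W1 %*% x[n, t, ] + b1)
    out[n, t, ] <- W2 %*% h + b2
  }
  out
}

# Naive 2-D convolution by explicit shift-and-add over kernel taps.
oracleConv <- function(x, W, b, stride = 1L, pad = 1L) {
  N <- dim(x)[1]; C <- dim(x)[2]; H <- dim(x)[3]; Wd <- dim(x)[4]
  Co <- dim(W)[1]; K <- dim(W)[3]
  Ho <- (H + 2 * pad - K) %/% stride + 1
  Wo <- (Wd + 2 * pad - K) %/% stride + 1
  xp <- array(0, dim = c(N, C, H + 2 * pad, Wd + 2 * pad))
  xp[, , pad + seq_len(H), pad + seq_len(Wd)] <- x
  y <- array(0, dim = c(N, Co, Ho, Wo))
  for (co in seq_len(Co)) {
    acc <- array(b[co], dim = c(N, Ho, Wo))
    for (ci in seq_len(C)) for (kh in seq_len(K)) for (kw in seq_len(K)) {
      rows <- kh + stride * (seq_len(Ho) - 1)
      cols <- kw + stride * (seq_len(Wo) - 1)
      acc <- acc + W[co, ci, kh, kw] *
        array(xp[, ci, rows, cols], dim = c(N, Ho, Wo))
    }
    y[, co, , ] <- acc
  }
  y
}

oracleDepthwise <- function(x, W, b) {
  N <- dim(x)[1]; C <- dim(x)[2]; H <- dim(x)[3]; Wd <- dim(x)[4]
  K <- dim(W)[2]; pad <- (K - 1) %/% 2
  xp <- array(0, dim = c(N, C, H + 2 * pad, Wd + 2 * pad))
  xp[, , pad + seq_len(H), pad + seq_len(Wd)] <- x
  y <- array(0, dim = dim(x))
  for (c in seq_len(C)) {
    acc <- array(b[c], dim = c(N, H, Wd))
    for (kh in seq_len(K)) for (kw in seq_len(K)) {
      acc <- acc + W[c, kh, kw] *
        array(xp[, c, kh + seq_len(H) - 1, kw + seq_len(Wd) - 1],
              dim = c(N, H, Wd))
    }
    y[, c, , ] <- acc
  }
  y
}

oracleInstanceNorm <- function(x, gamma, beta, eps = 1e-5) {
  y <- array(0, dim = dim(x))
  for (n in seq_len(dim(x)[1])) for (c in seq_len(dim(x)[2])) {
    v <- x[n, c, , ]
    z <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + eps)
    y[n, c, , ] <- gamma[c] * z + beta[c]
  }
  y
}

oracleLeaky <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)

# Explicitly unrolled gnConv recursion: channel-grid reshape by index
# loops, phi_in by matrix product, shared depthwise convolution over the
# concatenated gating groups, n gating steps with 1/sqrt(C_k) scaling,
# phi_out, inverse reshape.
oracleGnconv <- function(x, n, params) {
  N <- dim(x)[1]; C0 <- dim(x)[2]; H0 <- dim(x)[3]; W0 <- dim(x)[4]
  s <- ceiling(sqrt(C0))
  # reshape: padded channel c (1-based) sits at grid (gi, gj) with
  # c - 1 = (gi - 1) + s * (gj - 1); new channel m: m - 1 = (h0-1) + H0*(w0-1)
  xg <- array(0, dim = c(N, H0 * W0, s, s))
  for (cc in seq_len(C0)) {
    gi <- (cc - 1) %% s + 1; gj <- (cc - 1) %/% s + 1
    for (h0 in seq_len(H0)) for (w0 in seq_len(W0)) {
      m <- (h0 - 1) + H0 * (w0 - 1) + 1
      xg[, m, gi, gj] <- x[, cc, h0, w0]
    }
  }
  C <- H0 * W0
  sch <- as.integer(C / 2^(n - seq_len(n)))
  # phi_in
  expand <- array(0, dim = c(N, 2 * C, s, s))
  for (n1 in seq_len(N)) for (gi in seq_len(s)) for (gj in seq_len(s))
    expand[n1, , gi, gj] <- params[["phiIn.W"]] %*% xg[n1, , gi, gj] +
      params[["phiIn.b"]]
  p <- expand[, seq_len(sch[1]), , , drop = FALSE]
  qcat <- expand[, -seq_len(sch[1]), , , drop = FALSE]
  f <- oracleDepthwise(qcat, params[["dw.W"]], params[["dw.b"]])
  off <- 0
  for (k in seq_len(n)) {
    fk <- f[, off + seq_len(sch[k]), , , drop = FALSE]
    off <- off + sch[k]
    if (k > 1) {
      pn <- array(0, dim = c(N, sch[k], s, s))
      for (n1 in seq_len(N)) for (gi in seq_len(s)) for (gj in seq_len(s))
        pn[n1, , gi, gj] <- params[[paste0("g", k - 1, ".W")]] %*%
          p[n1, , gi, gj] + params[[paste0("g", k - 1, ".b")]]
      p <- pn
    }
    p <- fk * p / sqrt(sch[k])
  }
  out <- array(0, dim = c(N, C, s, s))
  for (n1 in seq_len(N)) for (gi in seq_len(s)) for (gj in seq_len(s))
    out[n1, , gi, gj] <- params[["phiOut.W"]] %*% p[n1, , gi, gj] +
      params[["phiOut.b"]]
  # inverse reshape
  y <- array(0, dim = dim(x))
  for (cc in seq_len(C0)) {
    gi <- (cc - 1) %% s + 1; gj <- (cc - 1) %/% s + 1
    for (h0 in seq_len(H0)) for (w0 in seq_len(W0)) {
      m <- (h0 - 1) + H0 * (w0 - 1) + 1
      y[, cc, h0, w0] <- out[, m, gi, gj]
    }
  }
  y
}

# Reference plain U-Net forward (nnUNet conventions) sharing the
# backbone's weight naming but built from the naive oracles above.
oracleUNet <- function(params, cfg, x) {
  unit <- function(v, pre, stride = 1L) {
    v <- oracleConv(v, params[[paste0(pre, ".W")]],
                    params[[paste0(pre, ".b")]], stride = stride)
    v <- oracleInstanceNorm(v, params[[paste0(pre, ".g")]],
                            params[[paste0(pre, ".beta")]])
    oracleLeaky(v)
  }
  tunit <- function(v, pre) {
    Wt <- params[[paste0(pre, "t.W")]]; bt <- params[[paste0(pre, "t.b")]]
    N <- dim(v)[1]; Cin <- dim(v)[2]; H <- dim(v)[3]; Wd <- dim(v)[4]
    Cout <- dim(Wt)[2]
    y <- array(0, dim = c(N, Cout, 2 * H, 2 * Wd))
    for (n in seq_len(N)) for (h in seq_len(H)) for (w in seq_len(Wd))
      for (dh in 1:2) for (dw in 1:2)
        y[n, , 2 * (h - 1) + dh, 2 * (w - 1) + dw] <-
          t(matrix(Wt[, , dh, dw], Cin, Cout)) %*% v[n, , h, w] + bt
    y <- oracleInstanceNorm(y, params[[paste0(pre, "t.g")]],
                            params[[paste0(pre, "t.beta")]])
    oracleLeaky(y)
  }
  L <- cfg@depth
  e <- vector("list", L)
  e[[1]] <- unit(unit(x, "stem.c1"), "stem.c2")
  for (l in 2:L)
    e[[l]] <- unit(unit(e[[l - 1]], paste0("down", l, ".c1"), stride = 2L),
                   paste0("down", l, ".c2"))
  prev <- e[[L]]
  for (j in rev(seq_len(L - 1))) {
    u <- unit(tunit(prev, paste0("up", j, ".")), paste0("up", j, ".c1"))
    cat0 <- array(0, dim = c(dim(u)[1], dim(u)[2] + dim(e[[j]])[2],
                             dim(u)[3], dim(u)[4]))
    cat0[, seq_len(dim(u)[2]), , ] <- u
    cat0[, dim(u)[2] + seq_len(dim(e[[j]])[2]), , ] <- e[[j]]
    prev <- unit(unit(cat0, paste0("dec", j, ".c1")), paste0("dec", j, ".c2"))
  }
  # pointwise head + channel softmax
  N <- dim(prev)[1]; H <- dim(prev)[3]; Wd <- dim(prev)[4]
  Wh <- params[["head.W"]]; bh <- params[["head.b"]]
  z <- array(0, dim = c(N, nrow(Wh), H, Wd))
  for (n in seq_len(N)) for (h in seq_len(H)) for (w in seq_len(Wd))
    z[n, , h, w] <- Wh %*% prev[n, , h, w] + bh
  p <- array(0, dim = dim(z))
  for (n in seq_len(N)) for (h in seq_len(H)) for (w in seq_len(Wd)) {
    ez <- exp(z[n, , h, w] - max(z[n, , h, w]))
    p[n, , h, w] <- ez / sum(ez)
  }
  p
}

# Exhaustive pairwise AUC oracle.
oracleAuc <- function(prob, truth) {
  pos <- prob[truth == 1]; neg <- prob[truth == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Central-difference gradient check returning max abs deviation.
fdGradCheck <- function(f, x, eps = 1e-5) {
  r <- f(x)
  untca:::agBackward(r$node)
  g <- r$leaf$grad
  ng <- array(0, dim = dim(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    ng[i] <- (f(xp)$node$value - f(xm)$node$value) / (2 * eps)
  }
  max(abs(g - ng))
}

sumSqNode <- function(y) {
  untca:::agNode(sum(y$value^2), list(y), function(g) list(2 * g * y$value))
}

tinyDataset <- function(n, size = 64L, seed = 11L, nCells = 6L) {
  mix <- untca:::.defaultMix(n)
  generateDataset(n, mix = mix, size = size, seed = seed,
                  nCells = nCells)$samples
}
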