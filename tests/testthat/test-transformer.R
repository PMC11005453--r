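test_that("scaled dot attention matches the explicit softmax-matmul oracle", {
  # hand-fixed small integer matrices: 2 queries x 3 keys
  Q <- array(c(1, 0, 0, 1, 2, -1, 0, 1), c(1, 2, 4))
  K <- array(seq(-1, 1, length.out = 12), c(1, 3, 4))
  V <- array(1:6, c(1, 3, 2))
  got <- scaledDotAttention(Q, K, V, dk = 4)
  expect_lt(max(abs(got - oracleAttention(Q, K, V, 4))), 1e-6)
  # random case
  set.seed(9)
  Q <- array(rnorm(2 * 5 * 6), c(2, 5, 6))
  K <- array(rnorm(2 * 7 * 6), c(2, 7, 6))
  V <- array(rnorm(2 * 7 * 3), c(2, 7, 3))
  expect_lt(max(abs(scaledDotAttention(Q, K, V) -
                    oracleAttention(Q, K, V, 6))), 1e-6)
})

test_that("attention degenerates correctly and its weights are a distribution", {
  # single key/value token: every query returns that value token
  Q <- array(rnorm(1 * 4 * 3), c(1, 4, 3))
  K <- array(rnorm(1 * 1 * 3), c(1, 1, 3))
  V <- array(c(2, -1), c(1, 1, 2))
  out <- scaledDotAttention(Q, K, V)
  for (t in 1:4) expect_equal(out[1, t, ], c(2, -1))
  # all-zero scores: uniform mean of value tokens
  Q0 <- array(0, c(1, 2, 3))
  K2 <- array(rnorm(6), c(1, 2, 3))
  V2 <- array(c(1, 3, 10, 20), c(1, 2, 2))
  out2 <- scaledDotAttention(Q0, K2, V2)
  expect_equal(out2[1, 1, ], c(mean(V2[1, , 1]), mean(V2[1, , 2])))
  # rows sum to one: with V the identity, outputs are the weight rows
  Tk <- 5
  Q <- array(rnorm(1 * 3 * 4), c(1, 3, 4))
  K <- array(rnorm(1 * Tk * 4), c(1, Tk, 4))
  V <- array(0, c(1, Tk, Tk)); V[1, , ] <- diag(Tk)
  w <- scaledDotAttention(Q, K, V)
  expect_equal(apply(w[1, , ], 1, sum), rep(1, 3), tolerance = 1e-6)
  expect_true(all(w >= 0))
  expect_error(scaledDotAttention(Q, K, array(0, c(1, 3, 2))),
               "token counts differ")
})

test_that("encoder update is residual attention over (x_u, x_d, gn(x_u))", {
  set.seed(10)
  xu <- array(rnorm(2 * 4 * 5), c(2, 4, 5))
  xd <- array(rnorm(2 * 6 * 5), c(2, 6, 5))
  g <- array(rnorm(2 * 6 * 5), c(2, 6, 5))
  out <- encodeUpsample(xu, xd, g)
  expect_identical(dim(out), dim(xu))          # query count rules the output
  expect_equal(out, xu + scaledDotAttention(xu, xd, g), tolerance = 1e-12)
  # zero values leave the residual stream untouched
  expect_equal(encodeUpsample(xu, xd, array(0, dim(g))), xu)
})

test_that("decoder cross-attention is residual and (key, value)-permutation equivariant", {
  set.seed(11)
  xc <- array(rnorm(1 * 6 * 16), c(1, 6, 16))
  xhatU <- array(rnorm(1 * 9 * 16), c(1, 9, 16))
  xd <- array(rnorm(1 * 9 * 16), c(1, 9, 16))
  out <- decodeMultiscale(xc, xhatU, xd)
  expect_lt(max(abs(out - (xc + oracleAttention(xc, xhatU, xd, 16)))), 1e-6)
  expect_equal(decodeMultiscale(xc, xhatU, array(0, dim(xd))), xc)
  perm <- sample(9)
  out2 <- decodeMultiscale(xc, xhatU[, perm, , drop = FALSE],
                           xd[, perm, , drop = FALSE])
  expect_equal(out2, out, tolerance = 1e-10)
})

test_that("the FFN is a residual rectified two-layer perceptron", {
  cfg <- nestedBlockConfig(4L, ffnHidden = 8L, dropout = 0, normMode = "none")
  set.seed(12)
  pars <- list("ffn.W1" = matrix(rnorm(32), 8, 4), "ffn.b1" = rnorm(8),
               "ffn.W2" = matrix(rnorm(32), 4, 8), "ffn.b2" = rnorm(4))
  x <- array(rnorm(1 * 2 * 4), c(1, 2, 4))
  out <- ffnUpdate(x, cfg, pars)
  want <- x + oracleMLP(x, pars[["ffn.W1"]], pars[["ffn.b1"]],
                        pars[["ffn.W2"]], pars[["ffn.b2"]])
  expect_lt(max(abs(out - want)), 1e-10)
  # zero weights and biases: identity
  zero <- lapply(pars, function(p) p * 0)
  expect_equal(ffnUpdate(x, cfg, zero), x)
  # saturated rectifier: FFN collapses to the output bias
  sat <- pars; sat[["ffn.b1"]][] <- -1e6
  want <- x + rep(pars[["ffn.b2"]], each = 2)  # b2 broadcast over tokens
  out <- ffnUpdate(x, cfg, sat)
  for (t in 1:2) expect_equal(out[1, t, ], x[1, t, ] + pars[["ffn.b2"]])
})

test_that("alpha fusion is an elementwise convex combination", {
  xu <- array(1, c(1, 3, 2)); xc <- array(0, c(1, 3, 2))
  expect_equal(fuseAlpha(xu, xc, 0.3), array(0.3, c(1, 3, 2)))  # the 3:7 ratio
  expect_equal(fuseAlpha(xu, xc, 1), xu)
  v <- array(rnorm(6), c(1, 3, 2))
  for (a in c(0, 0.3, 0.7, 1)) expect_equal(fuseAlpha(v, v, a), v)
  # bounds property over random draws
  set.seed(13)
  for (rep in 1:10) {
    a <- runif(1)
    x1 <- array(rnorm(24), c(2, 3, 4)); x2 <- array(rnorm(24), c(2, 3, 4))
    f <- fuseAlpha(x1, x2, a)
    expect_true(all(f >= pmin(x1, x2) - 1e-12 & f <= pmax(x1, x2) + 1e-12))
  }
  expect_error(fuseAlpha(xu, array(0, c(1, 2, 2))), "shape mismatch")
  expect_error(fuseAlpha(xu, xc, 1.2), "alpha")
})

test_that("learned blocks respect configuration invariants", {
  expect_error(nestedBlockConfig(6L, heads = 4L), "divisible")
  expect_error(nestedBlockConfig(8L, dropout = 1), "dropout")
  expect_error(nestedBlockConfig(8L, alpha = 2), "alpha")
  cfg <- nestedBlockConfig(8L, ffnHidden = 16L, dropout = 0.1, heads = 2L)
  pars <- initNestedBlockParams(cfg, seed = 4)
  xu <- array(rnorm(1 * 5 * 8), c(1, 5, 8))
  xd <- array(rnorm(1 * 5 * 8), c(1, 5, 8))
  # evaluation mode is deterministic despite configured dropout
  o1 <- encodeUpsample(xu, xd, xd, cfg, pars)
  o2 <- encodeUpsample(xu, xd, xd, cfg, pars)
  expect_identical(o1, o2)
  expect_identical(dim(o1), dim(xu))
})
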