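# Finite-difference checks of the hand-derived backward passes, plus
# value checks of the fused segmentation loss.

test_that("convolution backward passes agree with central differences", {
  set.seed(61)
  x <- array(rnorm(1 * 2 * 5 * 5), c(1, 2, 5, 5))
  W <- array(rnorm(3 * 2 * 3 * 3) * 0.3, c(3, 2, 3, 3)); b <- rnorm(3)
  agLeaf <- untca:::agLeaf
  for (stride in c(1L, 2L)) {
    f <- function(xx) {
      l <- agLeaf(xx)
      list(node = sumSqNode(untca:::agConv2d(l, agLeaf(W), agLeaf(b),
                                             stride, 1L)), leaf = l)
    }
    expect_lt(fdGradCheck(f, x), 1e-6)
  }
  # forward value against the shift-and-add oracle
  y <- untca:::agConv2d(agLeaf(x), agLeaf(W), agLeaf(b), 1L, 1L)$value
  expect_lt(max(abs(y - oracleConv(x, W, b))), 1e-10)
  Wd <- array(rnorm(2 * 3 * 3) * 0.3, c(2, 3, 3)); bd <- rnorm(2)
  fdw <- function(xx) {
    l <- agLeaf(xx)
    list(node = sumSqNode(untca:::agDepthwiseConv(l, agLeaf(Wd), agLeaf(bd))),
         leaf = l)
  }
  expect_lt(fdGradCheck(fdw, x), 1e-6)
  expect_lt(max(abs(untca:::agDepthwiseConv(agLeaf(x), agLeaf(Wd),
                                            agLeaf(bd))$value -
                    oracleDepthwise(x, Wd, bd))), 1e-10)
  Wt <- array(rnorm(2 * 3 * 2 * 2) * 0.3, c(2, 3, 2, 2)); bt <- rnorm(3)
  ft <- function(xx) {
    l <- agLeaf(xx)
    list(node = sumSqNode(untca:::agConvTranspose2(l, agLeaf(Wt), agLeaf(bt))),
         leaf = l)
  }
  expect_lt(fdGradCheck(ft, x), 1e-6)
})

test_that("normalisation and attention backward passes agree with central differences", {
  set.seed(62)
  agLeaf <- untca:::agLeaf
  x <- array(rnorm(2 * 2 * 4 * 4), c(2, 2, 4, 4))
  g2 <- rnorm(2); b2 <- rnorm(2)
  fin <- function(xx) {
    l <- agLeaf(xx)
    list(node = sumSqNode(untca:::agInstanceNorm(l, agLeaf(g2), agLeaf(b2))),
         leaf = l)
  }
  expect_lt(fdGradCheck(fin, x), 1e-5)
  xt <- array(rnorm(2 * 4 * 6), c(2, 4, 6))
  gl <- rnorm(6); bl <- rnorm(6)
  fln <- function(xx) {
    l <- agLeaf(xx)
    list(node = sumSqNode(untca:::agLayerNorm(l, agLeaf(gl), agLeaf(bl))),
         leaf = l)
  }
  expect_lt(fdGradCheck(fln, xt), 1e-5)
  fat <- function(xx) {
    l <- agLeaf(xx)
    list(node = sumSqNode(untca:::.attentionNode(l, l, l, 6)), leaf = l)
  }
  expect_lt(fdGradCheck(fat, xt), 1e-5)
})

test_that("the fused soft-Dice + cross-entropy loss and gradient are correct", {
  set.seed(63)
  z <- array(rnorm(2 * 2 * 4 * 4), c(2, 2, 4, 4))
  mask <- array(rbinom(32, 1, 0.4), c(2, 4, 4))
  r <- untca:::agSegLoss(untca:::agLeaf(z), mask)
  # value: recompute from definitions
  p1 <- exp(z[, 2, , ]) / (exp(z[, 1, , ]) + exp(z[, 2, , ]))
  ce <- -mean(mask * log(p1) + (1 - mask) * log(1 - p1))
  dice <- (2 * sum(p1 * mask) + 1e-5) / (sum(p1) + sum(mask) + 1e-5)
  expect_equal(r$node$value, 0.5 * ce + 0.5 * (1 - dice), tolerance = 1e-10)
  expect_equal(r$ce, ce, tolerance = 1e-10)
  f <- function(zz) {
    l <- untca:::agLeaf(zz)
    list(node = untca:::agSegLoss(l, mask)$node, leaf = l)
  }
  expect_lt(fdGradCheck(f, z), 1e-8)
})

test_that("bilinear token-grid resampling is exact on constants and differentiable", {
  x <- array(1, c(1, 2, 6, 6))
  y <- untca:::agBilinearResize(untca:::agLeaf(x), 4L, 9L)
  expect_identical(dim(y$value), c(1L, 2L, 4L, 9L))
  expect_lt(max(abs(y$value - 1)), 1e-12)              # partition of unity
  set.seed(64)
  x2 <- array(rnorm(1 * 2 * 5 * 4), c(1, 2, 5, 4))
  f <- function(xx) {
    l <- untca:::agLeaf(xx)
    list(node = sumSqNode(untca:::agBilinearResize(l, 7L, 3L)), leaf = l)
  }
  expect_lt(fdGradCheck(f, x2), 1e-6)
})
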