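test_that("channel schedule follows the halving rule and doubles to C", {
  expect_identical(channelSchedule(484, 3), c(121L, 242L, 484L))
  expect_identical(channelSchedule(8, 1), 8L)
  sch <- channelSchedule(16, 3)
  expect_identical(sch, c(4L, 8L, 16L))
  expect_equal(sch[1] + sum(sch), 2 * 16)    # phi_in "two times" expansion
  expect_error(channelSchedule(10, 3), "divisible")
  expect_error(channelSchedule(8, 0), "n must be")
})

test_that("phi_in width expansion and geometric-series identity hold for n = 1..5", {
  for (n in 1:5) {
    C <- 3L * 2L^(n - 1L)
    sch <- channelSchedule(C, n)
    expect_length(sch, n)
    expect_equal(sch[n], C)
    expect_equal(sch[1] + sum(sch), 2 * C)
    if (n > 1) expect_true(all(diff(log2(sch)) == 1))
  }
})

test_that("channel-grid reshape grids channels on a square and inverts exactly", {
  x <- array(rnorm(2 * 9 * 4 * 4), c(2, 9, 4, 4))
  y <- channelGridReshape(x)
  expect_identical(dim(y), c(2L, 16L, 3L, 3L))       # 9 = 3^2, C = 4*4
  expect_identical(inverseChannelGridReshape(y), x)  # exact bijection
  # padded case: 8 channels pad to 9
  x2 <- array(rnorm(1 * 8 * 4 * 4), c(1, 8, 4, 4))
  y2 <- channelGridReshape(x2)
  expect_identical(dim(y2), c(1L, 16L, 3L, 3L))
  expect_identical(inverseChannelGridReshape(y2), x2)
  expect_error(channelGridReshape(x2, padPolicy = "strict"), "perfect square")
  # the printed pairing: 484 channels <-> 22 x 22 grid
  x3 <- array(0, c(1, 484, 2, 2))
  expect_identical(dim(channelGridReshape(x3))[3:4], c(22L, 22L))
})

test_that("phi_in splits the doubled width along the schedule", {
  cfg <- gnConvConfig(3L, inChannels = 16L, inHeight = 4L, inWidth = 4L)
  expect_equal(cfg@baseChannels, 16L)
  pars <- initGnConvParams(cfg, seed = 3)
  x <- array(rnorm(2 * 16 * 4 * 4), c(2, 16, 4, 4))  # re-gridded input
  r <- phiInProject(x, cfg, pars)
  expect_equal(dim(r$p0)[2], 4L)
  expect_equal(vapply(r$q, function(q) dim(q)[2], integer(1)), c(4L, 8L, 16L))
  total <- dim(r$p0)[2] + sum(vapply(r$q, function(q) dim(q)[2], integer(1)))
  expect_equal(total, 2L * 16L)
  # zero input with zero bias -> all outputs zero (linearity)
  r0 <- phiInProject(array(0, dim(x)), cfg, pars)
  expect_true(all(r0$p0 == 0) && all(unlist(r0$q) == 0))
})

test_that("recursive gate reduces to a single gated convolution at n = 1", {
  cfg <- gnConvConfig(1L, inChannels = 16L, inHeight = 2L, inWidth = 2L)
  pars <- initGnConvParams(cfg, seed = 5)
  C <- cfg@baseChannels
  p0 <- array(rnorm(1 * C * 4 * 4), c(1, C, 4, 4))
  q0 <- array(rnorm(1 * C * 4 * 4), c(1, C, 4, 4))
  out <- recursiveGate(p0, list(q0), cfg, pars)
  f <- oracleDepthwise(q0, pars[["dw.W"]], pars[["dw.b"]])
  manual <- f * p0 / sqrt(C)
  expected <- array(0, dim(manual))
  for (gi in 1:4) for (gj in 1:4)
    expected[1, , gi, gj] <- pars[["phiOut.W"]] %*% manual[1, , gi, gj] +
      pars[["phiOut.b"]]
  expect_equal(out, expected, tolerance = 1e-10)
})

test_that("forcing unit gates and identity projections broadcasts p0", {
  cfg <- gnConvConfig(1L, inChannels = 16L, inHeight = 2L, inWidth = 2L)
  pars <- initGnConvParams(cfg, seed = 5)
  C <- cfg@baseChannels
  pars[["dw.W"]][] <- 0; pars[["dw.b"]][] <- 1          # f(q) = 1 everywhere
  pars[["phiOut.W"]] <- diag(C); pars[["phiOut.b"]][] <- 0
  p0 <- array(rnorm(2 * C * 3 * 3), c(2, C, 3, 3))
  q0 <- array(rnorm(2 * C * 3 * 3), c(2, C, 3, 3))
  out <- recursiveGate(p0, list(q0), cfg, pars)
  expect_equal(out, p0 / sqrt(C), tolerance = 1e-12)
})

test_that("gnConv forward preserves shape, is deterministic, composes, and counts n gates", {
  cfg <- gnConvConfig(3L, inChannels = 484L, inHeight = 6L, inWidth = 6L)
  pars <- initGnConvParams(cfg, seed = 7)
  x <- array(rnorm(2 * 484 * 6 * 6), c(2, 484, 6, 6))
  resetGateMultCount()
  y1 <- gnconvForward(x, cfg, pars)
  expect_identical(gateMultCount(), 3L)                # exactly n gate products
  expect_identical(dim(y1), dim(x))
  y2 <- gnconvForward(x, cfg, pars)
  expect_identical(y1, y2)                              # bitwise determinism
  # composition of the exposed pieces equals the fused forward
  xg <- channelGridReshape(x)
  pieces <- phiInProject(xg, cfg, pars)
  gated <- recursiveGate(pieces$p0, pieces$q, cfg, pars)
  attr(gated, "origChannels") <- 484L
  attr(gated, "origHeight") <- 6L; attr(gated, "origWidth") <- 6L
  expect_equal(inverseChannelGridReshape(gated), y1, tolerance = 1e-12)
})

test_that("gnConv forward matches the explicitly unrolled recursion", {
  set.seed(42)
  worst <- 0
  for (rep in 1:20) {
    n <- sample(1:3, 1)
    H0 <- sample(2:4, 1); W0 <- sample(2:4, 1)
    C <- H0 * W0
    if (C %% 2^(n - 1) != 0) n <- 1
    C0 <- sample(c(4L, 8L, 9L), 1)
    cfg <- gnConvConfig(n, inChannels = C0, inHeight = H0, inWidth = W0)
    pars <- initGnConvParams(cfg, seed = rep)
    x <- array(rnorm(2 * C0 * H0 * W0), c(2, C0, H0, W0))
    got <- gnconvForward(x, cfg, pars)
    pp <- pars; names(pp) <- names(pars)
    want <- oracleGnconv(x, n, pp)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-5)
})

test_that("mismatched widths raise configuration errors", {
  cfg <- gnConvConfig(3L, inChannels = 16L, inHeight = 4L, inWidth = 4L)
  pars <- initGnConvParams(cfg)
  bad <- array(0, c(1, 5, 4, 4))
  expect_error(phiInProject(bad, cfg, pars), "channels")
  expect_error(gnconvForward(bad, cfg, pars), "expects input")
  p0 <- array(0, c(1, 3, 4, 4))
  expect_error(recursiveGate(p0, list(p0, p0, p0), cfg, pars), "schedule")
})
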