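smallCfg <- function(...) reducedConfig(tokenGrid = 8L, tokenWidths = c(16L, 16L),
                                        ffnHidden = 32L, ...)

test_that("conv stages halve and double the spatial extent with leaky activations", {
  x <- array(rnorm(1 * 4 * 64 * 64), c(1, 4, 64, 64))
  down <- convStage(x, 8L, "down", seed = 2)
  expect_identical(dim(down), c(1L, 8L, 32L, 32L))
  up <- convStage(down, 4L, "up", seed = 3)
  expect_identical(dim(up), c(1L, 4L, 64L, 64L))      # shape round trip
  # leaky ReLU scales negatives instead of zeroing them
  expect_true(min(down) < 0)
  expect_error(convStage(array(0, c(1, 2, 5, 5)), 4L, "down"), "even")
})

test_that("aggregate_H concatenates or averages token-grid-aligned parts", {
  set.seed(4)
  a <- array(rnorm(1 * 16 * 3), c(1, 16, 3))
  # identical parts, concatenation, identity projection: parts stacked
  out <- aggregateH(list(a, a), "concatenation", targetWidth = 6L)
  expect_identical(dim(out), c(1L, 16L, 6L))
  expect_equal(out[, , 1:3], a[, , , drop = TRUE], ignore_attr = TRUE)
  expect_equal(out[, , 4:6], a[, , , drop = TRUE], ignore_attr = TRUE)
  # interpolation on a shared grid with equal weights: elementwise mean
  b <- array(rnorm(1 * 16 * 3), c(1, 16, 3))
  mid <- aggregateH(list(a, b), "interpolation", targetWidth = 3L)
  expect_equal(mid, (a + b) / 2, tolerance = 1e-12)
  # four parts of widths 4, 4, 8, 16 concatenate to width 32 pre-projection
  parts <- lapply(c(4, 4, 8, 16), function(w) array(rnorm(9 * w), c(1, 9, w)))
  cat4 <- aggregateH(parts, "concatenation", targetWidth = 32L)
  expect_identical(dim(cat4)[3], 32L)
  expect_error(aggregateH(list(a), "concatenation", 3L), "two parts")
})

test_that("forward output matches input size with per-pixel probability simplex", {
  cfg <- smallCfg()
  m <- buildModel(cfg, seed = 1)
  x <- array(runif(1 * 1 * 64 * 64), c(1, 1, 64, 64))
  p <- untcaForward(m, x)
  expect_identical(dim(p), c(1L, 2L, 64L, 64L))
  expect_lt(max(abs(apply(p, c(1, 3, 4), sum) - 1)), 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  # evaluation passes are bitwise identical
  expect_identical(p, untcaForward(m, x))
  # indivisible size names the minimal valid size
  expect_error(untcaForward(m, array(0, c(1, 1, 30, 30))), "minimal valid size")
})

test_that("recursive transmission produces depth-1 four-part bundles bottom-up", {
  x <- array(runif(1 * 1 * 64 * 64), c(1, 1, 64, 64))
  m <- buildModel(smallCfg(), seed = 1)
  r <- recursiveTransmit(m, x)
  expect_identical(r$blockCalls, 2L)
  expect_length(r$bundles, 2L)                        # depth - 1 bundles
  expect_identical(r$bundleArity, c(4L, 4L))          # H takes four parts
  # depth 2: exactly one nested block invocation and one bundle
  cfg2 <- backboneConfig(depth = 2L, widths = c(8L, 16L), tokenWidths = 16L,
                         tokenGrid = 8L, ffnHidden = 32L)
  m2 <- buildModel(cfg2, seed = 1)
  r2 <- recursiveTransmit(m2, array(runif(32 * 32), c(1, 1, 32, 32)))
  expect_identical(r2$blockCalls, 1L)
  expect_length(r2$bundles, 1L)
})

test_that("with both attention modules disabled the network is a plain U-Net", {
  cfg <- smallCfg(useGnconv = FALSE, useTransformer = FALSE)
  m <- buildModel(cfg, seed = 6)
  x <- array(runif(1 * 1 * 32 * 32), c(1, 1, 32, 32))
  got <- untcaForward(m, x)
  want <- oracleUNet(m@params, cfg, x)
  expect_lt(max(abs(got - want)), 1e-5)
})

test_that("parameter sets are a pure function of configuration and seed", {
  cfg <- smallCfg()
  m1 <- buildModel(cfg, seed = 3); m2 <- buildModel(cfg, seed = 3)
  expect_identical(m1@params, m2@params)
  expect_identical(parameterCount(m1), parameterCount(m2))
  m3 <- buildModel(cfg, seed = 4)
  expect_identical(parameterCount(m1), parameterCount(m3))
  expect_false(identical(m1@params, m3@params))
  # ablation flags change the parameter inventory
  expect_lt(parameterCount(buildModel(smallCfg(useTransformer = FALSE,
                                               useGnconv = FALSE), 1)),
            parameterCount(m1))
})

test_that("every parameter group receives gradient from the segmentation loss", {
  cfg <- smallCfg()
  m <- buildModel(cfg, seed = 2)
  set.seed(5)
  x <- array(runif(2 * 1 * 32 * 32), c(2, 1, 32, 32))
  y <- array(rbinom(2 * 32 * 32, 1, 0.3), c(2, 32, 32))
  pn <- lapply(m@params, untca:::agLeaf)
  out <- untca:::.forwardNode(pn, untca:::agLeaf(x), cfg, training = FALSE)
  loss <- untca:::agSegLoss(out$logits, y)
  untca:::agBackward(loss$node)
  gnorm <- vapply(pn, function(n)
    if (is.null(n$grad)) 0 else sum(abs(n$grad)), numeric(1))
  dead <- names(gnorm)[gnorm == 0]
  expect_identical(dead, character(0))
})

test_that("both encoding strategies and single ablations run end to end", {
  x <- array(runif(1 * 1 * 32 * 32), c(1, 1, 32, 32))
  for (cfg in list(smallCfg(encodingStrategy = "interpolation"),
                   smallCfg(useGnconv = FALSE),
                   smallCfg(useTransformer = FALSE),
                   smallCfg(normMode = "none"),
                   smallCfg(heads = 2L))) {
    p <- untcaForward(buildModel(cfg, seed = 1), x)
    expect_identical(dim(p), c(1L, 2L, 32L, 32L))
    expect_true(all(is.finite(p)))
  }
})
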