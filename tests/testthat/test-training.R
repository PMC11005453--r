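test_that("augmentation preserves registration, binarity and known invariances", {
  s <- tinyDataset(1, size = 32, seed = 31, nCells = 3)[[1]]
  off <- c(rotate = FALSE, contrast = FALSE, noise = FALSE,
           translate = FALSE, flip = FALSE)
  expect_identical(augmentSample(s, off), s)           # all-false: identity
  # horizontal flip applied twice restores the original
  flipped <- s$image[, rev(seq_len(ncol(s$image)))]
  expect_identical(flipped[, rev(seq_len(ncol(flipped)))], s$image)
  # quarter-turn rotation preserves the foreground pixel count
  r <- untca:::.rot90(s$mask)
  expect_identical(sum(r), sum(s$mask))
  expect_identical(untca:::.rot90(untca:::.rot90(untca:::.rot90(untca:::.rot90(s$mask)))),
                   s$mask)
  # property: any augmentation keeps the mask binary and sizes matched
  set.seed(32)
  for (r in 1:15) {
    a <- augmentSample(s)
    expect_true(all(a$mask %in% c(0, 1)))
    expect_identical(dim(a$image), dim(a$mask))
    expect_true(all(a$image >= 0 & a$image <= 1))
  }
  # geometric-only augmentation preserves foreground area
  geo <- c(rotate = TRUE, contrast = FALSE, noise = FALSE,
           translate = FALSE, flip = TRUE)
  for (r in 1:10) {
    a <- augmentSample(s, geo)
    expect_identical(sum(a$mask), sum(s$mask))
  }
})

test_that("k-fold splits are disjoint covering partitions with balanced sizes", {
  f <- kfoldSplit(10, 5, seed = 1)
  expect_true(all(vapply(f, function(x) length(x$val), integer(1)) == 2L))
  f96 <- kfoldSplit(96, 5, seed = 2)
  sizes <- sort(vapply(f96, function(x) length(x$val), integer(1)))
  expect_identical(sizes, c(19L, 19L, 19L, 19L, 20L))
  allVal <- sort(unlist(lapply(f96, `[[`, "val")))
  expect_identical(allVal, 1:96)                       # cover, no duplicates
  for (x in f96) {
    expect_length(intersect(x$train, x$val), 0L)
    expect_identical(sort(c(x$train, x$val)), 1:96)
  }
  # the 8:2 ratio at k = 5
  expect_equal(length(f96[[1]]$train) / 96, 0.8, tolerance = 0.02)
  expect_error(kfoldSplit(3, 5), "folds")
  expect_identical(kfoldSplit(12, 4, seed = 9), kfoldSplit(12, 4, seed = 9))
})

test_that("two training steps checkpoint and reload to an identical model", {
  ds <- tinyDataset(2, size = 32, seed = 33, nCells = 3)
  cfg <- reducedConfig(tokenGrid = 8L, tokenWidths = c(16L, 16L),
                       ffnHidden = 32L)
  tc <- trainConfig(steps = 2L, batchSize = 1L, seed = 7L, evalEvery = 10L)
  ck <- tempfile(fileext = ".rds")
  fit <- trainModel(ds, cfg, tc, checkpointPath = ck)
  expect_true(file.exists(ck))
  expect_true(all(is.finite(fit$history$loss)))
  reloaded <- loadCheckpoint(ck)
  x <- ds[[1]]$image
  expect_identical(untcaForward(reloaded$model, x), untcaForward(fit$model, x))
  expect_identical(reloaded$seed, 7L)
})

test_that("a fixed seed reproduces the loss curve bit for bit", {
  ds <- tinyDataset(2, size = 32, seed = 34, nCells = 3)
  cfg <- reducedConfig(tokenGrid = 8L, tokenWidths = c(16L, 16L),
                       ffnHidden = 32L)
  tc <- trainConfig(steps = 3L, batchSize = 2L, seed = 99L, evalEvery = 10L)
  f1 <- trainModel(ds, cfg, tc)
  f2 <- trainModel(ds, cfg, tc)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$model@params, f2$model@params)
})
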