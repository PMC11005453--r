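test_that("Dice matches its closed form and conventions", {
  a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(0, 0, 1, 1), 2)
  expect_equal(diceScore(a, a), 1)
  expect_equal(diceScore(a, b), 0)
  # |A| = |B| = 4 with overlap 2 -> 0.5
  A <- matrix(0, 3, 3); A[1:4] <- 1
  B <- matrix(0, 3, 3); B[3:6] <- 1
  expect_equal(diceScore(A, B), 0.5)
  z <- matrix(0, 2, 2)
  expect_equal(diceScore(z, z), 1)               # both empty
  expect_error(diceScore(A, matrix(0, 2, 2)), "shapes")
  # symmetry over random masks
  set.seed(21)
  for (r in 1:10) {
    x <- matrix(rbinom(36, 1, 0.4), 6); y <- matrix(rbinom(36, 1, 0.4), 6)
    expect_equal(diceScore(x, y), diceScore(y, x))
  }
})

test_that("confusion metrics count pixels with the stated degenerate conventions", {
  pred <- matrix(c(1, 1, 0, 0), 2); truth <- matrix(c(1, 0, 0, 0), 2)
  cm <- confusionMetrics(pred, truth)   # TP=1 FP=1 FN=0 TN=2
  expect_equal(cm[["acc"]], 0.75)
  expect_equal(cm[["recall"]], 1)
  expect_equal(cm[["precision"]], 0.5)
  perfect <- confusionMetrics(truth, truth)
  expect_equal(unname(perfect), c(1, 1, 1))
  # all-background prediction on non-empty truth: recall 0
  expect_equal(confusionMetrics(matrix(0, 2, 2), truth)[["recall"]], 0)
  # empty truth and empty prediction: vacuously perfect
  z <- matrix(0, 2, 2)
  expect_equal(unname(confusionMetrics(z, z)), c(1, 1, 1))
  expect_equal(confusionMetrics(pred, z)[["recall"]], 0)
})

test_that("AUC equals the exhaustive pairwise Mann-Whitney statistic", {
  truth <- matrix(c(1, 1, 1, 0, 0, 0), 2, 3)
  hi <- matrix(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), 2, 3)
  expect_equal(rocAuc(hi, truth), 1)
  expect_equal(rocAuc(matrix(0.5, 2, 3), truth), 0.5)  # all ties
  set.seed(22)
  for (r in 1:10) {
    p <- matrix(round(runif(6), 2), 2, 3)
    t6 <- matrix(rbinom(6, 1, 0.5), 2, 3)
    if (sum(t6) %in% c(0, 6)) next
    expect_equal(rocAuc(p, t6), oracleAuc(p, t6))
    # invariance under a strictly monotone transform
    expect_equal(rocAuc(plogis(5 * p - 2), t6), rocAuc(p, t6))
  }
  expect_true(is.na(rocAuc(hi, matrix(1, 2, 3))))      # single-class mask
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(23)
  p <- matrix(runif(100), 10)
  t10 <- matrix(rbinom(100, 1, 0.35), 10)
  got <- rocAuc(p, t10)
  ref <- as.numeric(pROC::auc(pROC::roc(as.vector(t10), as.vector(p),
                                        quiet = TRUE, direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("stratified reports aggregate per tag in percent, macro and micro", {
  set.seed(24)
  probs <- lapply(1:4, function(i) matrix(runif(64), 8))
  truths <- lapply(1:4, function(i) matrix(rbinom(64, 1, 0.3), 8))
  tags <- c("clear", "clear", "occluded", "blurred")
  rep <- evaluateSegmentation(probs, truths, tags)
  expect_s4_class(rep, "MetricReport")
  expect_identical(nrow(rep@perImage), 4L)
  expect_setequal(rep@aggregate$tag, c("clear", "occluded", "blurred", "all"))
  allRow <- rep@aggregate[rep@aggregate$tag == "all", ]
  expect_equal(allRow$dice, mean(rep@perImage$dice))    # macro = mean
  expect_true(all(rep@aggregate$dice >= 0 & rep@aggregate$dice <= 100))
  micro <- evaluateSegmentation(probs, truths, tags, mode = "micro")
  pooledPred <- unlist(lapply(probs, function(p) (p > 0.5) * 1))
  pooledTruth <- unlist(truths)
  expect_equal(micro@aggregate$dice[micro@aggregate$tag == "all"],
               100 * diceScore(array(pooledPred, dim = length(pooledPred)),
                               array(pooledTruth, dim = length(pooledTruth))))
  # serialisation twins
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  writeMetricReport(rep, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(back$dice, rep@aggregate$dice, tolerance = 1e-9)
  expect_true(jsonlite::validate(readLines(js, warn = FALSE)))
})
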