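# Pixel-level segmentation metrics: Dice, accuracy, recall, precision and
# ROC-AUC, with per-image and stratified aggregate reporting.

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two binary masks; defined as 1 when
#' both masks are empty.
#'
#' @param pred,truth Equal-shaped binary (0/1) arrays.
#' @return Dice in \[0, 1\].
#' @export
diceScore <- function(pred, truth) {
  stopShape(all(dim(pred) == dim(truth)), "mask shapes differ")
  stopShape(all(pred %in% c(0, 1)) && all(truth %in% c(0, 1)),
            "masks must be binary 0/1")
  a <- sum(pred); b <- sum(truth)
  if (a + b == 0) return(1)
  2 * sum(pred * truth) / (a + b)
}

#' Accuracy, recall and precision from binary masks
#'
#' Acc = (TP+TN)/N, recall = TP/(TP+FN), precision = TP/(TP+FP). A ratio
#' with zero denominator is reported as 1 when the corresponding other
#' pixel set is also empty (a vacuously perfect prediction), else 0.
#'
#' @param pred,truth Equal-shaped binary arrays.
#' @return Named numeric vector `c(acc, recall, precision)`.
#' @export
confusionMetrics <- function(pred, truth) {
  stopShape(all(dim(pred) == dim(truth)), "mask shapes differ")
  stopShape(all(pred %in% c(0, 1)) && all(truth %in% c(0, 1)),
            "masks must be binary 0/1")
  tp <- sum(pred * truth)
  fp <- sum(pred * (1 - truth))
  fn <- sum((1 - pred) * truth)
  tn <- sum((1 - pred) * (1 - truth))
  acc <- (tp + tn) / (tp + tn + fp + fn)
  recall <- if (tp + fn > 0) tp / (tp + fn) else as.numeric(tp + fp == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else as.numeric(tp + fn == 0)
  c(acc = acc, recall = recall, precision = precision)
}

#' Area under the ROC curve over a probability map
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' foreground pixel receives a higher score than a random background
#' pixel, ties counted one half. Invariant under strictly monotone
#' transforms of the scores.
#'
#' @param prob Numeric array of scores in \[0, 1\].
#' @param truth Binary array of the same shape.
#' @return AUC in \[0, 1\], or `NA` when the mask is single-class.
#' @export
rocAuc <- function(prob, truth) {
  stopShape(all(dim(prob) == dim(truth)), "shapes differ")
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(as.vector(prob), ties.method = "average")
  (sum(r[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Stratified metric report
#'
#' @slot perImage Per-image metrics in percent, with condition tags.
#' @slot aggregate Per-tag and overall aggregates in percent.
#' @slot mode "macro" (unweighted mean of per-image metrics) or "micro"
#'   (pixel-pooled).
#' @export
setClass("MetricReport", representation(
  perImage = "data.frame", aggregate = "data.frame", mode = "character"))

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport (%s aggregation, %d images)\n",
              object@mode, nrow(object@perImage)))
  print(object@aggregate, row.names = FALSE, digits = 4)
})

.metricRow <- function(probMap, predMask, truth) {
  cm <- confusionMetrics(predMask, truth)
  c(dice = diceScore(predMask, truth), acc = cm[["acc"]],
    recall = cm[["recall"]], precision = cm[["precision"]],
    auc = rocAuc(probMap, truth))
}

#' Evaluate predictions against reference masks
#'
#' Probability maps are binarised by class argmax (foreground wins at
#' probability > 0.5). Metrics are reported per image and aggregated per
#' condition tag and overall, in percent. Macro aggregation averages
#' per-image metrics (images with single-class masks are excluded from
#' the AUC average); micro aggregation pools pixels across images.
#'
#' @param probs List of foreground-probability matrices.
#' @param truths List of binary reference masks.
#' @param tags Character vector of condition tags (optional).
#' @param mode "macro" (default) or "micro".
#' @return A [MetricReport-class].
#' @export
evaluateSegmentation <- function(probs, truths, tags = NULL,
                                 mode = c("macro", "micro")) {
  mode <- match.arg(mode)
  stopShape(length(probs) == length(truths), "probs/truths length mismatch")
  if (is.null(tags)) tags <- rep("all", length(probs))
  rows <- t(vapply(seq_along(probs), function(i) {
    .metricRow(probs[[i]], (probs[[i]] > 0.5) * 1, truths[[i]])
  }, numeric(5)))
  perImage <- data.frame(image = seq_along(probs), tag = tags,
                         100 * rows, check.names = FALSE)
  aggOne <- function(sel, label) {
    if (mode == "macro") {
      m <- colMeans(perImage[sel, c("dice", "acc", "recall", "precision")])
      aucv <- perImage$auc[sel]
      data.frame(tag = label, n = sum(sel), dice = m[["dice"]],
                 acc = m[["acc"]], recall = m[["recall"]],
                 precision = m[["precision"]],
                 auc = if (all(is.na(aucv))) NA_real_
                       else mean(aucv, na.rm = TRUE))
    } else {
      pr <- unlist(lapply(which(sel), function(i) as.vector(probs[[i]])))
      tr <- unlist(lapply(which(sel), function(i) as.vector(truths[[i]])))
      pm <- (pr > 0.5) * 1
      cm <- confusionMetrics(pm, tr)
      data.frame(tag = label, n = sum(sel),
                 dice = 100 * diceScore(pm, tr), acc = 100 * cm[["acc"]],
                 recall = 100 * cm[["recall"]],
                 precision = 100 * cm[["precision"]],
                 auc = 100 * rocAuc(pr, tr))
    }
  }
  agg <- do.call(rbind, c(
    lapply(unique(tags), function(tg) aggOne(tags == tg, tg)),
    list(aggOne(rep(TRUE, length(probs)), "all"))))
  new("MetricReport", perImage = perImage, aggregate = agg, mode = mode)
}

#' Write a metric report as CSV and JSON
#'
#' The CSV mirrors the (condition x metric) aggregate layout; the JSON
#' twin carries both the aggregate and the per-image table.
#'
#' @param report A [MetricReport-class].
#' @param csvPath,jsonPath Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
writeMetricReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(report@aggregate, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(mode = report@mode,
                              aggregate = report@aggregate,
                              perImage = report@perImage),
                         jsonPath, dataframe = "rows", digits = NA,
                         na = "null")
  invisible(report)
}
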