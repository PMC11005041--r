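# Binary-classification performance statistics.
#
# Five statistics evaluate every model and every consensus combination:
# precision, recall (sensitivity), specificity, accuracy and the
# Matthews correlation coefficient (MCC), the balanced statistic used
# for all model selection in this package.

#' Confusion counts from binary labels
#'
#' TP/TN count toxic/nontoxic compounds correctly predicted as such; FP
#' counts nontoxic compounds predicted toxic; FN counts toxic compounds
#' predicted nontoxic.
#'
#' @param truth,predicted equal-length 0/1 vectors (1 = toxic).
#' @return list with `TP`, `TN`, `FP`, `FN`; the four counts partition
#'   the sample.
#' @export
confusionCounts <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stop("labels must be binary 0/1")
  list(TP = sum(truth == 1 & predicted == 1),
       TN = sum(truth == 0 & predicted == 0),
       FP = sum(truth == 0 & predicted == 1),
       FN = sum(truth == 1 & predicted == 0))
}

#' Five-statistic performance report
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, `accuracy = (TP+TN)/total` and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' MCC is 1 for a perfect classification, 0 for random agreement and -1
#' for complete disagreement. A zero factor in the MCC denominator gives
#' MCC = 0 (standard convention); a zero denominator in
#' precision/recall/specificity is reported as `NA` (excluded from
#' ranking).
#'
#' @param counts list with `TP`, `TN`, `FP`, `FN` (see
#'   [confusionCounts()]).
#' @return list with `precision`, `recall`, `specificity`, `accuracy`,
#'   `mcc`.
#' @examples
#' computeMetrics(list(TP = 2, TN = 3, FP = 1, FN = 1))$mcc  # 5/12
#' @export
computeMetrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  stopifnot(all(c(TP, TN, FP, FN) >= 0))
  total <- TP + TN + FP + FN
  if (total == 0) stop("empty confusion table")
  safeDiv <- function(num, den) if (den == 0) NA_real_ else num / den
  denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom == 0) 0 else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom)
  list(precision = safeDiv(TP, TP + FP),
       recall = safeDiv(TP, TP + FN),
       specificity = safeDiv(TN, TN + FP),
       accuracy = (TP + TN) / total,
       mcc = mcc)
}

#' Convenience: metrics straight from label vectors
#' @inheritParams confusionCounts
#' @return see [computeMetrics()].
#' @export
classificationMetrics <- function(truth, predicted) {
  computeMetrics(confusionCounts(truth, predicted))
}
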