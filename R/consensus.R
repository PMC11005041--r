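# Exhaustive consensus-combination scanning.
#
# A consensus combination is a subset of >= 2 trained models; its
# consensus score (CS) for a compound is the arithmetic mean of the
# member probability scores, thresholded at 0.5 (inclusive on the toxic
# side, like PS). All C(n,2) + ... + C(n,n) subsets are enumerated,
# scored on the held-out test set and ranked by MCC.

#' Number of consensus combinations
#'
#' `sum_{k = kMin}^{kMax} choose(n, k)`. For n = 12 models and k in
#' 2..12 this is 4083 (= 2^12 - 12 - 1); for n = 20, 1,048,555.
#'
#' @param n total number of models.
#' @param kMin,kMax combination size range (defaults 2..n).
#' @return the combination count (numeric to stay exact past 2^31).
#' @export
countCombinations <- function(n, kMin = 2L, kMax = n) {
  stopifnot(length(n) == 1, n >= 0)
  if (kMin < 0 || kMax < kMin || kMax > n)
    stop("invalid combination size range")
  sum(choose(n, kMin:kMax))
}

#' Consensus score and label of one combination
#'
#' @param ps numeric vector of member probability scores (>= 2 members),
#'   or a matrix (members x compounds).
#' @return list with `cs` (mean PS per compound) and `label`
#'   (toxic = 1 iff CS >= 0.5).
#' @export
consensusScore <- function(ps) {
  if (is.matrix(ps)) {
    if (nrow(ps) < 2L) stop("a consensus needs >= 2 member scores")
    cs <- colMeans(ps)
  } else {
    if (length(ps) < 2L) stop("a consensus needs >= 2 member scores")
    cs <- mean(ps)
  }
  stopifnot(all(cs >= 0 & cs <= 1))
  list(cs = cs, label = psLabel(cs))
}

# all index subsets of sizes kMin..kMax, in deterministic order:
# increasing size, then lexicographic
enumerateCombinations <- function(n, kMin = 2L, kMax = n) {
  stopifnot(kMin >= 0, kMax >= kMin, kMax <= n)
  out <- list()
  for (k in kMin:kMax) {
    cmb <- utils::combn(n, k)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  out
}

#' Exhaustive consensus scan
#'
#' Evaluates every combination of ensemble members (sizes `kMin`..n) on
#' a labeled test set: each model's PS vector is computed once and
#' reused across all combinations, so a 12-model ensemble costs 4083
#' mean-and-threshold passes. Results are ranked by MCC (ties: smaller
#' combination first, then lexicographic member order).
#'
#' @param ensemble a [ModelEnsemble-class], or a precomputed PS matrix
#'   (models x compounds, rownames = model ids).
#' @param test data.frame with `smiles` and 0/1 `label`; ignored except
#'   for `label` when a PS matrix is supplied with no smiles needed.
#' @param kMin smallest combination size (default 2).
#' @return data.frame ranked by decreasing MCC with columns `members`
#'   (ids joined by `+`), `k`, `precision`, `recall`, `specificity`,
#'   `accuracy`, `mcc`.
#' @export
exhaustiveScan <- function(ensemble, test, kMin = 2L) {
  if (is(ensemble, "ModelEnsemble")) {
    ps <- ensemblePS(ensemble, test$smiles)
  } else {
    ps <- ensemble
    stopifnot(is.matrix(ps), !is.null(rownames(ps)))
  }
  y <- as.integer(test$label)
  stopifnot(length(y) == ncol(ps))
  n <- nrow(ps)
  combos <- enumerateCombinations(n, kMin = kMin)
  ids <- rownames(ps)
  rows <- lapply(combos, function(sel) {
    cs <- colMeans(ps[sel, , drop = FALSE])
    m <- classificationMetrics(y, as.integer(cs >= 0.5))
    data.frame(members = paste(ids[sel], collapse = "+"),
               k = length(sel),
               precision = m$precision, recall = m$recall,
               specificity = m$specificity, accuracy = m$accuracy,
               mcc = m$mcc, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res[order(-res$mcc, res$k, res$members), , drop = FALSE]
}

#' Select the best consensus combination
#'
#' Maximal MCC; ties prefer fewer members (cheaper prediction), then the
#' lexicographically smallest member-id tuple, so selection is
#' deterministic.
#'
#' @param results the ranked data.frame from [exhaustiveScan()].
#' @return a [ConsensusResult-class] (with empty `cs`; scores per
#'   compound are recomputed on demand via [consensusPredict()]).
#' @export
selectBest <- function(results) {
  stopifnot(nrow(results) >= 1L)
  ord <- order(-results$mcc, results$k, results$members)
  top <- results[ord[1], ]
  new("ConsensusResult",
      members = strsplit(top$members, "+", fixed = TRUE)[[1]],
      cs = numeric(),
      metrics = as.list(top[c("precision", "recall", "specificity",
                              "accuracy", "mcc")]))
}

#' Consensus prediction for new compounds
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param best a [ConsensusResult-class] (or character vector of member
#'   ids).
#' @param smiles SMILES to predict.
#' @return data.frame with `smiles`, `cs`, `label`, plus one `PS.<id>`
#'   column per member model.
#' @export
consensusPredict <- function(ensemble, best, smiles) {
  members <- if (is(best, "ConsensusResult")) best@members else best
  stopifnot(all(members %in% modelIds(ensemble)))
  mols <- standardizeSmiles(smiles)
  ps <- ensemblePS(ensemble, mols)[members, , drop = FALSE]
  sc <- consensusScore(ps)
  out <- data.frame(smiles = canonicalSmiles(mols), cs = sc$cs,
                    label = sc$label, stringsAsFactors = FALSE)
  for (id in members) out[[paste0("PS.", id)]] <- ps[id, ]
  out
}

#' @rdname consensusMembers
#' @export
setMethod("consensusMembers", "ConsensusResult", function(object)
  object@members)

#' @rdname consensusMetrics
#' @export
setMethod("consensusMetrics", "ConsensusResult", function(object)
  object@metrics)

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: %d members (MCC %.3f)\n",
              length(object@members),
              if (length(object@metrics)) object@metrics$mcc else NA))
  cat(" ", paste(object@members, collapse = " + "), "\n")
})

#' Write the scan ranking and the best-combination manifest
#'
#' @param results ranked data.frame from [exhaustiveScan()].
#' @param best a [ConsensusResult-class].
#' @param csvPath,jsonPath output paths (NULL to skip either).
#' @export
writeScanReport <- function(results, best, csvPath = NULL,
                            jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(results, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(members = best@members, metrics = best@metrics),
      jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
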