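# Kernel SHAP: local, model-agnostic Shapley-value estimation.
#
# Features that never differ from the background have Shapley value 0
# and are excluded from the regression. When the budget covers all
# 2^M - 2 nonempty proper coalitions of the M varying features, the
# weighted regression recovers the exact Shapley values of the
# value function v(S) = E_b[ f(x_S, b_!S) ]; otherwise coalition sizes
# are enumerated smallest-first (paired with their complements) and the
# remainder is sampled. The sum of the returned scores plus the base
# expectation equals the model output (local accuracy) by construction
# of the constrained regression.

#' Kernel SHAP feature attributions for one prediction
#'
#' @param predictFun function mapping a 0/1 matrix (rows = synthetic
#'   compounds) to probability scores.
#' @param x numeric/integer 0/1 vector: the explained compound's
#'   fingerprint.
#' @param background matrix (reference compounds x bits) drawn from the
#'   model's training set; masked-out features take background values.
#' @param nsamples coalition budget, `"auto"` = `2 * M + 2048` where M
#'   is the number of varying features.
#' @param seed integer seed for coalition sampling.
#' @param chunkRows maximum synthetic rows per predict call.
#' @return list with `phi` (signed score per bit; positive pushes toward
#'   toxicity), `base` (mean model output on the background), `fx`
#'   (model output at `x`), `varying` (indices of features entering the
#'   regression).
#' @export
kernelShap <- function(predictFun, x, background, nsamples = "auto",
                       seed = 1L, chunkRows = 25000L) {
  x <- as.numeric(x)
  stopifnot(is.matrix(background), ncol(background) == length(x))
  L <- length(x)
  m <- nrow(background)
  base <- mean(predictFun(background))
  fx <- predictFun(matrix(x, nrow = 1))[1]
  differs <- colSums(background != matrix(x, m, L, byrow = TRUE)) > 0
  varying <- which(differs)
  M <- length(varying)
  phi <- numeric(L)
  if (M == 0) return(list(phi = phi, base = base, fx = fx,
                          varying = integer()))
  if (M == 1) {
    phi[varying] <- fx - base
    return(list(phi = phi, base = base, fx = fx, varying = varying))
  }
  budget <- if (identical(nsamples, "auto")) 2L * M + 2048L
            else as.integer(nsamples)
  coal <- sampleCoalitions(M, budget, seed)
  v <- coalitionValues(coal$Z, predictFun, x, background, varying,
                       chunkRows)
  phi[varying] <- solveShapRegression(coal$Z, coal$w, v, base, fx)
  list(phi = phi, base = base, fx = fx, varying = varying)
}

# kernel weight of one coalition of size s among M features
shapKernelWeight <- function(M, s) (M - 1) / (choose(M, s) * s * (M - s))

# Z: logical coalition matrix (ncoal x M); w: regression weights.
sampleCoalitions <- function(M, budget, seed) {
  sizes <- 1:(M - 1)
  # paired ordering: 1, M-1, 2, M-2, ...
  ord <- unique(as.vector(rbind(sizes, rev(sizes))))
  nOf <- choose(M, ord)
  Z <- list(); w <- numeric(0)
  remaining <- budget
  sampled <- integer(0)
  for (i in seq_along(ord)) {
    s <- ord[i]
    if (nOf[i] <= remaining) {
      cmb <- utils::combn(M, s)
      zi <- matrix(FALSE, ncol(cmb), M)
      zi[cbind(rep(seq_len(ncol(cmb)), each = s), as.vector(cmb))] <- TRUE
      Z[[length(Z) + 1]] <- zi
      w <- c(w, rep(shapKernelWeight(M, s), ncol(cmb)))
      remaining <- remaining - ncol(cmb)
    } else {
      sampled <- c(sampled, s)
    }
  }
  if (length(sampled) && remaining > 0) {
    wSize <- (M - 1) / (sampled * (M - sampled))  # total weight per size
    pr <- wSize / sum(wSize)
    draw <- withSeed(seed, {
      ss <- sample(sampled, remaining, replace = TRUE, prob = pr)
      lapply(ss, function(s) sort(sample.int(M, s)))
    })
    ss <- lengths(draw)
    zi <- matrix(FALSE, length(draw), M)
    for (j in seq_along(draw)) zi[j, draw[[j]]] <- TRUE
    # each size's total kernel mass split over its sampled coalitions
    wj <- numeric(length(draw))
    for (s in unique(ss)) {
      sel <- ss == s
      wj[sel] <- ((M - 1) / (s * (M - s))) / sum(sel)
    }
    Z[[length(Z) + 1]] <- zi
    w <- c(w, wj)
  }
  list(Z = do.call(rbind, Z), w = w)
}

coalitionValues <- function(Z, predictFun, x, background, varying,
                            chunkRows) {
  m <- nrow(background)
  ncoal <- nrow(Z)
  v <- numeric(ncoal)
  perChunk <- max(1L, chunkRows %/% m)
  for (start in seq(1L, ncoal, by = perChunk)) {
    idx <- start:min(start + perChunk - 1L, ncoal)
    synth <- background[rep(seq_len(m), times = length(idx)), ,
                        drop = FALSE]
    for (j in seq_along(idx)) {
      rows <- (j - 1L) * m + seq_len(m)
      on <- varying[Z[idx[j], ]]
      if (length(on))
        synth[rows, on] <- matrix(x[on], m, length(on), byrow = TRUE)
    }
    p <- predictFun(synth)
    v[idx] <- colMeans(matrix(p, nrow = m))
  }
  v
}

# constrained WLS: min sum w (v - base - Z phi)^2  s.t. sum(phi) = fx - base
solveShapRegression <- function(Z, w, v, base, fx) {
  M <- ncol(Z)
  Zn <- matrix(as.numeric(Z), nrow(Z), M)
  total <- fx - base
  yv <- v - base - Zn[, M] * total
  Xm <- Zn[, -M, drop = FALSE] - Zn[, M]
  XtW <- t(Xm * w)
  A <- XtW %*% Xm
  b <- XtW %*% yv
  phiHead <- tryCatch(solve(A, b), error = function(e)
    solve(A + diag(1e-8, ncol(A)), b))
  c(phiHead, total - sum(phiHead))
}

#' Per-bit Shapley scores for one compound under one model
#'
#' Runs Kernel SHAP on the model's own fingerprint family. Positive
#' scores contribute toward the prediction of toxicity, negative toward
#' nontoxicity.
#'
#' @param model a [TrainedClassifier-class].
#' @param fp the compound's [FingerprintSet-class] (one row) of the
#'   model's family, or a 0/1 vector.
#' @param background matrix of training fingerprints of the same family
#'   (the Kernel SHAP reference set).
#' @inheritParams kernelShap
#' @return list with `modelId`, `scores` (length = bit count), `base`,
#'   `ps` (the model's probability score for the compound).
#' @export
featureScores <- function(model, fp, background, nsamples = "auto",
                          seed = 1L) {
  stopifnot(is(model, "TrainedClassifier"))
  x <- if (is(fp, "FingerprintSet")) {
    if (fpFamily(fp) != model@family)
      stop("fingerprint family mismatch: model is ", model@family)
    stopifnot(nMolecules(fp) == 1L)
    fingerprintMatrix(fp)[1, ]
  } else as.numeric(fp)
  ks <- kernelShap(function(m) predictPS(model, m), x, background,
                   nsamples = nsamples, seed = seed)
  list(modelId = paste(model@algorithm, model@family, sep = "."),
       scores = ks$phi, base = ks$base, ps = ks$fx)
}
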