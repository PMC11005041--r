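# Independent oracles used by the SHAP and acceptance suites.

# Brute-force Shapley values by subset enumeration over the varying
# features, with the value function v(S) = E_b[f(x_S, b_!S)]. Kept
# deliberately naive and independent of the package's Kernel SHAP path.
exactShapleyOracle <- function(f, x, background) {
  L <- length(x)
  varying <- which(colSums(background != matrix(x, nrow(background), L,
                                                byrow = TRUE)) > 0)
  M <- length(varying)
  phi <- numeric(L)
  if (M == 0) return(phi)
  vOf <- function(S) {
    synth <- background
    if (length(S))
      synth[, varying[S]] <- matrix(x[varying[S]], nrow(background),
                                    length(S), byrow = TRUE)
    mean(f(synth))
  }
  subsets <- lapply(0:(2^M - 1), function(code) which(bitwAnd(
    code, 2^(0:(M - 1))) > 0))
  vCache <- vapply(subsets, vOf, numeric(1))
  codeOf <- function(S) sum(2^(S - 1)) + 1
  for (j in seq_len(M)) {
    total <- 0
    for (S in subsets) {
      if (j %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(M - s - 1) / factorial(M)
      total <- total + w * (vCache[codeOf(c(S, j))] - vCache[codeOf(S)])
    }
    phi[varying[j]] <- total
  }
  phi
}

linearToyModel <- function(beta0, beta) {
  function(X) {
    eta <- beta0 + as.matrix(X) %*% beta
    as.vector(1 / (1 + exp(-eta)))
  }
}

toyBackground <- function(M, m = 8, seed = 4) {
  withr::local_seed(seed)
  matrix(rbinom(m * M, 1, 0.4), m, M)
}
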