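# The four classification algorithms behind TrainedClassifier.
#
# Common internal contract: fitAlgorithm() returns a list with $type and
# fitted state; predictAlgorithm() maps a 0/1 feature matrix to a
# probability score in [0,1]. No installed R package provides RF, SVM or
# MLP in this environment: RF is compiled Rcpp (src/forest.cpp), the SVM
# solves the dual QP with quadprog and calibrates probabilities with a
# Platt sigmoid, and the MLP is a vectorized R implementation with
# sgd/adam/L-BFGS solvers. KNN rides on FNN's neighbor search.

#' @useDynLib ToxConsensus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

fitAlgorithm <- function(algorithm, X, y, params, seed = 1L) {
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L)
    stop("single-class training data: both classes must be present")
  switch(algorithm,
    RF = fitRF(X, y, params, seed),
    SVM = fitSVM(X, y, params, seed),
    KNN = fitKNN(X, y, params, seed),
    MLP = fitMLP(X, y, params, seed),
    stop("unknown algorithm: ", algorithm))
}

predictAlgorithm <- function(fit, X) {
  stopifnot(is.matrix(X))
  p <- switch(fit$type,
    RF = .forestPredict(fit$trees, storageMatrix(X)),
    SVM = predictSVMProb(fit, X),
    KNN = predictKNNProb(fit, X),
    MLP = predictMLPProb(fit, X),
    stop("unknown fit type"))
  pmin(1, pmax(0, p))
}

storageMatrix <- function(X) {
  if (!is.integer(X)) storage.mode(X) <- "integer"
  X
}

# ----------------------------------------------------------------- RF

fitRF <- function(X, y, params, seed) {
  p <- ncol(X)
  mtry <- switch(as.character(params$max_features %||% "sqrt"),
                 sqrt = max(1L, floor(sqrt(p))),
                 log2 = max(1L, floor(log2(p))),
                 all = p,
                 none = p,
                 stop("unknown max_features option"))
  ntree <- as.integer(params$n_estimators %||% 100L)
  trees <- .forestFit(storageMatrix(X), as.integer(y), ntree, mtry,
                      as.integer(seed))
  list(type = "RF", trees = trees, mtry = mtry, ntree = ntree)
}

# ----------------------------------------------------------------- SVM

svmKernel <- function(A, B, kernel, gamma) {
  if (kernel == "linear") return(A %*% t(B))
  # rbf: |a-b|^2 = |a|^2 + |b|^2 - 2ab
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

fitSVM <- function(X, y, params, seed) {
  kernel <- match.arg(params$kernel %||% "rbf", c("linear", "rbf"))
  C <- as.numeric(params$C %||% 1)
  storage.mode(X) <- "double"
  # sklearn's gamma = "scale": 1 / (n_features * Var(X))
  v <- stats::var(as.vector(X))
  gamma <- if (kernel == "rbf") 1 / (ncol(X) * max(v, 1e-12)) else 0
  n <- nrow(X)
  ys <- ifelse(y == 1, 1, -1)
  K <- svmKernel(X, X, kernel, gamma)
  D <- (ys %o% ys) * K
  diag(D) <- diag(D) + 1e-8  # ridge for positive definiteness
  A <- cbind(ys, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A,
                            bvec = b0, meq = 1)
  alpha <- pmin(C, pmax(0, sol$solution))
  sv <- alpha > 1e-6
  f <- as.vector(K %*% (alpha * ys))
  margin <- sv & alpha < C - 1e-6
  use <- if (any(margin)) margin else sv
  b <- mean(ys[use] - f[use])
  dec <- f + b
  # Platt sigmoid on the training decision values
  platt <- suppressWarnings(
    stats::glm(y ~ dec, family = stats::binomial()))
  list(type = "SVM", kernel = kernel, gamma = gamma, C = C,
       sv = X[sv, , drop = FALSE], coef = (alpha * ys)[sv], b = b,
       platt = stats::coef(platt))
}

predictSVMDecision <- function(fit, X) {
  storage.mode(X) <- "double"
  K <- svmKernel(X, fit$sv, fit$kernel, fit$gamma)
  as.vector(K %*% fit$coef) + fit$b
}

predictSVMProb <- function(fit, X) {
  dec <- predictSVMDecision(fit, X)
  eta <- fit$platt[1] + fit$platt[2] * dec
  1 / (1 + exp(-eta))
}

# ----------------------------------------------------------------- KNN

fitKNN <- function(X, y, params, seed) {
  list(type = "KNN", X = storageMatrix(X), y = as.integer(y),
       k = as.integer(params$n_neighbors %||% 5L),
       weights = match.arg(params$weights %||% "uniform",
                           c("uniform", "distance")))
}

predictKNNProb <- function(fit, X) {
  k <- min(fit$k, nrow(fit$X))
  nn <- FNN::get.knnx(fit$X, storageMatrix(X), k = k)
  lab <- matrix(fit$y[nn$nn.index], ncol = k)
  if (fit$weights == "uniform") return(rowMeans(lab))
  d <- nn$nn.dist
  w <- 1 / pmax(d, .Machine$double.eps)
  ps <- rowSums(w * lab) / rowSums(w)
  # exact-distance ties dominate: average the zero-distance neighbors
  zero <- rowSums(d == 0) > 0
  if (any(zero)) {
    z <- d[zero, , drop = FALSE] == 0
    ps[zero] <- rowSums(lab[zero, , drop = FALSE] * z) / rowSums(z)
  }
  ps
}

# ----------------------------------------------------------------- MLP

mlpActivation <- function(name) {
  switch(name,
    identity = list(f = function(z) z, df = function(a) 1),
    logistic = list(f = function(z) 1 / (1 + exp(-z)),
                    df = function(a) a * (1 - a)),
    tanh = list(f = tanh, df = function(a) 1 - a^2),
    relu = list(f = function(z) pmax(z, 0), df = function(a) (a > 0) * 1),
    stop("unknown activation: ", name))
}

mlpInit <- function(sizes, seed) {
  withSeed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      # Glorot uniform
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
    list(W = W, b = b)
  })
}

mlpForward <- function(par, X, act) {
  L <- length(par$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L - 1))
    A[[l + 1]] <- act$f(sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], "+"))
  zo <- sweep(A[[L]] %*% par$W[[L]], 2, par$b[[L]], "+")
  A[[L + 1]] <- 1 / (1 + exp(-zo))
  A
}

# gradient of mean log-loss + alpha/(2n) * ||W||^2 on one batch
mlpGrad <- function(par, X, y, act, alpha, nTotal) {
  L <- length(par$W)
  A <- mlpForward(par, X, act)
  n <- nrow(X)
  delta <- (A[[L + 1]] - y) / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(A[[l]], delta) + (alpha / nTotal) * par$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% t(par$W[[l]])) * act$df(A[[l]])
  }
  list(W = gW, b = gb, prob = A[[L + 1]])
}

mlpLoss <- function(par, X, y, act, alpha) {
  p <- mlpForward(par, X, act)[[length(par$W) + 1]]
  eps <- 1e-10
  ll <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  ll + alpha / (2 * nrow(X)) * sum(vapply(par$W, function(w) sum(w^2),
                                          numeric(1)))
}

mlpPack <- function(par) unlist(c(par$W, par$b), use.names = FALSE)

mlpUnpack <- function(theta, sizes) {
  W <- list(); b <- list(); off <- 0L
  for (l in seq_len(length(sizes) - 1)) {
    len <- sizes[l] * sizes[l + 1]
    W[[l]] <- matrix(theta[off + seq_len(len)], sizes[l], sizes[l + 1])
    off <- off + len
  }
  for (l in seq_len(length(sizes) - 1)) {
    len <- sizes[l + 1]
    b[[l]] <- theta[off + seq_len(len)]
    off <- off + len
  }
  list(W = W, b = b)
}

fitMLP <- function(X, y, params, seed) {
  storage.mode(X) <- "double"
  hidden <- as.integer(unlist(params$hidden_layer_sizes %||% 100L))
  solver <- match.arg(params$solver %||% "adam",
                      c("adam", "sgd", "lbfgs"))
  activation <- match.arg(params$activation %||% "relu",
                          c("identity", "logistic", "tanh", "relu"))
  lr <- as.numeric(params$learning_rate_init %||% 0.001)
  maxIter <- as.integer(params$max_iter %||% 200L)
  alpha <- as.numeric(params$alpha %||% 1e-4)
  act <- mlpActivation(activation)
  sizes <- c(ncol(X), hidden, 1L)
  par <- mlpInit(sizes, seed)
  y <- matrix(as.numeric(y), ncol = 1)
  n <- nrow(X)
  if (solver == "lbfgs") {
    obj <- function(theta)
      mlpLoss(mlpUnpack(theta, sizes), X, y, act, alpha)
    grd <- function(theta) {
      g <- mlpGrad(mlpUnpack(theta, sizes), X, y, act, alpha, n)
      mlpPack(g)
    }
    opt <- stats::optim(mlpPack(par), obj, grd, method = "L-BFGS-B",
                        control = list(maxit = maxIter))
    par <- mlpUnpack(opt$par, sizes)
  } else {
    batch <- min(200L, n)
    theta <- mlpPack(par)
    mAdam <- vAdam <- numeric(length(theta))
    beta1 <- 0.9; beta2 <- 0.999; epsAdam <- 1e-8; t <- 0L
    withSeed(seed + 1L, {
      for (epoch in seq_len(maxIter)) {
        ord <- sample.int(n)
        for (start in seq(1L, n, by = batch)) {
          idx <- ord[start:min(start + batch - 1L, n)]
          par <- mlpUnpack(theta, sizes)
          g <- mlpGrad(par, X[idx, , drop = FALSE],
                       y[idx, , drop = FALSE], act, alpha, n)
          gvec <- mlpPack(g)
          if (solver == "sgd") {
            theta <- theta - lr * gvec
          } else {
            t <- t + 1L
            mAdam <- beta1 * mAdam + (1 - beta1) * gvec
            vAdam <- beta2 * vAdam + (1 - beta2) * gvec^2
            mhat <- mAdam / (1 - beta1^t)
            vhat <- vAdam / (1 - beta2^t)
            theta <- theta - lr * mhat / (sqrt(vhat) + epsAdam)
          }
        }
      }
    })
    par <- mlpUnpack(theta, sizes)
  }
  list(type = "MLP", par = par, sizes = sizes, activation = activation)
}

predictMLPProb <- function(fit, X) {
  storage.mode(X) <- "double"
  act <- mlpActivation(fit$activation)
  as.vector(mlpForward(fit$par, X, act)[[length(fit$par$W) + 1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
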