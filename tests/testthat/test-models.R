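# Classifier training: grids, grid-search CV scored by MCC, the PS
# contract and y-randomization.

# tiny separable binary world: bit 3 decides the label, other bits noise
toyData <- function(n = 60, p = 20, seed = 5) {
  withr::local_seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.3), n, p)
  y <- X[, 3]
  list(X = X, y = as.integer(y))
}

test_that("default grids encode the documented candidate values", {
  expect_length(defaultGrid("RF"), 3 * 2)
  expect_length(defaultGrid("SVM"), 2 * 4)
  expect_length(defaultGrid("KNN"), 15 * 2)
  # 3 + 9 + 27 layer layouts x 3 solvers x 4 activations x 3 rates
  expect_length(defaultGrid("MLP"), 39 * 3 * 4 * 3)
  rf <- defaultGrid("RF")
  expect_setequal(unique(vapply(rf, `[[`, character(1), "max_features")),
                  c("sqrt", "log2", "all"))
  expect_setequal(unique(vapply(rf, `[[`, numeric(1), "n_estimators")),
                  c(100, 500))
  mlp <- defaultGrid("MLP")
  depths <- vapply(mlp, function(g) length(g$hidden_layer_sizes),
                   integer(1))
  expect_setequal(unique(depths), 1:3)
})

test_that("every algorithm fits separable data and honors the PS contract", {
  d <- toyData()
  params <- list(RF = list(max_features = "sqrt", n_estimators = 50L),
                 SVM = list(kernel = "linear", C = 1),
                 KNN = list(n_neighbors = 3L, weights = "distance"),
                 MLP = list(hidden_layer_sizes = 16L, solver = "lbfgs",
                            activation = "relu", max_iter = 150L))
  for (alg in names(params)) {
    fit <- ToxConsensus:::fitAlgorithm(alg, d$X, d$y, params[[alg]],
                                       seed = 2)
    ps <- ToxConsensus:::predictAlgorithm(fit, d$X)
    expect_true(all(ps >= 0 & ps <= 1), info = alg)
    m <- classificationMetrics(d$y, psLabel(ps))
    expect_gte(m$mcc, 0.9)
    # determinism given the seed
    fit2 <- ToxConsensus:::fitAlgorithm(alg, d$X, d$y, params[[alg]],
                                        seed = 2)
    expect_equal(ToxConsensus:::predictAlgorithm(fit2, d$X), ps,
                 info = alg)
  }
  expect_error(
    ToxConsensus:::fitAlgorithm("RF", d$X, rep(1L, nrow(d$X)),
                                params$RF),
    "single-class")
})

test_that("PS thresholding is inclusive at 0.5", {
  expect_identical(psLabel(c(0.5, 0.49, 1, 0)), c(1L, 0L, 1L, 0L))
})

test_that("grid search evaluates every point on shared CV resamples", {
  d <- toyData(n = 50)
  grid <- expandGrid(n_neighbors = c(1L, 5L), weights = "uniform")
  cv <- gridSearchCV(d$X, d$y, "KNN", grid = grid, folds = 20L, seed = 3)
  expect_identical(dim(cv$foldMCC), c(2L, 20L))     # 20 MCC per point
  expect_identical(cv$best, grid[[cv$bestIndex]])
  expect_equal(cv$meanMCC[cv$bestIndex], max(cv$meanMCC))
  # a one-point grid selects that point
  cv1 <- gridSearchCV(d$X, d$y, "KNN", grid = grid[1], folds = 3L,
                      seed = 3)
  expect_identical(cv1$bestIndex, 1L)
  expect_error(gridSearchCV(d$X, rep(0L, nrow(d$X)), "KNN", grid = grid),
               "single-class")
})

test_that("trainFinal yields a working TrainedClassifier", {
  d <- toyData()
  model <- trainFinal(d$X, d$y, "RF", "MORGAN",
                      list(max_features = "sqrt", n_estimators = 50L),
                      familyParams = list(nbits = ncol(d$X)), seed = 1)
  expect_s4_class(model, "TrainedClassifier")
  ps <- predictPS(model, d$X)
  expect_length(ps, nrow(d$X))
  # family mismatch between model and fingerprints is rejected
  fp <- new("FingerprintSet", family = "PUBCHEM",
            bits = matrix(0L, 1, 881), smiles = "C",
            params = list(nbits = 881L))
  expect_error(predictPS(model, fp), "family mismatch")
})

test_that("y-randomization collapses a real signal to chance", {
  d <- toyData(n = 80)
  yr <- yRandomization(d$X, d$y, d$X, d$y, "KNN",
                       list(n_neighbors = 3L, weights = "uniform"),
                       nRounds = 5L, seed = 9)
  expect_identical(nrow(yr), 5L)
  expect_lt(mean(abs(yr$mcc)), 0.35)
  # shuffles are reproducible
  yr2 <- yRandomization(d$X, d$y, d$X, d$y, "KNN",
                        list(n_neighbors = 3L, weights = "uniform"),
                        nRounds = 5L, seed = 9)
  expect_equal(yr$mcc, yr2$mcc)
})

test_that("ensembles save and load as bundles with a manifest", {
  ens <- sharedEnsemble()
  dir <- withr::local_tempdir()
  saveEnsemble(ens, dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(manifest$models, 12)
  back <- loadEnsemble(dir)
  expect_setequal(modelIds(back), modelIds(ens))
  # a reloaded ensemble predicts identically
  smi <- sharedSplit()$test$smiles[1:5]
  expect_equal(ensemblePS(back, smi), ensemblePS(ens, smi))
})
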