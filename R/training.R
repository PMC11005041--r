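# Grid-searched model training under repeated random-split CV.
#
# One endpoint gets 12 classifiers (4 algorithms x 3 fingerprint
# families). Hyperparameters are tuned by exhaustive grid search; each
# grid point is scored by the mean Matthews correlation coefficient over
# cross-validation folds, where a "fold" is an independent random 80/20
# resample of the training data (repeated holdout, 20 folds by default).

#' Default hyperparameter grid of an algorithm
#'
#' The full grids: RF tunes `max_features` (sqrt, log2 or all features)
#' and `n_estimators` (100, 500); KNN tunes `n_neighbors` (1--15) and
#' `weights` (uniform, distance); MLP tunes `hidden_layer_sizes` (all
#' 1--3 layer combinations of 100, 200 and 1000 neurons), `solver`
#' (lbfgs, adam, sgd), `activation` (identity, logistic, tanh, relu) and
#' `learning_rate_init` (0.01, 0.001, 0.0001); SVM tunes `kernel`
#' (linear, rbf) and `C` (0.1, 1, 10, 100).
#'
#' @param algorithm one of `"RF"`, `"SVM"`, `"KNN"`, `"MLP"`.
#' @return list of hyperparameter settings (each itself a named list).
#' @export
defaultGrid <- function(algorithm) {
  switch(algorithm,
    RF = expandGrid(max_features = c("sqrt", "log2", "all"),
                    n_estimators = c(100L, 500L)),
    SVM = expandGrid(kernel = c("linear", "rbf"), C = c(0.1, 1, 10, 100)),
    KNN = expandGrid(n_neighbors = 1:15,
                     weights = c("uniform", "distance")),
    MLP = {
      sizes <- unlist(lapply(1:3, function(d)
        lapply(seq_len(3^d), function(i) {
          idx <- (i - 1)
          v <- integer(d)
          for (j in seq_len(d)) {
            v[j] <- c(100L, 200L, 1000L)[idx %% 3 + 1]
            idx <- idx %/% 3
          }
          v
        })), recursive = FALSE)
      expandGrid(hidden_layer_sizes = sizes,
                 solver = c("lbfgs", "adam", "sgd"),
                 activation = c("identity", "logistic", "tanh", "relu"),
                 learning_rate_init = c(0.01, 0.001, 0.0001))
    },
    stop("unknown algorithm: ", algorithm))
}

#' Reduced grid for desk-scale runs
#'
#' A small subset of [defaultGrid()] candidate values used by the test
#' suite, the acceptance script and the worked examples to keep training
#' of the full 12-model ensemble within minutes. The grid structure and
#' the selection rule are identical to the full run.
#'
#' @inheritParams defaultGrid
#' @export
fastGrid <- function(algorithm) {
  switch(algorithm,
    RF = expandGrid(max_features = "sqrt", n_estimators = 100L),
    SVM = expandGrid(kernel = c("linear", "rbf"), C = c(1, 10)),
    KNN = expandGrid(n_neighbors = c(1L, 3L, 5L),
                     weights = c("uniform", "distance")),
    MLP = expandGrid(hidden_layer_sizes = list(64L), solver = "adam",
                     activation = "relu", learning_rate_init = 0.001,
                     max_iter = 60L),
    stop("unknown algorithm: ", algorithm))
}

#' Cartesian product of hyperparameter candidate values
#'
#' Like `expand.grid()` but returning a list of named settings and
#' accepting list-valued candidates (e.g. MLP layer layouts).
#'
#' @param ... named candidate vectors or lists.
#' @return list of hyperparameter settings (named lists).
#' @export
expandGrid <- function(...) {
  cand <- list(...)
  cand <- lapply(cand, function(x) if (is.list(x)) x else as.list(x))
  idx <- expand.grid(lapply(cand, seq_along), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(idx)), function(i) {
    setting <- lapply(seq_along(cand), function(j)
      cand[[j]][[idx[i, j]]])
    names(setting) <- names(cand)
    setting
  })
}

# fold index sets: independent random 80/20 resamples whose CV-training
# part contains both classes
cvFoldIndices <- function(y, folds, trainFraction, seed) {
  n <- length(y)
  nTrain <- round(n * trainFraction)
  withSeed(seed, lapply(seq_len(folds), function(f) {
    for (try in 1:100) {
      idx <- sample.int(n, nTrain)
      if (length(unique(y[idx])) == 2L) return(idx)
    }
    stop("could not draw a two-class CV resample")
  }))
}

#' Grid search with repeated random-split cross-validation
#'
#' Evaluates every grid point on the same set of random 80/20 resamples
#' of the training data and selects the setting with the highest mean
#' fold MCC (ties: first in grid order).
#'
#' @param X 0/1 fingerprint matrix of the training compounds.
#' @param y 0/1 labels (1 = toxic); both classes must be present.
#' @param algorithm `"RF"`, `"SVM"`, `"KNN"` or `"MLP"`.
#' @param grid list of hyperparameter settings, default [defaultGrid()].
#' @param folds number of random resamples (default 20).
#' @param trainFraction fraction of data in each CV-training resample.
#' @param seed integer; fold resamples and model fits derive from it.
#' @return list with `best` (hyperparameters), `meanMCC` (per grid
#'   point), `foldMCC` (matrix grid x folds), `bestIndex`, `grid`.
#' @export
gridSearchCV <- function(X, y, algorithm, grid = defaultGrid(algorithm),
                         folds = 20L, trainFraction = 0.8, seed = 1L) {
  stopifnot(length(grid) >= 1L)
  if (length(unique(y)) < 2L)
    stop("single-class training data: both classes must be present")
  foldIdx <- cvFoldIndices(y, folds, trainFraction, seed)
  foldMCC <- matrix(NA_real_, nrow = length(grid), ncol = folds)
  for (g in seq_along(grid)) {
    for (f in seq_len(folds)) {
      tr <- foldIdx[[f]]
      fit <- fitAlgorithm(algorithm, X[tr, , drop = FALSE], y[tr],
                          grid[[g]], seed = seed + f)
      ps <- predictAlgorithm(fit, X[-tr, , drop = FALSE])
      foldMCC[g, f] <- classificationMetrics(y[-tr],
                                             as.integer(ps >= 0.5))$mcc
    }
  }
  meanMCC <- rowMeans(foldMCC)
  bestIndex <- which.max(meanMCC)
  list(best = grid[[bestIndex]], meanMCC = meanMCC, foldMCC = foldMCC,
       bestIndex = bestIndex, grid = grid)
}

#' Fit the final model on the full training set
#'
#' @inheritParams gridSearchCV
#' @param family fingerprint family the matrix `X` was computed with.
#' @param hyperparams the selected hyperparameter setting (typically
#'   `gridSearchCV(...)$best`).
#' @param familyParams fingerprint parameters (default
#'   [familyParams()]).
#' @param cv optional CV summary to store with the model.
#' @return a [TrainedClassifier-class].
#' @export
trainFinal <- function(X, y, algorithm, family, hyperparams,
                       familyParams = NULL, seed = 1L, cv = list()) {
  fit <- fitAlgorithm(algorithm, X, y, hyperparams, seed = seed)
  new("TrainedClassifier", algorithm = algorithm, family = family,
      hyperparams = hyperparams, fit = fit,
      familyParams = familyParams %||% ToxConsensus::familyParams(family),
      seed = as.integer(seed), cv = cv)
}

#' @describeIn predictPS probability scores from a fingerprint matrix.
#' @export
setMethod("predictPS", signature("TrainedClassifier", "matrix"),
  function(object, newdata, ...) {
    predictAlgorithm(object@fit, newdata)
  })

#' @describeIn predictPS probability scores from a
#'   [FingerprintSet-class]; the family must match the model's.
#' @export
setMethod("predictPS", signature("TrainedClassifier", "FingerprintSet"),
  function(object, newdata, ...) {
    if (fpFamily(newdata) != object@family)
      stop("fingerprint family mismatch: model is ", object@family,
           ", data is ", fpFamily(newdata))
    predictAlgorithm(object@fit, fingerprintMatrix(newdata))
  })

#' Toxicity label from probability scores
#'
#' The 0.5 threshold is inclusive on the toxic side: PS (or CS) >= 0.5
#' is toxic, < 0.5 nontoxic.
#'
#' @param ps numeric scores in \[0,1\].
#' @return integer 0/1 labels.
#' @export
psLabel <- function(ps) {
  stopifnot(all(ps >= 0 & ps <= 1))
  as.integer(ps >= 0.5)
}

setMethod("show", "TrainedClassifier", function(object) {
  hp <- vapply(object@hyperparams, function(x)
    paste(format(x), collapse = ","), character(1))
  cat(sprintf("TrainedClassifier %s.%s (%s)\n", object@algorithm,
              object@family,
              paste(names(hp), hp, sep = "=", collapse = ", ")))
  if (length(object@cv))
    cat(sprintf("  CV mean MCC: %.3f over %d folds\n",
                object@cv$meanMCC[object@cv$bestIndex],
                ncol(object@cv$foldMCC)))
})

# --------------------------------------------------------------- ensemble

#' A 12-model ensemble for one endpoint
#'
#' @slot models named list of [TrainedClassifier-class] with ids
#'   `"<ALGORITHM>.<FAMILY>"`.
#' @slot endpoint character, endpoint label (free text).
#' @slot familyParamsList per-family fingerprint parameters.
#' @slot seed integer.
#' @export
setClass("ModelEnsemble",
  representation(models = "list", endpoint = "character",
                 familyParamsList = "list", seed = "integer"))

#' Train the full (algorithm x family) ensemble
#'
#' Computes each fingerprint family once, grid-searches every
#' (algorithm, family) pair and refits the selected setting on the full
#' training set: 3 families x 4 algorithms = 12 models per endpoint.
#'
#' @param train data.frame with canonical `smiles` and 0/1 `label`.
#' @param endpoint endpoint label stored with the ensemble.
#' @param algorithms,families subsets for reduced runs.
#' @param grids named list algorithm -> grid; default [fastGrid()] per
#'   algorithm (use [defaultGrid()] for full-scale runs).
#' @param folds CV folds (resamples) per grid point.
#' @param seed integer master seed.
#' @return a [ModelEnsemble-class]; fingerprints of the training set are
#'   attached as attribute `"fingerprints"`.
#' @export
trainEnsemble <- function(train, endpoint = "FIXTURE",
                          algorithms = c("RF", "SVM", "KNN", "MLP"),
                          families = fingerprintFamilies(),
                          grids = NULL, folds = 20L, seed = 1L) {
  stopifnot(all(c("smiles", "label") %in% names(train)))
  y <- as.integer(train$label)
  mols <- standardizeSmiles(train$smiles)
  fps <- lapply(families, function(fam) computeFingerprints(mols, fam))
  names(fps) <- families
  models <- list()
  for (fam in families) {
    X <- fingerprintMatrix(fps[[fam]])
    for (alg in algorithms) {
      grid <- if (!is.null(grids) && !is.null(grids[[alg]]))
        grids[[alg]] else fastGrid(alg)
      cv <- gridSearchCV(X, y, alg, grid = grid, folds = folds,
                         seed = seed)
      id <- paste(alg, fam, sep = ".")
      models[[id]] <- trainFinal(X, y, alg, fam, cv$best,
                                 familyParams = fps[[fam]]@params,
                                 seed = seed, cv = cv)
    }
  }
  ens <- new("ModelEnsemble", models = models, endpoint = endpoint,
             familyParamsList = lapply(fps, function(f) f@params),
             seed = as.integer(seed))
  attr(ens, "fingerprints") <- fps
  ens
}

#' Model identifiers of an ensemble
#' @param ensemble a [ModelEnsemble-class].
#' @export
modelIds <- function(ensemble) names(ensemble@models)

#' Probability-score matrix of an ensemble
#'
#' Computes each family's fingerprints once and every member model's PS
#' for a set of compounds.
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param smiles character vector of SMILES (standardized internally) or
#'   a [MoleculeSet-class].
#' @return numeric matrix, models x compounds, rownames = model ids.
#' @export
ensemblePS <- function(ensemble, smiles) {
  mols <- if (is(smiles, "MoleculeSet")) smiles else
    standardizeSmiles(smiles)
  fams <- unique(vapply(ensemble@models, fpFamily, character(1)))
  fps <- lapply(fams, function(fam)
    computeFingerprints(mols, fam,
                        params = ensemble@familyParamsList[[fam]]))
  names(fps) <- fams
  ps <- t(vapply(ensemble@models, function(m)
    predictPS(m, fps[[fpFamily(m)]]), numeric(nMolecules(mols))))
  rownames(ps) <- modelIds(ensemble)
  ps
}

setMethod("show", "ModelEnsemble", function(object) {
  cat(sprintf("ModelEnsemble '%s': %d models\n", object@endpoint,
              length(object@models)))
  cat(" ", paste(modelIds(object), collapse = ", "), "\n")
})

#' y-randomization negative control
#'
#' Re-trains a model on label-shuffled training data and evaluates it on
#' the untouched test set, once per round. Informative models collapse
#' to chance: MCC near 0 and accuracy near the majority rate (0.5 on a
#' balanced set).
#'
#' @param X,y training fingerprint matrix and labels.
#' @param Xtest,ytest test fingerprint matrix and labels.
#' @param algorithm,params model to train each round.
#' @param nRounds number of shuffling rounds (>= 1).
#' @param seed integer; round r shuffles with seed `seed + r`.
#' @return data.frame with one row per round: the five statistics.
#' @export
yRandomization <- function(X, y, Xtest, ytest, algorithm, params,
                           nRounds = 10L, seed = 1L) {
  stopifnot(nRounds >= 1L)
  rows <- lapply(seq_len(nRounds), function(r) {
    ys <- withSeed(seed + r, sample(y))
    if (length(unique(ys)) < 2L) ys <- c(0L, 1L, ys[-(1:2)])
    fit <- fitAlgorithm(algorithm, X, ys, params, seed = seed + r)
    ps <- predictAlgorithm(fit, Xtest)
    as.data.frame(classificationMetrics(ytest, psLabel(ps)))
  })
  do.call(rbind, rows)
}

# ------------------------------------------------------------ bundles

#' Save / load an ensemble as model bundles with a JSON manifest
#'
#' Each model is serialized to `<id>.rds`; `manifest.json` records
#' algorithm, family, selected hyperparameters, seeds and the MD5 hash
#' of each bundle.
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
saveEnsemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (id in modelIds(ensemble)) {
    f <- file.path(dir, paste0(id, ".rds"))
    saveRDS(ensemble@models[[id]], f)
    files[id] <- f
  }
  manifest <- list(
    endpoint = ensemble@endpoint, seed = ensemble@seed,
    familyParams = ensemble@familyParamsList,
    models = lapply(modelIds(ensemble), function(id) {
      m <- ensemble@models[[id]]
      list(id = id, algorithm = m@algorithm, family = m@family,
           hyperparams = m@hyperparams, seed = m@seed,
           file = basename(files[id]),
           md5 = unname(tools::md5sum(files[id])))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  models <- list()
  for (m in manifest$models)
    models[[m$id]] <- readRDS(file.path(dir, m$file))
  fp <- lapply(manifest$familyParams, function(p)
    lapply(p, function(x) if (is.numeric(x)) as.integer(x) else x))
  new("ModelEnsemble", models = models,
      endpoint = manifest$endpoint %||% "UNKNOWN",
      familyParamsList = fp, seed = as.integer(manifest$seed %||% 1L))
}
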