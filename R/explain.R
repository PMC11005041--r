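# Bit retro-mapping: Shapley feature scores -> signed atom weights.
#
# Each consensus member is explained on its own fingerprint family; the
# molecule's atoms are the common denominator on which the per-model
# attributions are averaged. The per-atom weight under one model is
#
#   fw(atom) = sum over features f containing the atom of
#              s_f / (n_Atoms_f x n_occ_f)
#
# where s_f is the feature's Shapley score, n_Atoms_f the number of
# atoms in the occurrence containing the atom and n_occ_f the number of
# occurrences of the feature in the molecule.

#' Collapse redundant ring-count bit scores (PubChem family)
#'
#' Bits 115--262 of the PubChem-layout fingerprint encode the same ring
#' systems at increasing occurrence thresholds; scoring all of them
#' would multiply-count the same atoms. Within each cluster of the
#' ring-bit cluster map, only the highest-scoring on-bit keeps its
#' score; the other members are zeroed (ties: the lowest bit index
#' wins). Non-PubChem score vectors pass through unchanged.
#'
#' @param scores a `featureScores()` result (or any list with `scores`).
#' @param onBits 0-based indices of the molecule's on-bits.
#' @param family fingerprint family of the scores.
#' @param clusters cluster map, default [ringBitClusters()].
#' @return `scores` with the cluster-pruned `scores` vector.
#' @export
clusterRingBits <- function(scores, onBits, family = "PUBCHEM",
                            clusters = ringBitClusters()) {
  if (family != "PUBCHEM") return(scores)
  s <- scores$scores
  for (cl in clusters) {
    members <- intersect(cl, onBits)
    if (length(members) < 2L) next
    vals <- s[members + 1L]
    keep <- members[which.max(vals)]  # ties: first = lowest bit index
    drop <- setdiff(members, keep)
    s[drop + 1L] <- 0
  }
  scores$scores <- s
  scores
}

#' Retro-map feature scores onto atoms
#'
#' Applies the atom-weight formula to one model's scores using the
#' molecule's bit-atom correspondence. Only mapped on-bits contribute;
#' unmappable on-bits (e.g. hydrogen-count keys) are skipped and
#' recorded in the `"skippedBits"` attribute.
#'
#' @param map a [BitAtomMap-class] of the molecule in the scores'
#'   family.
#' @param scores a `featureScores()` result (cluster-pruned for the
#'   PubChem family).
#' @return an [AtomWeightMap-class] (single model, `nModels = 1`).
#' @export
atomWeights <- function(map, scores) {
  stopifnot(is(map, "BitAtomMap"))
  s <- scores$scores
  w <- numeric(map@nAtoms)
  prov <- vector("list", map@nAtoms)
  for (bitChr in names(map@entries)) {
    bit <- as.integer(bitChr)
    sf <- s[bit + 1L]
    if (sf == 0) next
    occ <- map@entries[[bitChr]]
    nOcc <- length(occ)
    for (atoms in occ) {
      if (any(atoms < 0L) || any(atoms >= map@nAtoms))
        stop("atom index out of range in bit-atom map")
      contrib <- sf / (length(atoms) * nOcc)
      w[atoms + 1L] <- w[atoms + 1L] + contrib
      for (a in atoms)
        prov[[a + 1L]] <- c(prov[[a + 1L]], bit)
    }
  }
  out <- new("AtomWeightMap", smiles = map@smiles, weights = w,
             provenance = lapply(prov, function(p) sort(unique(p))),
             nModels = 1L)
  skipped <- map@unmappable[s[map@unmappable + 1L] != 0]
  attr(out, "skippedBits") <- skipped
  out
}

#' Average atom-weight maps over consensus members
#'
#' @param maps list of [AtomWeightMap-class] for the same molecule.
#' @return an [AtomWeightMap-class] with per-atom arithmetic means and
#'   `nModels` = total number of contributing models.
#' @export
aggregateOverModels <- function(maps) {
  stopifnot(length(maps) >= 1L)
  smiles <- unique(vapply(maps, canonicalSmiles, character(1)))
  if (length(smiles) != 1L)
    stop("atom-weight maps describe different molecules")
  W <- vapply(maps, atomWeightValues, numeric(length(maps[[1]]@weights)))
  W <- matrix(W, ncol = length(maps))
  prov <- lapply(seq_len(nrow(W)), function(a)
    sort(unique(unlist(lapply(maps, function(m) m@provenance[[a]])))))
  new("AtomWeightMap", smiles = smiles, weights = rowMeans(W),
      provenance = prov,
      nModels = sum(vapply(maps, function(m) m@nModels, integer(1))))
}

#' @rdname atomWeightValues
#' @export
setMethod("atomWeightValues", "AtomWeightMap", function(object)
  object@weights)

setMethod("show", "AtomWeightMap", function(object) {
  cat(sprintf("AtomWeightMap for %s (%d atoms, %d models)\n",
              object@smiles, length(object@weights), object@nModels))
  top <- order(-abs(object@weights))[seq_len(min(3, length(object@weights)))]
  cat(sprintf("  top |fw|: %s\n",
              paste(sprintf("atom %d = %+.4f", top - 1L,
                            object@weights[top]), collapse = ", ")))
})

#' Explain a compound with the best consensus combination
#'
#' End-to-end local explanation: for every member of the consensus
#' combination, Kernel SHAP scores are computed on the member's own
#' fingerprint family against a seeded background subsample of the
#' training set, ring-count bit scores are cluster-pruned (PubChem
#' family), scores are retro-mapped onto atoms, and the per-model maps
#' are averaged into the final atom-weight map.
#'
#' @param ensemble a [ModelEnsemble-class] (from [trainEnsemble()], with
#'   training fingerprints attached) or one carrying `trainSmiles`.
#' @param members member model ids (a [ConsensusResult-class] or
#'   character vector).
#' @param smiles a single SMILES to explain.
#' @param trainSmiles training-set SMILES for the SHAP background; not
#'   needed when `ensemble` still carries its training fingerprints.
#' @param nBackground background subsample size (default 50).
#' @param nsamples Kernel SHAP coalition budget (`"auto"` = 2M + 2048).
#' @param seed integer seed (background subsample + coalition sampling).
#' @return the aggregated [AtomWeightMap-class]; per-model maps and
#'   feature scores are attached as attributes `"perModel"` and
#'   `"featureScores"`.
#' @export
explainCompound <- function(ensemble, members, smiles,
                            trainSmiles = NULL, nBackground = 50L,
                            nsamples = "auto", seed = 1L) {
  stopifnot(is(ensemble, "ModelEnsemble"), length(smiles) == 1L)
  ids <- if (is(members, "ConsensusResult")) members@members else members
  stopifnot(all(ids %in% modelIds(ensemble)))
  mol <- standardizeSmiles(smiles)
  fams <- unique(vapply(ensemble@models[ids], fpFamily, character(1)))
  trainFps <- attr(ensemble, "fingerprints")
  if (is.null(trainFps)) {
    if (is.null(trainSmiles))
      stop("supply trainSmiles: the ensemble carries no training ",
           "fingerprints for the SHAP background")
    trainMols <- standardizeSmiles(trainSmiles)
    trainFps <- lapply(fams, function(fam)
      computeFingerprints(trainMols, fam,
                          params = ensemble@familyParamsList[[fam]]))
    names(trainFps) <- fams
  }
  nTrain <- nMolecules(trainFps[[fams[1]]])
  bgIdx <- withSeed(seed,
                    sample.int(nTrain, min(nBackground, nTrain)))
  molFps <- lapply(fams, function(fam)
    computeFingerprints(mol, fam,
                        params = ensemble@familyParamsList[[fam]]))
  names(molFps) <- fams
  maps <- list()
  allScores <- list()
  for (id in ids) {
    model <- ensemble@models[[id]]
    fam <- fpFamily(model)
    bg <- fingerprintMatrix(trainFps[[fam]])[bgIdx, , drop = FALSE]
    sc <- featureScores(model, molFps[[fam]], bg, nsamples = nsamples,
                        seed = seed)
    bam <- bitAtomMap(mol, fam,
                      params = ensemble@familyParamsList[[fam]])
    onBits <- which(fingerprintMatrix(molFps[[fam]])[1, ] == 1L) - 1L
    sc <- clusterRingBits(sc, onBits, family = fam)
    allScores[[id]] <- sc
    maps[[id]] <- atomWeights(bam, sc)
  }
  out <- aggregateOverModels(maps)
  attr(out, "perModel") <- maps
  attr(out, "featureScores") <- allScores
  out
}

#' Render an atom-weight map on the structure
#'
#' Draws the molecule as SVG with a signed color scale (red = toward
#' toxicity, blue = toward nontoxicity) and writes a machine-readable
#' JSON sidecar `{"atom_index": weight, ...}`. If drawing fails, the
#' sidecar is still emitted.
#'
#' @param map an [AtomWeightMap-class].
#' @param svgPath output SVG path (NULL to skip drawing).
#' @param jsonPath output JSON sidecar path (NULL to skip).
#' @return list with `svg` (path or NA) and `json` (path or NA),
#'   invisibly.
#' @export
renderAtomWeights <- function(map, svgPath = NULL, jsonPath = NULL) {
  stopifnot(is(map, "AtomWeightMap"))
  jsonOut <- NA_character_
  if (!is.null(jsonPath)) {
    sidecar <- as.list(map@weights)
    names(sidecar) <- as.character(seq_along(map@weights) - 1L)
    jsonlite::write_json(
      list(smiles = map@smiles, n_models = map@nModels,
           atom_weights = sidecar),
      jsonPath, auto_unbox = TRUE, digits = NA)
    jsonOut <- jsonPath
  }
  svgOut <- NA_character_
  if (!is.null(svgPath)) {
    res <- tryCatch(
      rdkitCall("depict", list(smiles = map@smiles,
                               weights = map@weights)),
      error = function(e) {
        warning("structure drawing failed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) {
      writeLines(res$svg, svgPath)
      svgOut <- svgPath
    }
  }
  invisible(list(svg = svgOut, json = jsonOut))
}
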