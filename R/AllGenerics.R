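#' Probability score of toxicity
#'
#' @param object a [TrainedClassifier-class].
#' @param newdata a 0/1 fingerprint matrix (compounds x bits) of the
#'   model's family, or a [FingerprintSet-class].
#' @param ... unused.
#' @return numeric vector of PS in \[0,1\]; toxic iff PS >= 0.5.
#' @export
setGeneric("predictPS", function(object, newdata, ...)
  standardGeneric("predictPS"))

#' Number of molecules in a container
#' @param object a MoleculeSet or FingerprintSet.
#' @export
setGeneric("nMolecules", function(object) standardGeneric("nMolecules"))

#' Canonical SMILES of a container
#' @param object a MoleculeSet, FingerprintSet, BitAtomMap or AtomWeightMap.
#' @export
setGeneric("canonicalSmiles", function(object)
  standardGeneric("canonicalSmiles"))

#' Fingerprint family identifier
#' @param object a FingerprintSet, BitAtomMap or TrainedClassifier.
#' @export
setGeneric("fpFamily", function(object) standardGeneric("fpFamily"))

#' Atom weights of an AtomWeightMap
#' @param object an [AtomWeightMap-class].
#' @export
setGeneric("atomWeightValues", function(object)
  standardGeneric("atomWeightValues"))

#' Member model ids of a consensus combination
#' @param object a [ConsensusResult-class].
#' @export
setGeneric("consensusMembers", function(object)
  standardGeneric("consensusMembers"))

#' Performance metrics of a consensus combination
#' @param object a [ConsensusResult-class].
#' @export
setGeneric("consensusMetrics", function(object)
  standardGeneric("consensusMetrics"))
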