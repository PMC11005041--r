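#' @import methods
NULL

#' Parsed, standardized small molecules
#'
#' A `MoleculeSet` holds one or more molecules that survived SMILES
#' standardization: parsing, retention of the largest covalent fragment and
#' canonicalization through RDKit. Atom indices used throughout the package
#' are 0-based heavy-atom indices of the canonical molecule.
#'
#' @slot rawSmiles character, the SMILES as supplied.
#' @slot canonicalSmiles character, canonical isomeric SMILES.
#' @slot nAtoms integer, heavy-atom count per molecule.
#' @slot ids character, user-facing identifiers (default the canonical
#'   SMILES).
#'
#' @seealso [standardizeSmiles()]
#' @export
setClass("MoleculeSet",
  representation(rawSmiles = "character", canonicalSmiles = "character",
                 nAtoms = "integer", ids = "character"),
  validity = function(object) {
    n <- length(object@canonicalSmiles)
    if (length(object@rawSmiles) != n || length(object@nAtoms) != n ||
        length(object@ids) != n)
      return("slot lengths differ")
    if (n > 0 && any(object@nAtoms < 1L))
      return("every molecule must have at least one heavy atom")
    TRUE
  })

#' Binary fingerprint matrix for one family
#'
#' Rows are compounds (in the order of the originating [MoleculeSet]),
#' columns are bits. Bits are stored as a dense 0/1 integer matrix whose
#' column count equals the family's fixed length (Morgan: 1024, PubChem
#' layout: 881, path-based topological: configurable, default 2048).
#'
#' @slot family character, one of `"MORGAN"`, `"PATH_TOPOLOGICAL"`,
#'   `"PUBCHEM"`.
#' @slot bits 0/1 integer matrix, compounds x bits.
#' @slot smiles character, canonical SMILES per row.
#' @slot params list, family parameters (radius, bit length, path sizes).
#'
#' @export
setClass("FingerprintSet",
  representation(family = "character", bits = "matrix",
                 smiles = "character", params = "list"),
  validity = function(object) {
    if (!object@family %in% fingerprintFamilies())
      return("unknown fingerprint family")
    if (nrow(object@bits) != length(object@smiles))
      return("row/smiles length mismatch")
    if (!all(object@bits %in% c(0L, 1L)))
      return("bits must be 0/1")
    TRUE
  })

#' Bit-to-atom correspondence map for one molecule
#'
#' For every on-bit of a fingerprint, the list of atom-index sets (one set
#' per occurrence of the underlying substructure/environment) that set the
#' bit. On-bits with no heavy-atom correspondence (e.g. hydrogen-count
#' keys) are recorded as unmappable rather than silently dropped.
#'
#' @slot family character, fingerprint family.
#' @slot smiles character, canonical SMILES of the molecule.
#' @slot nAtoms integer, heavy-atom count.
#' @slot entries named list: bit index (as character, 0-based) -> list of
#'   integer vectors of 0-based atom indices, one vector per occurrence.
#' @slot unmappable integer, on-bits with no atom correspondence.
#'
#' @export
setClass("BitAtomMap",
  representation(family = "character", smiles = "character",
                 nAtoms = "integer", entries = "list",
                 unmappable = "integer"),
  validity = function(object) {
    for (occ in object@entries) {
      if (!length(occ)) return("mapped bit with zero occurrences")
      for (a in occ) {
        if (any(a < 0L) || any(a >= object@nAtoms))
          return("atom index out of range")
      }
    }
    TRUE
  })

#' A fitted (algorithm x fingerprint family) binary toxicity classifier
#'
#' Emits a probability score PS in \[0,1\] per compound; the class label is
#' toxic iff PS >= 0.5. The `fit` slot holds the algorithm-specific fitted
#' state; use [predictPS()] rather than touching it.
#'
#' @slot algorithm character, one of `"RF"`, `"SVM"`, `"KNN"`, `"MLP"`.
#' @slot family character, fingerprint family the model consumes.
#' @slot hyperparams list, the selected hyperparameter setting.
#' @slot fit list, fitted state.
#' @slot familyParams list, fingerprint parameters used at train time.
#' @slot seed integer, training seed.
#' @slot cv list, cross-validation summary (may be empty).
#'
#' @export
setClass("TrainedClassifier",
  representation(algorithm = "character", family = "character",
                 hyperparams = "list", fit = "list", familyParams = "list",
                 seed = "integer", cv = "list"),
  validity = function(object) {
    if (!object@algorithm %in% c("RF", "SVM", "KNN", "MLP"))
      return("unknown algorithm")
    if (!object@family %in% fingerprintFamilies())
      return("unknown fingerprint family")
    TRUE
  })

#' One consensus combination and its performance
#'
#' A subset (size >= 2) of an ensemble's models; its consensus score CS per
#' compound is the arithmetic mean of the member probability scores, and a
#' compound is labeled toxic iff CS >= 0.5.
#'
#' @slot members character, member model ids.
#' @slot cs numeric, consensus score per evaluated compound.
#' @slot metrics list, five-statistic performance report.
#'
#' @export
setClass("ConsensusResult",
  representation(members = "character", cs = "numeric", metrics = "list"),
  validity = function(object) {
    if (length(object@members) < 2) return("a consensus needs >= 2 members")
    if (anyDuplicated(object@members)) return("duplicate member ids")
    if (length(object@cs) && (any(object@cs < 0) || any(object@cs > 1)))
      return("CS out of [0,1]")
    TRUE
  })

#' Signed per-atom contribution weights for one molecule
#'
#' Atom weights fw aggregate Shapley feature scores retro-mapped through
#' the bit-atom correspondence: positive weights push the prediction toward
#' toxicity, negative toward nontoxicity. Atoms untouched by any mapped
#' feature have weight 0.
#'
#' @slot smiles character, canonical SMILES.
#' @slot weights numeric, one signed weight per heavy atom (0-based order).
#' @slot provenance list, per-atom contributing bit indices.
#' @slot nModels integer, number of consensus members averaged.
#'
#' @export
setClass("AtomWeightMap",
  representation(smiles = "character", weights = "numeric",
                 provenance = "list", nModels = "integer"),
  validity = function(object) {
    if (any(!is.finite(object@weights))) return("non-finite atom weight")
    TRUE
  })
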