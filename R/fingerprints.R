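#' Supported fingerprint families
#'
#' Three binary fingerprint families encode each compound: `MORGAN`
#' (circular environments of radius 2 hashed to 1024 bits),
#' `PATH_TOPOLOGICAL` (the RDKit path-based topological fingerprint,
#' subgraphs of 1--7 bonds hashed to 2048 bits by default) and `PUBCHEM`
#' (the 881-bit substructure-key layout, see [pubchemKeyTable()]).
#'
#' @return character vector of family identifiers.
#' @export
fingerprintFamilies <- function() c("MORGAN", "PATH_TOPOLOGICAL", "PUBCHEM")

#' Default parameters of a fingerprint family
#'
#' @param family one of [fingerprintFamilies()].
#' @return list with at least `nbits`; Morgan adds `radius`, the path
#'   fingerprint adds `min_path`/`max_path`.
#' @export
familyParams <- function(family) {
  family <- match.arg(family, fingerprintFamilies())
  switch(family,
    MORGAN = list(nbits = 1024L, radius = 2L),
    PATH_TOPOLOGICAL = list(nbits = 2048L, min_path = 1L, max_path = 7L),
    PUBCHEM = list(nbits = 881L))
}

#' Standardize SMILES into a MoleculeSet
#'
#' Parses each SMILES with RDKit, keeps the largest covalent fragment,
#' and canonicalizes (stereochemistry retained, no tautomer
#' canonicalization). Identical structures written differently map to the
#' same canonical SMILES. Unparsable inputs either abort with the
#' offending input echoed (default) or are dropped with a warning.
#'
#' @param smiles character vector of raw SMILES; must be non-empty
#'   strings.
#' @param ids optional identifiers (default: the input SMILES).
#' @param onError `"stop"` (default) or `"drop"` — per-record failures
#'   never silently yield records.
#' @return a [MoleculeSet-class]. With `onError = "drop"`, the dropped
#'   inputs are attached as attribute `"failures"` (data.frame
#'   `raw`/`error`).
#' @examples
#' \dontrun{
#' mols <- standardizeSmiles(c("c1ccccc1", "C1=CC=CC=C1"))
#' canonicalSmiles(mols)  # both rows identical
#' }
#' @export
standardizeSmiles <- function(smiles, ids = NULL, onError = c("stop", "drop")) {
  onError <- match.arg(onError)
  if (length(smiles) == 0)
    return(new("MoleculeSet", rawSmiles = character(), ids = character(),
               canonicalSmiles = character(), nAtoms = integer()))
  stopifnot(is.character(smiles))
  if (is.null(ids)) ids <- smiles
  stopifnot(length(ids) == length(smiles))
  res <- rdkitCall("standardize", list(smiles = as.list(smiles)))
  ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
  if (any(!ok)) {
    bad <- data.frame(
      raw = vapply(res[!ok], function(r)
        if (is.null(r$raw)) NA_character_ else as.character(r$raw),
        character(1)),
      error = vapply(res[!ok], function(r) r$error, character(1)),
      stringsAsFactors = FALSE)
    if (onError == "stop")
      stop("SMILES standardization failed for: ",
           paste(sprintf("'%s' (%s)", bad$raw, bad$error), collapse = "; "))
    warning(sum(!ok), " SMILES dropped during standardization")
  } else bad <- NULL
  out <- new("MoleculeSet",
             rawSmiles = smiles[ok], ids = as.character(ids)[ok],
             canonicalSmiles = vapply(res[ok], `[[`, character(1),
                                      "canonical"),
             nAtoms = vapply(res[ok], function(r) as.integer(r$n_atoms),
                             integer(1)))
  if (!is.null(bad)) attr(out, "failures") <- bad
  out
}

#' Compute a fingerprint family for a set of molecules
#'
#' @param mols a [MoleculeSet-class] (or character vector of SMILES,
#'   standardized on the fly).
#' @param family one of [fingerprintFamilies()].
#' @param params family parameters, default [familyParams()]. The bit
#'   length is fixed per family for a whole experiment.
#' @return a [FingerprintSet-class]; deterministic for a given canonical
#'   SMILES and family.
#' @export
computeFingerprints <- function(mols, family, params = familyParams(family)) {
  family <- match.arg(family, fingerprintFamilies())
  if (is.character(mols)) mols <- standardizeSmiles(mols)
  stopifnot(is(mols, "MoleculeSet"))
  smiles <- mols@canonicalSmiles
  payload <- c(list(smiles = as.list(smiles), family = family,
                    atom_map = FALSE), params)
  if (family == "PUBCHEM") payload$keys <- pubchemKeysPayload()
  res <- rdkitCall("fingerprint", payload)
  nbits <- as.integer(params$nbits)
  m <- matrix(0L, nrow = length(smiles), ncol = nbits)
  for (i in seq_along(res)) {
    if (!isTRUE(res[[i]]$ok))
      stop("fingerprint failed for '", smiles[i], "'")
    b <- unlist(res[[i]]$bits)
    if (length(b)) {
      if (any(b >= nbits)) stop("bit index out of range")
      m[i, b + 1L] <- 1L
    }
  }
  colnames(m) <- sprintf("bit%04d", 0:(nbits - 1L))
  new("FingerprintSet", family = family, bits = m, smiles = smiles,
      params = params)
}

#' Map fingerprint on-bits back to atoms
#'
#' For one molecule, returns the atoms that set each on-bit: for
#' `MORGAN`, the atoms of each hashed circular environment (center plus
#' neighborhood); for `PATH_TOPOLOGICAL`, the atoms of each hashed bond
#' subgraph; for `PUBCHEM`, the atoms matched by the bit's key
#' (substructure matching), one atom set per distinct occurrence. Hash
#' collisions retain all contributing environments as separate
#' occurrences. On-bits with no heavy-atom correspondence (hydrogen-count
#' keys) are recorded as unmappable.
#'
#' @param mol a single-molecule [MoleculeSet-class] or one SMILES.
#' @param family one of [fingerprintFamilies()].
#' @param params family parameters; must match the ones used for the
#'   [FingerprintSet-class] being explained.
#' @return a [BitAtomMap-class].
#' @export
bitAtomMap <- function(mol, family, params = familyParams(family)) {
  family <- match.arg(family, fingerprintFamilies())
  if (is.character(mol)) mol <- standardizeSmiles(mol)
  stopifnot(is(mol, "MoleculeSet"), nMolecules(mol) == 1L)
  payload <- c(list(smiles = as.list(mol@canonicalSmiles), family = family,
                    atom_map = TRUE), params)
  if (family == "PUBCHEM") payload$keys <- pubchemKeysPayload()
  res <- rdkitCall("fingerprint", payload)[[1]]
  if (!isTRUE(res$ok)) stop("fingerprint failed for bit-atom mapping")
  entries <- lapply(res$atom_map, function(occ)
    lapply(occ, function(a) as.integer(unlist(a))))
  new("BitAtomMap", family = family, smiles = mol@canonicalSmiles,
      nAtoms = mol@nAtoms, entries = entries,
      unmappable = as.integer(unlist(res$unmappable)))
}

#' On-bits recorded in a BitAtomMap
#' @param map a [BitAtomMap-class].
#' @return 0-based integer bit indices (mapped and unmappable).
#' @export
mappedBits <- function(map) {
  stopifnot(is(map, "BitAtomMap"))
  sort(unique(c(as.integer(names(map@entries)), map@unmappable)))
}

#' Occurrence count of a bit in a BitAtomMap
#' @param map a [BitAtomMap-class].
#' @param bit 0-based bit index.
#' @return number of occurrences (atom sets) recorded for the bit.
#' @export
nOccurrences <- function(map, bit) {
  occ <- map@entries[[as.character(bit)]]
  if (is.null(occ)) 0L else length(occ)
}

# ------------------------------------------------------------- accessors

#' @rdname nMolecules
#' @export
setMethod("nMolecules", "MoleculeSet", function(object)
  length(object@canonicalSmiles))

#' @rdname nMolecules
#' @export
setMethod("nMolecules", "FingerprintSet", function(object)
  nrow(object@bits))

#' @rdname canonicalSmiles
#' @export
setMethod("canonicalSmiles", "MoleculeSet", function(object)
  object@canonicalSmiles)

#' @rdname canonicalSmiles
#' @export
setMethod("canonicalSmiles", "FingerprintSet", function(object)
  object@smiles)

#' @rdname canonicalSmiles
#' @export
setMethod("canonicalSmiles", "BitAtomMap", function(object) object@smiles)

#' @rdname canonicalSmiles
#' @export
setMethod("canonicalSmiles", "AtomWeightMap", function(object)
  object@smiles)

#' @rdname fpFamily
#' @export
setMethod("fpFamily", "FingerprintSet", function(object) object@family)

#' @rdname fpFamily
#' @export
setMethod("fpFamily", "BitAtomMap", function(object) object@family)

#' @rdname fpFamily
#' @export
setMethod("fpFamily", "TrainedClassifier", function(object) object@family)

#' Fingerprint bit matrix
#' @param fp a [FingerprintSet-class].
#' @return 0/1 integer matrix, compounds x bits.
#' @export
fingerprintMatrix <- function(fp) {
  stopifnot(is(fp, "FingerprintSet"))
  fp@bits
}

setMethod("show", "MoleculeSet", function(object) {
  cat("MoleculeSet with", nMolecules(object), "molecules\n")
  n <- min(3L, nMolecules(object))
  if (n > 0)
    cat(paste0("  ", utils::head(object@canonicalSmiles, n),
               collapse = "\n"), if (nMolecules(object) > n) "\n  ..." else "",
        "\n", sep = "")
})

setMethod("show", "FingerprintSet", function(object) {
  cat(sprintf("FingerprintSet [%s]: %d molecules x %d bits (density %.3f)\n",
              object@family, nrow(object@bits), ncol(object@bits),
              mean(object@bits)))
})

setMethod("show", "BitAtomMap", function(object) {
  cat(sprintf(
    "BitAtomMap [%s] for %s: %d mapped bits, %d unmappable\n",
    object@family, object@smiles, length(object@entries),
    length(object@unmappable)))
})

# ------------------------------------------------------------------- I/O

#' Write / read a fingerprint matrix as CSV
#'
#' One row per compound (column `smiles` first), one 0/1 column per bit.
#'
#' @param fp a [FingerprintSet-class].
#' @param path output CSV path.
#' @export
writeFingerprintCSV <- function(fp, path) {
  stopifnot(is(fp, "FingerprintSet"))
  df <- data.frame(smiles = fp@smiles, fp@bits, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a bit-atom map as JSON
#'
#' Dialect: `{"bit": [[atom, ...], [atom, ...]], ...}` with 0-based atom
#' indices, one inner list per occurrence; unmappable on-bits are listed
#' under `"unmappable"`.
#'
#' @param map a [BitAtomMap-class].
#' @param path output JSON path.
#' @export
writeBitAtomMapJSON <- function(map, path) {
  stopifnot(is(map, "BitAtomMap"))
  obj <- list(smiles = map@smiles, family = map@family,
              entries = map@entries, unmappable = map@unmappable)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
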