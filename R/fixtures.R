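# Seeded synthetic datasets with a planted toxicophore.
#
# Molecules are assembled from a fixed grammar of ~16 drug-like
# aromatic scaffolds x 30 substituents, which guarantees chemical
# validity without a generative model. The toxic class carries a
# planted toxicophore (default: an aromatic nitro group); the label is
# assigned by actually substructure-matching the toxicophore on the
# assembled molecule, then optionally flipped by label noise. Fixtures
# test pipeline mechanics, not real toxicology.

# scaffolds with substitution tokens R1 (aromatic) and R2
.fixtureScaffolds <- function() {
  data.frame(
    smiles = c(
      "c1ccc(R1)cc1R2", "c1cc(R1)ccc1R2", "c1ccc2cc(R1)ccc2c1R2",
      "c1cc(R1)cnc1R2", "c1cc(R1)sc1R2", "c1cc(R1)oc1R2",
      "c1cc(R1)n(C)c1R2", "c1cc(R2)ccc1-c1ccc(R1)cc1",
      "c1cc(R1)cc(R2)c1", "Cc1cc(R1)ccc1R2", "COc1ccc(R1)cc1R2",
      "OCc1ccc(R1)cc1R2", "c1cc(R1)c(R2)cc1C",
      "C1CCC(c2ccc(R1)cc2R2)CC1", "c1cc(R1)ccc1CCR2",
      "Fc1cc(R1)ccc1R2"),
    r2Aromatic = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                   TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

.fixtureSubstituents <- function() {
  c("C", "CC", "CCC", "C(C)C", "CCCC", "O", "OC", "OCC", "N", "NC",
    "N(C)C", "F", "Cl", "Br", "I", "C(=O)O", "C(=O)OC", "C(=O)N",
    "C(=O)C", "C=O", "C#N", "S", "SC", "S(=O)(=O)C", "C(F)(F)F",
    "OC(=O)C", "CO", "CCO", "C=C", "CC#N")
}

.fillScaffold <- function(scaffold, r1, r2) {
  s <- sub("R1", r1, scaffold, fixed = TRUE)
  sub("R2", r2, s, fixed = TRUE)
}

#' Specification of a synthetic fixture dataset
#'
#' @param nCompounds total number of molecules (>= 20).
#' @param toxicophore SMARTS of the planted substructure; the default is
#'   an aromatic nitro group, a classical structural alert.
#' @param toxicophoreSmiles SMILES fragment grafted onto the toxic
#'   class's scaffolds (must match `toxicophore` once attached).
#' @param labelNoise probability in \[0, 0.5) of flipping each label
#'   after substructure labeling.
#' @param classBalance target fraction of the nontoxic class (default
#'   0.70, emulating the roughly 70/30 imbalance of curated binary
#'   toxicity endpoint tables).
#' @param seed integer seed; generation is a pure function of this spec.
#' @return list of class `"FixtureSpec"`.
#' @export
fixtureSpec <- function(nCompounds = 300L, toxicophore = "c[N+](=O)[O-]",
                        toxicophoreSmiles = "[N+](=O)[O-]",
                        labelNoise = 0, classBalance = 0.70, seed = 1L) {
  stopifnot(nCompounds >= 20L, labelNoise >= 0, labelNoise < 0.5,
            classBalance > 0, classBalance < 1)
  structure(list(nCompounds = as.integer(nCompounds),
                 toxicophore = toxicophore,
                 toxicophoreSmiles = toxicophoreSmiles,
                 labelNoise = labelNoise, classBalance = classBalance,
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

#' Generate a labeled synthetic dataset
#'
#' Samples unique scaffold/substituent combinations for each class,
#' assembles and canonicalizes the molecules, labels them by
#' substructure-matching the planted toxicophore, and applies label
#' noise. Reproducible: the output is a pure function of the
#' [fixtureSpec()].
#'
#' @param spec a [fixtureSpec()].
#' @return data.frame with canonical `smiles` and 0/1 `label`;
#'   attributes: `"spec"`, `"matches"` (per-molecule list of toxicophore
#'   match atom sets, 0-based) and `"cleanLabel"` (labels before noise).
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  sc <- .fixtureScaffolds()
  subs <- .fixtureSubstituents()
  tox <- spec$toxicophoreSmiles
  # candidate pools: toxic = toxicophore in one (aromatic) slot
  toxic <- character()
  for (i in seq_len(nrow(sc))) {
    toxic <- c(toxic,
               vapply(subs, function(s)
                 .fillScaffold(sc$smiles[i], tox, s), character(1)))
    if (sc$r2Aromatic[i])
      toxic <- c(toxic,
                 vapply(subs, function(s)
                   .fillScaffold(sc$smiles[i], s, tox), character(1)))
  }
  nontoxic <- character()
  for (i in seq_len(nrow(sc)))
    nontoxic <- c(nontoxic, as.vector(outer(subs, subs, function(a, b)
      mapply(function(x, y) .fillScaffold(sc$smiles[i], x, y), a, b))))
  nNon <- round(spec$nCompounds * spec$classBalance)
  nTox <- spec$nCompounds - nNon
  if (nTox < 1L || nNon < 1L)
    stop("both classes must be represented; adjust nCompounds/balance")
  pick <- function(pool, n, seedOff) {
    if (length(pool) < n)
      stop("molecule grammar too small for ", n, " unique compounds")
    withSeed(spec$seed + seedOff, sample(pool, min(length(pool),
                                                   ceiling(n * 1.2))))
  }
  candTox <- pick(unique(toxic), nTox, 0L)
  candNon <- pick(unique(nontoxic), nNon, 100L)
  mols <- standardizeSmiles(c(candTox, candNon))
  can <- canonicalSmiles(mols)
  keep <- !duplicated(can)
  isTox <- c(rep(TRUE, length(candTox)), rep(FALSE, length(candNon)))[keep]
  can <- can[keep]
  takeTox <- which(isTox)[seq_len(nTox)]
  takeNon <- which(!isTox)[seq_len(nNon)]
  if (anyNA(takeTox) || anyNA(takeNon))
    stop("grammar produced too few unique molecules after deduplication")
  smiles <- can[c(takeTox, takeNon)]
  matches <- matchSubstructure(smiles, spec$toxicophore)
  labelClean <- as.integer(lengths(matches) > 0)
  if (sum(labelClean) == 0L)
    stop("toxicophore '", spec$toxicophore,
         "' cannot be planted by the molecule grammar")
  label <- labelClean
  if (spec$labelNoise > 0) {
    flip <- withSeed(spec$seed + 200L,
                     stats::runif(length(label)) < spec$labelNoise)
    label <- as.integer(xor(label == 1L, flip))
  }
  ord <- withSeed(spec$seed + 300L, sample.int(length(smiles)))
  out <- data.frame(smiles = smiles[ord], label = label[ord],
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  attr(out, "matches") <- matches[ord]
  attr(out, "cleanLabel") <- labelClean[ord]
  out
}

#' Substructure matches of a SMARTS pattern
#'
#' @param smiles character vector of SMILES.
#' @param smarts one SMARTS pattern.
#' @return list (one element per molecule) of lists of 0-based atom
#'   index vectors, one per distinct match; empty list = no match.
#' @export
matchSubstructure <- function(smiles, smarts) {
  res <- rdkitCall("match", list(smiles = as.list(smiles),
                                 smarts = smarts))
  lapply(res, function(r) {
    if (!isTRUE(r$ok)) stop("unparsable SMILES in match: ", r$smiles)
    lapply(r$matches, function(m) as.integer(unlist(m)))
  })
}

#' The four worked-example compounds
#'
#' Known toxicants used for qualitative demonstration of the
#' explanation pipeline: aflatoxin B1 (carcinogenicity), 6-ketoestrone
#' (estrogenicity), trimethylolpropane triacrylate (skin irritation)
#' and ethyl-parathion (acute oral toxicity; its thiophosphate P=S
#' linkage is the expected toxicophore).
#'
#' @return data.frame with `name` and `smiles`.
#' @export
workedExamples <- function() {
  data.frame(
    name = c("aflatoxin B1", "6-ketoestrone",
             "trimethylolpropane triacrylate", "ethyl-parathion"),
    smiles = c(
      "COc1cc2c(c3oc(=O)c4c(c13)CCC4=O)C1C=COC1O2",
      "CC12CCC3c4ccc(O)cc4C(=O)CC3C1CCC2=O",
      "CCC(COC(=O)C=C)(COC(=O)C=C)COC(=O)C=C",
      "CCOP(=S)(OCC)Oc1ccc(cc1)[N+](=O)[O-]"),
    stringsAsFactors = FALSE)
}
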