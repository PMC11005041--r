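# SMILES standardization, the three fingerprint families and their
# bit-to-atom correspondence maps.

test_that("standardization canonicalizes, rejects bad input, strips salts", {
  m <- standardizeSmiles(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_equal(canonicalSmiles(m)[1], canonicalSmiles(m)[2])
  expect_equal(m@nAtoms, c(6L, 6L))

  expect_error(standardizeSmiles(""), "empty")
  expect_error(standardizeSmiles("C(C)(C)(C)(C)C"), "unparsable")
  expect_error(standardizeSmiles("not_a_smiles"), "not_a_smiles")

  # largest covalent fragment is kept
  salt <- standardizeSmiles("CC(=O)O.[Na+]")
  expect_equal(canonicalSmiles(salt), canonicalSmiles(standardizeSmiles("CC(=O)O")))

  # drop mode keeps the good records and reports the failures
  expect_warning(
    mixed <- standardizeSmiles(c("CCO", "xyz"), onError = "drop"),
    "dropped")
  expect_equal(nMolecules(mixed), 1L)
  expect_equal(attr(mixed, "failures")$raw, "xyz")
})

test_that("fingerprint length contracts hold for any valid molecule", {
  mols <- standardizeSmiles(c("C", "CCO", "c1ccccc1",
                              workedExamples()$smiles))
  for (fam in fingerprintFamilies()) {
    fp <- computeFingerprints(mols, fam)
    expected <- c(MORGAN = 1024L, PATH_TOPOLOGICAL = 2048L,
                  PUBCHEM = 881L)[[fam]]
    expect_identical(ncol(fingerprintMatrix(fp)), expected)
    expect_true(all(fingerprintMatrix(fp) %in% c(0L, 1L)))
  }
})

test_that("fingerprints are deterministic and match frozen references", {
  m <- standardizeSmiles(c("C", "CCO"))
  fp1 <- computeFingerprints(m, "MORGAN")
  fp2 <- computeFingerprints(m, "MORGAN")
  expect_identical(fingerprintMatrix(fp1), fingerprintMatrix(fp2))
  # frozen independent reference: methane has exactly one Morgan
  # environment (radius 0), hashed to bit 240 at 1024 bits; ethanol has 6
  expect_identical(unname(which(fingerprintMatrix(fp1)[1, ] == 1L) - 1L),
                   240L)
  expect_identical(sum(fingerprintMatrix(fp1)[2, ]), 6L)
})

test_that("Morgan bit-atom map covers every heavy atom", {
  # radius-0 environments exist for every atom, so the union of all
  # mapped atoms must be the full heavy-atom set
  parathion <- workedExamples()$smiles[4]
  mol <- standardizeSmiles(parathion)
  map <- bitAtomMap(mol, "MORGAN")
  covered <- sort(unique(unlist(map@entries)))
  expect_identical(covered, 0:(mol@nAtoms - 1L))
})

test_that("benzene PubChem mapping respects ring symmetry", {
  mol <- standardizeSmiles("c1ccccc1")
  map <- bitAtomMap(mol, "PUBCHEM")
  tab <- pubchemKeyTable()
  ringBits <- tab$bit[tab$kind == "ring"]
  onRing <- intersect(as.integer(names(map@entries)), ringBits)
  expect_gt(length(onRing), 0)
  for (bit in onRing) {
    atoms <- sort(unique(unlist(map@entries[[as.character(bit)]])))
    expect_identical(atoms, 0:5)  # all six equivalent carbons
  }
})

test_that("PubChem occurrence counts equal distinct substructure matches", {
  tab <- pubchemKeyTable()
  methylBit <- tab$bit[!is.na(tab$smarts) & tab$smarts == "[CH3]"]
  # p-xylene: two methyl groups -> n_occ = 2, each a singleton atom set
  mol <- standardizeSmiles("Cc1ccc(C)cc1")
  map <- bitAtomMap(mol, "PUBCHEM")
  expect_identical(nOccurrences(map, methylBit), 2L)
  occ <- map@entries[[as.character(methylBit)]]
  expect_true(all(lengths(occ) == 1L))
  ref <- matchSubstructure(canonicalSmiles(mol), "[CH3]")[[1]]
  expect_identical(length(ref), 2L)
  expect_setequal(unlist(occ), unlist(ref))
})

test_that("hydrogen-count bits are flagged unmappable, not dropped", {
  map <- bitAtomMap(standardizeSmiles("CCCC"), "PUBCHEM")
  # butane has >= 8 H: bits 0 and 1 are on but have no heavy atoms
  expect_true(all(c(0L, 1L) %in% map@unmappable))
  expect_false(any(c("0", "1") %in% names(map@entries)))
})

test_that("PubChem key table is well-formed", {
  tab <- pubchemKeyTable()
  expect_identical(nrow(tab), 881L)
  expect_identical(tab$bit, 0:880)
  # ring block occupies exactly bits 115-262
  expect_identical(tab$bit[tab$kind == "ring"], 115:262)
  # clusters partition the ring block
  cl <- ringBitClusters()
  expect_identical(sort(unlist(cl, use.names = FALSE)), 115:262)
  # every SMARTS key parses
  smarts <- tab$smarts[!is.na(tab$smarts)]
  chk <- ToxConsensus:::rdkitCall("check_smarts",
                                  list(smarts = as.list(smarts)))
  expect_true(all(vapply(chk, function(x) isTRUE(x$ok), logical(1))))
})

test_that("fingerprint CSV and bit-atom JSON round out the I/O contract", {
  m <- standardizeSmiles(c("CCO", "c1ccccc1"))
  fp <- computeFingerprints(m, "MORGAN")
  csv <- tempfile(fileext = ".csv")
  writeFingerprintCSV(fp, csv)
  back <- read.csv(csv, check.names = FALSE)
  expect_identical(back$smiles, canonicalSmiles(m))
  expect_identical(unname(as.matrix(back[, -1])),
                   unname(fingerprintMatrix(fp)))
  map <- bitAtomMap(standardizeSmiles("CCO"), "MORGAN")
  js <- tempfile(fileext = ".json")
  writeBitAtomMapJSON(map, js)
  obj <- jsonlite::read_json(js)
  expect_identical(sort(names(obj$entries)), sort(names(map@entries)))
})
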