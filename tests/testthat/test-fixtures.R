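# Synthetic dataset generator and the bundled worked examples.

test_that("generation is a pure function of the spec", {
  spec <- fixtureSpec(nCompounds = 40, seed = 3)
  d1 <- generateDataset(spec)
  d2 <- generateDataset(spec)
  expect_identical(d1$smiles, d2$smiles)
  expect_identical(d1$label, d2$label)
  d3 <- generateDataset(fixtureSpec(nCompounds = 40, seed = 4))
  expect_false(identical(d1$smiles, d3$smiles))
})

test_that("noise-free labels equal toxicophore presence", {
  d <- generateDataset(fixtureSpec(nCompounds = 60, labelNoise = 0,
                                   seed = 5))
  matches <- matchSubstructure(d$smiles, "c[N+](=O)[O-]")
  expect_identical(d$label, as.integer(lengths(matches) > 0))
  expect_true(all(table(d$label) >= 1))  # both classes represented
})

test_that("label noise flips substructure labels, XOR-style", {
  d <- generateDataset(fixtureSpec(nCompounds = 100, labelNoise = 0.2,
                                   seed = 6))
  clean <- attr(d, "cleanLabel")
  matches <- matchSubstructure(d$smiles, "c[N+](=O)[O-]")
  expect_identical(clean, as.integer(lengths(matches) > 0))
  flips <- sum(d$label != clean)
  expect_gt(flips, 5)   # ~20 expected
  expect_lt(flips, 40)
})

test_that("class balance tracks the target fraction", {
  d <- generateDataset(fixtureSpec(nCompounds = 200, classBalance = 0.7,
                                   seed = 7))
  expect_equal(mean(d$label == 0), 0.7, tolerance = 0.02)
  d2 <- generateDataset(fixtureSpec(nCompounds = 200,
                                    classBalance = 0.5, seed = 7))
  expect_equal(mean(d2$label == 0), 0.5, tolerance = 0.02)
})

test_that("structures are unique and chemically valid", {
  d <- generateDataset(fixtureSpec(nCompounds = 80, seed = 8))
  expect_identical(anyDuplicated(d$smiles), 0L)
  # canonical already: re-standardization is the identity
  again <- canonicalSmiles(standardizeSmiles(d$smiles))
  expect_identical(again, d$smiles)
})

test_that("a toxicophore the grammar cannot plant is rejected", {
  expect_error(
    generateDataset(fixtureSpec(nCompounds = 40, toxicophore = "[#78]",
                                seed = 1)),
    "cannot be planted")
})

test_that("worked examples parse and contain the expected anchors", {
  we <- workedExamples()
  expect_identical(nrow(we), 4L)
  mols <- standardizeSmiles(we$smiles)
  expect_identical(nMolecules(mols), 4L)
  expect_true(all(mols@nAtoms >= 1))
  # ethyl-parathion carries a thiophosphate P=S bond
  ps <- matchSubstructure(we$smiles[4], "P=S")[[1]]
  expect_length(ps, 1)
  # trimethylolpropane triacrylate has three acrylate groups
  acr <- matchSubstructure(we$smiles[3], "C=CC(=O)O")[[1]]
  expect_length(acr, 3)
})
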