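# Endpoint labeling rules, refinement and the random split.

test_that("androgenicity rule needs binding plus reporter evidence", {
  expect_identical(labelAndrogenicity(TRUE, TRUE, FALSE), 1L)
  expect_identical(labelAndrogenicity(FALSE, FALSE, TRUE), 0L)
  # binding without reporter confirmation is indeterminate
  expect_identical(labelAndrogenicity(TRUE, FALSE, FALSE), NA_integer_)
  expect_error(labelAndrogenicity(logical(), logical(), logical()),
               "no assay evidence")
  expect_error(labelAndrogenicity(TRUE, FALSE, TRUE), "contradictory")
})

test_that("skin rule: strictly above 2.3, or irreversible corrosion", {
  expect_identical(labelSkin(2.4), 1L)
  expect_identical(labelSkin(2.3), 0L)   # threshold itself is nontoxic
  expect_identical(labelSkin(0, irreversibleCorrosion = TRUE), 1L)
  expect_error(labelSkin(-0.1), "negative")
})

test_that("eye rule: damage to any tissue labels toxic", {
  expect_identical(labelEye(TRUE, TRUE, TRUE), 1L)
  expect_identical(labelEye(FALSE, FALSE, FALSE), 0L)
  expect_identical(labelEye(FALSE, TRUE, FALSE), 1L)
})

test_that("oral rule: toxic iff LD50 strictly below 2000 mg/kg", {
  expect_identical(labelOral(1999), 1L)
  expect_identical(labelOral(2000), 0L)
  expect_identical(labelOral(50), 1L)
  expect_error(labelOral(0), "positive")
})

test_that("refinement collapses duplicates and drops conflicts entirely", {
  rec <- data.frame(
    smiles = c("CCO", "CCO", "CCN", "CCC", "CCC", "CCS"),
    label = c(1L, 1L, 0L, 1L, 0L, 1L))
  out <- refineDataset(rec)
  expect_identical(sort(out$smiles), c("CCN", "CCO", "CCS"))
  expect_false("CCC" %in% out$smiles)  # conflicting labels: both dropped
  rep <- attr(out, "report")
  expect_identical(rep$nInconsistentStructures, 1L)
  expect_identical(rep$nInconsistentRecords, 2L)
  expect_identical(rep$nDuplicatesRemoved, 1L)
  # all-unique input is untouched
  uniq <- data.frame(smiles = c("C", "CC", "CCC"), label = c(1L, 0L, 1L))
  expect_identical(refineDataset(uniq)$smiles, uniq$smiles)
})

test_that("random split is disjoint, exhaustive and reproducible", {
  rec <- data.frame(smiles = sprintf("mol%03d", 1:100), label = rep(0:1, 50))
  sp <- randomSplit(rec, trainFraction = 0.8, seed = 42)
  expect_identical(nrow(sp$train), 80L)
  expect_identical(nrow(sp$test), 20L)
  expect_length(intersect(sp$train$smiles, sp$test$smiles), 0)
  expect_setequal(c(sp$train$smiles, sp$test$smiles), rec$smiles)
  sp2 <- randomSplit(rec, trainFraction = 0.8, seed = 42)
  expect_identical(sp$train$smiles, sp2$train$smiles)
  expect_error(randomSplit(rec[1:3, ]), "too few")
})

test_that("an endpoint-sized table splits to the published 80/20 sizes", {
  # 2842 records at 80/20 gives the 2274/568 train/test pattern
  rec <- data.frame(smiles = sprintf("m%04d", 1:2842),
                    label = rep(c(0L, 0L, 1L), length.out = 2842))
  sp <- randomSplit(rec, trainFraction = 0.8, seed = 1)
  expect_identical(nrow(sp$train), 2274L)
  expect_identical(nrow(sp$test), 568L)
})

test_that("compound files round-trip through CSV and .smi", {
  rec <- data.frame(smiles = c("CCO", "c1ccccc1"), label = c(1L, 0L))
  csv <- tempfile(fileext = ".csv")
  writeCompounds(rec, csv)
  expect_identical(readCompounds(csv), rec)
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "c1ccccc1 mol2"), smi)
  got <- readCompounds(smi)
  expect_identical(got$smiles, rec$smiles)
  expect_identical(got$id, c("mol1", "mol2"))
})
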