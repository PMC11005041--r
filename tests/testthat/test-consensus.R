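# Consensus scoring, exhaustive combination scanning and selection.

# independent oracle: subsets of {1..n} with size >= kMin, via the
# binary powerset
powersetOracle <- function(n, kMin = 2) {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  subsets <- apply(grid, 1, which, simplify = FALSE)
  Filter(function(s) length(s) >= kMin, subsets)
}

test_that("combination counts match the printed constants", {
  expect_equal(countCombinations(12, 2, 12), 4083)
  expect_equal(countCombinations(20, 2, 20), 1048555)
  expect_equal(countCombinations(2, 2, 2), 1)
  expect_error(countCombinations(5, 3, 2), "invalid")
})

test_that("closed form and enumeration agree with the powerset oracle", {
  for (n in 2:20) expect_equal(countCombinations(n), 2^n - n - 1)
  for (n in 2:8) {
    oracle <- powersetOracle(n)
    expect_equal(countCombinations(n), length(oracle))
    enum <- ToxConsensus:::enumerateCombinations(n)
    expect_equal(length(enum), length(oracle))
    key <- function(s) paste(sort(s), collapse = ",")
    expect_setequal(vapply(enum, key, character(1)),
                    vapply(oracle, key, character(1)))
  }
})

test_that("consensus score is the mean PS with an inclusive 0.5 bound", {
  expect_equal(consensusScore(c(0.6, 0.6)),
               list(cs = 0.6, label = 1L))
  expect_equal(consensusScore(c(0.4, 0.6)),
               list(cs = 0.5, label = 1L))  # 0.5 classifies toxic
  expect_equal(consensusScore(c(0.2, 0.3, 0.4)),
               list(cs = 0.3, label = 0L))
  expect_error(consensusScore(0.7), ">= 2")
  # permutation invariance in the members
  ps <- matrix(c(0.1, 0.9, 0.4, 0.2, 0.8, 0.6), nrow = 3)
  expect_equal(consensusScore(ps)$cs,
               consensusScore(ps[c(3, 1, 2), ])$cs)
})

test_that("a toy 4-model scan enumerates 11 combinations", {
  ps <- rbind(A = c(0.9, 0.1, 0.8, 0.2), B = c(0.7, 0.3, 0.6, 0.4),
              C = c(0.8, 0.2, 0.9, 0.1), D = c(0.2, 0.8, 0.3, 0.7))
  test <- data.frame(smiles = paste0("m", 1:4), label = c(1, 0, 1, 0))
  res <- exhaustiveScan(ps, test)
  expect_identical(nrow(res), 11L)  # sum_{k=2}^{4} C(4,k)
  expect_true(all(res$k >= 2 & res$k <= 4))
  # A, B, C agree perfectly with the labels; D is inverted
  expect_equal(res$mcc[res$members == "A+B+C"], 1)
})

test_that("identical members reproduce the single model's predictions", {
  one <- c(0.9, 0.1, 0.55, 0.45)
  ps <- rbind(M1 = one, M2 = one, M3 = one)
  sc <- consensusScore(ps)
  expect_equal(sc$cs, one)
  expect_identical(sc$label, psLabel(one))
})

test_that("selection maximizes MCC with size-then-lexicographic ties", {
  res <- data.frame(
    members = c("A+B", "A+B+C+D+E+F+G", "A+C", "B+C+D"),
    k = c(2, 7, 2, 3),
    precision = 1, recall = 1, specificity = 1, accuracy = 1,
    mcc = c(0.8, 0.9, 0.9, 0.9))
  best <- selectBest(res)
  expect_identical(consensusMembers(best), c("A", "C"))  # size 2 < 3 < 7
  expect_equal(consensusMetrics(best)$mcc, 0.9)
  # equal MCC and size: lexicographically smallest member tuple
  res2 <- res[c(1, 3), ]
  res2$mcc <- 0.9
  expect_identical(consensusMembers(selectBest(res2)), c("A", "B"))
})

test_that("the full scan ranks 4083 combinations on the fixture ensemble", {
  ranked <- sharedScan()
  expect_identical(nrow(ranked), 4083L)
  expect_identical(max(ranked$k), 12L)
  expect_true(!is.unsorted(rev(ranked$mcc)))
  # reported metrics are consistent with recomputation for the top row
  best <- sharedBest()
  ps <- sharedTestPS()[consensusMembers(best), , drop = FALSE]
  m <- classificationMetrics(sharedSplit()$test$label,
                             consensusScore(ps)$label)
  expect_equal(m$mcc, consensusMetrics(best)$mcc)
})
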