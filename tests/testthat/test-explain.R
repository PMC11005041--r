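# Bit retro-mapping: ring-bit clustering, the atom-weight formula and
# aggregation over consensus members.

# construct a BitAtomMap directly (synthetic, no chemistry needed)
mkMap <- function(entries, nAtoms, unmappable = integer()) {
  new("BitAtomMap", family = "PUBCHEM", smiles = "synthetic",
      nAtoms = as.integer(nAtoms), entries = entries,
      unmappable = as.integer(unmappable))
}

mkScores <- function(scores) list(modelId = "toy", scores = scores,
                                  base = 0.4, ps = 0.4 + sum(scores))

test_that("ring-bit clustering keeps exactly the max score per cluster", {
  cl <- list(g1 = c(120L, 121L, 122L), g2 = c(130L, 131L))
  s <- numeric(881)
  s[c(120, 121, 122) + 1] <- c(0.2, 0.5, 0.1)
  s[c(130, 131) + 1] <- c(0.3, 0.3)  # tie
  out <- clusterRingBits(mkScores(s), onBits = c(120L, 121L, 122L, 130L,
                                                 131L),
                         family = "PUBCHEM", clusters = cl)
  expect_equal(out$scores[121 + 1], 0.5)
  expect_equal(out$scores[c(120, 122) + 1], c(0, 0))
  # tie: deterministic lowest-index winner
  expect_equal(out$scores[130 + 1], 0.3)
  expect_equal(out$scores[131 + 1], 0)
  # non-PubChem input passes through unchanged
  same <- clusterRingBits(mkScores(s), onBits = 120:131,
                          family = "MORGAN", clusters = cl)
  expect_equal(same$scores, s)
  # molecule with no on ring bits: unchanged
  noRing <- clusterRingBits(mkScores(s), onBits = c(400L),
                            family = "PUBCHEM", clusters = cl)
  expect_equal(noRing$scores, s)
})

test_that("the atom-weight formula reproduces forced hand values", {
  s <- numeric(881)
  s[10 + 1] <- 0.30
  # one feature, 2 atoms, 1 occurrence -> each atom +0.15
  m1 <- atomWeights(mkMap(list("10" = list(c(0L, 1L))), nAtoms = 4),
                    mkScores(s))
  expect_equal(atomWeightValues(m1), c(0.15, 0.15, 0, 0))
  # one feature, 2 atoms per occurrence, 2 occurrences -> +0.075 each
  m2 <- atomWeights(mkMap(list("10" = list(c(0L, 1L), c(2L, 3L))),
                          nAtoms = 4), mkScores(s))
  expect_equal(atomWeightValues(m2), rep(0.075, 4))
  # overlapping features: the shared atom sums both contributions
  s2 <- numeric(881)
  s2[c(10, 20) + 1] <- c(0.30, 0.10)
  m3 <- atomWeights(mkMap(list("10" = list(c(0L, 1L)),
                               "20" = list(c(1L, 2L))), nAtoms = 3),
                    mkScores(s2))
  expect_equal(atomWeightValues(m3), c(0.15, 0.20, 0.05))
})

test_that("conservation holds for non-overlapping single-occurrence maps", {
  withr::local_seed(13)
  for (rep in 1:20) {
    nAtoms <- sample(4:12, 1)
    # partition the atoms into disjoint features
    atoms <- sample(0:(nAtoms - 1))
    cuts <- sort(sample(seq_len(nAtoms - 1), sample(1:3, 1)))
    groups <- split(atoms, findInterval(seq_len(nAtoms) - 1, cuts))
    bits <- sample(300:800, length(groups))
    entries <- stats::setNames(
      lapply(groups, function(g) list(as.integer(g))),
      as.character(bits))
    s <- numeric(881)
    s[bits + 1] <- round(rnorm(length(bits), sd = 0.3), 3)
    awm <- atomWeights(mkMap(entries, nAtoms), mkScores(s))
    expect_equal(sum(atomWeightValues(awm)), sum(s), tolerance = 1e-12)
  }
})

test_that("sign is preserved for atoms in purely positive features", {
  s <- numeric(881)
  s[c(5, 6) + 1] <- c(0.2, 0.4)
  awm <- atomWeights(mkMap(list("5" = list(c(0L, 1L)),
                                "6" = list(c(1L, 2L))), nAtoms = 3),
                     mkScores(s))
  expect_true(all(atomWeightValues(awm) >= 0))
})

test_that("unmappable on-bits with scores are skipped and reported", {
  s <- numeric(881)
  s[0 + 1] <- 0.5  # hydrogen-count bit: on, scored, but unmappable
  s[10 + 1] <- 0.2
  awm <- atomWeights(mkMap(list("10" = list(0L)), nAtoms = 2,
                           unmappable = 0L), mkScores(s))
  expect_equal(atomWeightValues(awm), c(0.2, 0))
  expect_identical(attr(awm, "skippedBits"), 0L)
})

test_that("aggregation averages atom weights across members", {
  a <- new("AtomWeightMap", smiles = "synthetic", weights = c(0.2, 0),
           provenance = list(1L, integer()), nModels = 1L)
  b <- new("AtomWeightMap", smiles = "synthetic", weights = c(-0.2, 0.1),
           provenance = list(2L, 3L), nModels = 1L)
  agg <- aggregateOverModels(list(a, b))
  expect_equal(atomWeightValues(agg), c(0, 0.05))
  expect_identical(agg@nModels, 2L)
  # identity cases
  expect_equal(atomWeightValues(aggregateOverModels(list(a))),
               atomWeightValues(a))
  expect_equal(atomWeightValues(aggregateOverModels(list(a, a))),
               atomWeightValues(a))
  cc <- new("AtomWeightMap", smiles = "other", weights = 0.1,
            provenance = list(integer()), nModels = 1L)
  expect_error(aggregateOverModels(list(a, cc)), "different molecules")
})

test_that("rendering emits the SVG and the JSON sidecar", {
  awm <- new("AtomWeightMap", smiles = "CCO",
             weights = c(0.3, -0.1, 0), provenance = list(1L, 2L, 3L),
             nModels = 1L)
  svg <- tempfile(fileext = ".svg")
  js <- tempfile(fileext = ".json")
  out <- renderAtomWeights(awm, svgPath = svg, jsonPath = js)
  expect_true(file.exists(js))
  side <- jsonlite::read_json(js)
  expect_equal(unlist(side$atom_weights), c(`0` = 0.3, `1` = -0.1,
                                            `2` = 0))
  expect_true(file.exists(svg))
  expect_match(readLines(svg, n = 2)[1], "xml|svg")
  # drawing failure still emits the sidecar
  bad <- new("AtomWeightMap", smiles = "CCO", weights = c(0.1, 0.1),
             provenance = list(1L, 2L), nModels = 1L)  # wrong atom count
  js2 <- tempfile(fileext = ".json")
  expect_warning(renderAtomWeights(bad, svgPath = tempfile(),
                                   jsonPath = js2), "drawing failed")
  expect_true(file.exists(js2))
})
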