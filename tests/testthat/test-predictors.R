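test_that("enumeration produces exactly the valid structures", {
  expect_equal(length(enumerateStructures("AAAAAAA")), 1L)  # only empty
  st <- enumerateStructures("GGAAACC")
  keys <- sort(vapply(st, dotBracket, character(1)))
  expect_equal(keys, sort(c(".......", "(....).", "(.....)", ".(...).",
                            ".(....)", "((...))")))
  expect_error(enumerateStructures(strrep("G", 20)), "guard")
  # appending a pairing partner never shrinks the structure set
  n1 <- length(enumerateStructures("GGAAAC"))
  n2 <- length(enumerateStructures("GGAAACC"))
  expect_gte(n2, n1)
})

test_that("MFE equals the enumeration optimum and its traceback energy", {
  p <- toyParams()
  set.seed(17)
  for (k in 1:40) {
    n <- sample(6:12, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    fr <- mfeFold(s, p)
    oracle <- enumBoltzmann(s, p)
    expect_equal(foldScore(fr), min(oracle$energies), tolerance = 1e-9)
    expect_equal(freeEnergy(s, fr@structure, p), foldScore(fr),
                 tolerance = 1e-6)
  }
  # degenerate cases
  fr0 <- mfeFold("AAAAAAA", p)
  expect_identical(foldScore(fr0), 0)
  expect_equal(nPairs(fr0@structure), 0L)
  frz <- mfeFold("GGGAAACCC", zeroParams())
  expect_identical(foldScore(frz), 0)
})

test_that("partition function matches the Boltzmann sum and counts structures", {
  p <- toyParams()
  set.seed(23)
  for (k in 1:25) {
    n <- sample(6:12, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    oracle <- enumBoltzmann(s, p)
    expect_equal(partitionZ(partitionFunction(s, p)), oracle$Z,
                 tolerance = 1e-9)
  }
  expect_equal(partitionZ(partitionFunction("AAAAAAA", p)), 1)
  # all parameters zero: Z equals the number of valid structures
  z <- zeroParams()
  for (s in c("GGAAACC", "GGGAAACCC", "GCGCAAAGCGC"))
    expect_equal(partitionZ(partitionFunction(s, z)),
                 length(enumerateStructures(s)), tolerance = 1e-9)
})

test_that("base-pair probabilities equal enumeration ratios and conserve mass", {
  p <- toyParams()
  set.seed(29)
  for (k in 1:25) {
    n <- sample(6:10, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    bpp <- basePairProbabilities(s, p)
    oracle <- enumBoltzmann(s, p)
    expect_lt(max(abs(pairProbs(bpp) - oracle$P)), 1e-9)
    expect_lt(max(abs(unpairedProbs(bpp) + rowSums(pairProbs(bpp)) - 1)), 1e-9)
  }
  # no allowed pairs: all-zero matrix, q = 1
  bpp0 <- basePairProbabilities("AAAAAAA", p)
  expect_true(all(pairProbs(bpp0) == 0))
  expect_equal(unpairedProbs(bpp0), rep(1, 7))
  # single possible pair, zero energies: two equal-weight structures
  bpp1 <- basePairProbabilities("GAAAAC", zeroParams())
  expect_equal(pairProbs(bpp1)[1, 6], 0.5, tolerance = 1e-12)
})

test_that("MEA fold maximizes the declared objective", {
  # hand example: one confident pair beats all-unpaired
  P <- matrix(0, 7, 7)
  P[1, 7] <- P[7, 1] <- 0.8
  bpp <- BasePairProbMatrix(P)
  fr <- meaFold(bpp, gamma = 1)
  expect_equal(basePairs(fr), matrix(c(1L, 7L), 1,
               dimnames = list(NULL, c("i", "j"))))
  expect_equal(foldScore(fr), 2 * 0.8 + 5 * 1, tolerance = 1e-12)
  # all-zero matrix: empty structure with score n
  bpp0 <- BasePairProbMatrix(matrix(0, 6, 6))
  fr0 <- meaFold(bpp0)
  expect_equal(nPairs(fr0@structure), 0L)
  expect_equal(foldScore(fr0), 6)
  expect_error(meaFold(bpp0, gamma = 0), "positive")
  # DP equals brute force over enumerated structures on thermodynamic matrices
  p <- toyParams()
  set.seed(31)
  for (k in 1:15) {
    s <- paste(sample(c("A", "C", "G", "U"), 10, TRUE), collapse = "")
    bpp <- basePairProbabilities(s, p)
    allst <- enumerateStructures(n = 10)
    for (g in c(0.25, 1, 4)) {
      expect_equal(foldScore(meaFold(bpp, g)),
                   bruteMeaScore(allst, pairProbs(bpp), unpairedProbs(bpp), g),
                   tolerance = 1e-9)
    }
  }
})

test_that("centroid fold maximizes its objective and respects the threshold", {
  P <- matrix(0, 7, 7)
  P[1, 7] <- P[7, 1] <- 0.8
  bpp <- BasePairProbMatrix(P)
  fr <- centroidFold(bpp, gamma = 1)
  expect_equal(foldScore(fr), 0.6, tolerance = 1e-12)  # 2*0.8 - 1
  expect_equal(nPairs(fr@structure), 1L)
  # below the 1/(gamma+1) threshold nothing is gained
  P2 <- matrix(0, 8, 8)
  P2[1, 8] <- P2[8, 1] <- 0.4
  fr2 <- centroidFold(BasePairProbMatrix(P2), gamma = 1)
  expect_equal(nPairs(fr2@structure), 0L)
  expect_equal(foldScore(fr2), 0)
  p <- toyParams()
  set.seed(37)
  for (k in 1:15) {
    s <- paste(sample(c("A", "C", "G", "U"), 10, TRUE), collapse = "")
    bpp <- basePairProbabilities(s, p)
    allst <- enumerateStructures(n = 10)
    for (g in c(0.5, 1, 6)) {
      fr <- centroidFold(bpp, g)
      expect_equal(foldScore(fr), bruteCentroidScore(allst, pairProbs(bpp), g),
                   tolerance = 1e-9)
      # gamma-threshold property: every predicted pair has p > 1/(gamma+1)
      pr <- basePairs(fr)
      if (nrow(pr)) expect_true(all(pairProbs(bpp)[pr] > 1 / (g + 1)))
    }
  }
})

test_that("pseudo-expected accuracy follows the eTP construction", {
  P <- matrix(0, 7, 7)
  P[1, 7] <- P[7, 1] <- 0.8
  bpp <- BasePairProbMatrix(P)
  S <- SecondaryStructure(7, rbind(c(1, 7)))
  pe <- pseudoExpectedAccuracy(bpp, S)
  expect_equal(unname(pe), c(1.0, 0.8, 2 * 1 * 0.8 / 1.8), tolerance = 1e-12)
  # empty candidate against mass: pseudo-F = 0
  pe0 <- pseudoExpectedAccuracy(bpp, SecondaryStructure(7))
  expect_equal(pe0[["f"]], 0)
  # structure containing every nonzero-probability pair: pseudo-sens = 1
  p <- toyParams()
  bppT <- basePairProbabilities("GGGGAAAACCCC", p)
  full <- mfeFold("GGGGAAAACCCC", p)@structure
  peT <- pseudoExpectedAccuracy(bppT, full)
  expect_lte(peT[["sensitivity"]], 1)
})

test_that("pseudo-MEA selects gamma by pseudo-F with ties to smaller gamma", {
  P <- matrix(0, 9, 9)
  P[2, 8] <- P[8, 2] <- 0.9
  bpp <- BasePairProbMatrix(P)
  fr <- pseudoMeaFold(bpp)
  # every gamma with threshold below 0.9 gives the same single-pair structure;
  # the smallest such grid gamma must be reported
  grid <- 2^(-5:10)
  expect_equal(foldGamma(fr), min(grid[1 / (grid + 1) < 0.9]))
  expect_equal(nPairs(fr@structure), 1L)
  # all-zero matrix: empty structure, smallest gamma reported
  fr0 <- pseudoMeaFold(BasePairProbMatrix(matrix(0, 6, 6)))
  expect_equal(nPairs(fr0@structure), 0L)
  expect_equal(foldGamma(fr0), 2^-5)
  expect_error(pseudoMeaFold(bpp, numeric(0)), "non-empty")
  # achieved pseudo-F is at least that of the gamma = 1 centroid
  p <- toyParams()
  set.seed(41)
  for (k in 1:5) {
    s <- paste(sample(c("A", "C", "G", "U"), 12, TRUE), collapse = "")
    bpp <- basePairProbabilities(s, p)
    f1 <- pseudoExpectedAccuracy(bpp, centroidFold(bpp, 1)@structure)[["f"]]
    expect_gte(foldScore(pseudoMeaFold(bpp)) + 1e-12, f1)
  }
})

test_that("predictions are deterministic for identical inputs", {
  p <- toyParams()
  s <- "GCGCAAUAAGCGCAAGGGCAAACCC"
  expect_identical(basePairs(mfeFold(s, p)), basePairs(mfeFold(s, p)))
  b1 <- basePairProbabilities(s, p)
  b2 <- basePairProbabilities(s, p)
  expect_identical(pairProbs(b1), pairProbs(b2))
  expect_identical(basePairs(meaFold(b1)), basePairs(meaFold(b2)))
  expect_identical(basePairs(pseudoMeaFold(b1)), basePairs(pseudoMeaFold(b2)))
})

test_that("probability matrices validate their invariants", {
  expect_error(BasePairProbMatrix(matrix(c(0, 0.5, 0.4, 0), 2, 2)),
               "symmetric|0 for")
  m <- matrix(0, 6, 6)
  m[1, 6] <- m[6, 1] <- 1.5
  expect_error(BasePairProbMatrix(m), "\\[0, 1\\]")
  m2 <- matrix(0, 6, 6)
  m2[1, 5] <- m2[5, 1] <- 0.7
  m2[1, 6] <- m2[6, 1] <- 0.7
  expect_error(BasePairProbMatrix(m2), "row sums")
})
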