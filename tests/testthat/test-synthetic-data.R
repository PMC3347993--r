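test_that("random sequences honor GC targets and seeds", {
  s0 <- randomSequence(100, gcFraction = 0, seed = 1)
  expect_false(grepl("[GC]", residues(s0)))
  expect_identical(residues(randomSequence(50, seed = 7)),
                   residues(randomSequence(50, seed = 7)))
  expect_error(randomSequence(10, gcFraction = 1.5), "gcFraction")
  gc <- vapply(1:300, function(k) {
    r <- residues(randomSequence(300, gcFraction = 0.6, seed = 1000 + k))
    mean(strsplit(r, "")[[1]] %in% c("G", "C"))
  }, numeric(1))
  expect_gt(mean(gc), 0.58)
  expect_lt(mean(gc), 0.62)
})

test_that("Boltzmann sampling reproduces the ensemble", {
  p <- toyParams()
  # no allowed pairs: always the empty structure
  draws <- sampleReferenceStructure("AAAAAAA", p, nSamples = 50, seed = 2)
  expect_true(all(vapply(draws, nPairs, integer(1)) == 0L))
  # single possible pair under the zero model: present in ~half the draws
  z <- zeroParams()
  d2 <- sampleReferenceStructure("GAAAAC", z, nSamples = 2000, seed = 3)
  frac <- mean(vapply(d2, nPairs, integer(1)) == 1L)
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
  # pair frequencies over many draws approach the inside-outside probabilities
  s <- "GGCAAAAGCC"
  P <- pairProbs(basePairProbabilities(s, p))
  d3 <- sampleReferenceStructure(s, p, nSamples = 5000, seed = 4)
  emp <- matrix(0, 10, 10)
  for (d in d3) {
    pr <- basePairs(d)
    if (nrow(pr)) emp[pr] <- emp[pr] + 1
  }
  emp <- (emp + t(emp)) / 5000
  expect_lt(max(abs(emp - P)), 0.03)
  # seeded draws are reproducible
  a <- sampleReferenceStructure(s, p, nSamples = 3, seed = 11)
  b <- sampleReferenceStructure(s, p, nSamples = 3, seed = 11)
  expect_identical(lapply(a, basePairs), lapply(b, basePairs))
})

test_that("class generation hits similarity targets and reports misses", {
  p <- toyParams()
  # similarity 1: identical members
  spec1 <- ClassSpec("ident", 5, 60, 4, similarity = 1)
  mc1 <- makeClass(spec1, p, seed = 5)
  seqs <- vapply(mc1$records, function(r) residues(r@sequence), character(1))
  expect_equal(length(unique(seqs)), 1L)
  expect_equal(mc1$achieved$similarity, 1)
  expect_equal(classSimilarity(mc1$records), 1)
  # transfer-RNA-like class: high similarity achievable
  spec2 <- ClassSpec("Transfer RNA", 60, 77.48, 4.8, similarity = 0.96)
  mc2 <- makeClass(spec2, p, seed = 6)
  expect_gte(mc2$achieved$similarity, 0.85)
  expect_equal(length(mc2$records), 60L)
  expect_true(all(vapply(mc2$records, function(r)
    r@sequence@classLabel, character(1)) == "Transfer RNA"))
  # moderate-similarity class with wide length spread
  spec3 <- ClassSpec("wide", 25, 200, 60, similarity = 0.55)
  mc3 <- makeClass(spec3, p, seed = 7)
  expect_lt(abs(mc3$achieved$similarity - 0.55), 0.15)
  # same seed regenerates the identical class
  mc2b <- makeClass(spec2, p, seed = 6)
  expect_identical(vapply(mc2b$records, function(r) residues(r@sequence),
                          character(1)),
                   vapply(mc2$records, function(r) residues(r@sequence),
                          character(1)))
  # an impossible target is reported, not silently missed
  spec4 <- ClassSpec("impossible", 6, 80, 60, similarity = 0.99)
  expect_warning(makeClass(spec4, p, seed = 8), "unattainable")
})

test_that("structure perturbation lands on its accuracy targets", {
  ref <- parseDotBracket("((((((....))))))..((((....))))")
  # roomier fixture for the stochastic calibration below
  bigref <- parseDotBracket(paste0("..((((((....))))))...((((....))))..",
                                   "(((((.....)))))....((((......))))..."))
  expect_identical(perturbStructure(ref, 1, 1), ref)
  # half sensitivity at perfect PPV: exactly half the pairs, nothing false
  half <- perturbStructure(ref, 0.5, 1, seed = 2)
  cmp <- compareStructures(ref, half)
  expect_equal(cmp[["sensitivity"]], 0.5)
  expect_equal(cmp[["ppv"]], 1)
  expect_equal(cmp[["f"]], 2 / 3)
  expect_error(perturbStructure(ref, 0, 1), "targets")
  expect_error(perturbStructure(SecondaryStructure(10), 1, 1), "non-empty")
  # stochastic calibration: mean achieved F near the target
  set.seed(9)
  fs <- vapply(1:300, function(k) {
    pert <- suppressWarnings(perturbStructure(bigref, 0.7, 0.7, seed = 2000 + k))
    compareStructures(bigref, pert)[["f"]]
  }, numeric(1))
  expect_lt(abs(mean(fs) - 0.7), 0.05)
  # sequence-restricted insertions only create allowed base pairs
  rec <- randomRecord(40, seed = 77)
  if (nPairs(rec@reference) >= 3) {
    pert <- perturbStructure(rec@reference, 0.6, 0.5, seed = 5,
                             sequence = rec@sequence)
    chars <- strsplit(residues(rec@sequence), "")[[1]]
    pr <- basePairs(pert)
    expect_true(all(paste0(chars[pr[, 1]], chars[pr[, 2]]) %in%
                    c("AU", "UA", "CG", "GC", "GU", "UG")))
  }
})

test_that("benchmark generation assembles classes, predictions and manifest", {
  specs <- list(ClassSpec("c1", 12, 50, 4, similarity = 0.8, accuracyMean = 0.68),
                ClassSpec("c2", 10, 80, 6, similarity = 0.6, accuracyMean = 0.60))
  sb <- generateBenchmark(specs, algorithms = list(
    good = list(mean = 0.8, sd = 0.08), poor = list(mean = 0.55, sd = 0.08)),
    seed = 31)
  ds <- sb@dataset
  expect_equal(vapply(datasetClasses(ds), length, integer(1)),
               c(c1 = 12L, c2 = 10L))
  expect_true(all(vapply(datasetRecords(ds), function(r)
    all(c("good", "poor") %in% names(r@predictions)), logical(1))))
  acc <- sb@manifest$achievedAccuracy
  expect_gt(mean(acc$good), mean(acc$poor))
  expect_equal(sb@manifest$seed, 31L)
  # regeneration from the manifest is bit-identical
  sb2 <- regenerateBenchmark(sb@manifest)
  expect_identical(
    lapply(datasetRecords(sb2@dataset), function(r) basePairs(r@reference)),
    lapply(datasetRecords(ds), function(r) basePairs(r@reference)))
  expect_identical(
    lapply(datasetRecords(sb2@dataset), function(r)
      lapply(r@predictions, basePairs)),
    lapply(datasetRecords(ds), function(r) lapply(r@predictions, basePairs)))
})

test_that("simulated accuracy differences drive downstream test power and size", {
  spec <- list(ClassSpec("c", 80, 60, 5, similarity = 0.7))
  # clearly separated algorithms: the permutation test nearly always rejects
  rejections <- vapply(1:12, function(k) {
    sb <- generateBenchmark(spec, algorithms = list(
      a = list(mean = 0.75, sd = 0.1), b = list(mean = 0.55, sd = 0.1)),
      seed = 4000 + k)
    f <- function(nm) vapply(datasetRecords(sb@dataset), function(r)
      compareStructures(r@reference, r@predictions[[nm]])[["f"]], numeric(1))
    permutationTest(f("a"), f("b"), sided = "two", nPermutations = 400,
                    seed = k, exhaustive = "never")@pValue < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
  # identical distributions: rejections stay near the nominal level
  null_rej <- vapply(1:40, function(k) {
    sb <- generateBenchmark(list(ClassSpec("c", 40, 40, 3, similarity = 0.7)),
                            algorithms = list(
      a = list(mean = 0.65, sd = 0.1), b = list(mean = 0.65, sd = 0.1)),
      seed = 5000 + k)
    f <- function(nm) vapply(datasetRecords(sb@dataset), function(r)
      compareStructures(r@reference, r@predictions[[nm]])[["f"]], numeric(1))
    permutationTest(f("a"), f("b"), sided = "two", nPermutations = 300,
                    seed = k, exhaustive = "never")@pValue < 0.05
  }, logical(1))
  expect_lte(mean(null_rej), 0.15)
})
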