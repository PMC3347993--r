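test_that("structure comparison counts exact-match pairs with the edge conventions", {
  ref <- SecondaryStructure(12, rbind(c(2, 11), c(3, 10)))
  pred <- SecondaryStructure(12, rbind(c(2, 11), c(4, 9)))
  expect_equal(unname(compareStructures(ref, pred)), c(0.5, 0.5, 0.5))
  expect_equal(unname(compareStructures(ref, ref)), c(1, 1, 1))
  empty <- SecondaryStructure(12)
  expect_equal(unname(compareStructures(empty, empty)), c(1, 1, 1))
  expect_equal(unname(compareStructures(ref, empty)), c(0, 0, 0))
  expect_equal(unname(compareStructures(empty, ref)), c(0, 0, 0))
  expect_error(compareStructures(ref, SecondaryStructure(11)), "length")
  # a shifted pair is not a match (no slippage)
  shifted <- SecondaryStructure(12, rbind(c(2, 10)))
  expect_equal(compareStructures(ref, shifted)[["sensitivity"]], 0)
})

test_that("F is symmetric in argument swap and monotone in sensitivity", {
  set.seed(19)
  for (k in 1:10) {
    a <- randomRecord(30, seed = 300 + k)@reference
    b <- randomRecord(30, seed = 400 + k)@reference
    expect_equal(compareStructures(a, b)[["f"]], compareStructures(b, a)[["f"]])
  }
  f <- function(s, p) 2 * s * p / (s + p)
  s <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(f(s, 0.6)) > 0))
  expect_true(all(f(s, 0.6) <= (s + 0.6) / 2 + 1e-12))
})

test_that("the three averages implement their defining formulas", {
  one <- list(ClassAccuracy("a", c(0.2, 0.4, 0.6)))
  expect_equal(unweightedAverage(one), 0.4)
  expect_equal(weightedAverage(one), 0.4)
  # size-independence of the unweighted average
  two <- list(ClassAccuracy("a", rep(0.2, 97)), ClassAccuracy("b", 0.8))
  expect_equal(unweightedAverage(two), 0.5)
  expect_equal(weightedAverage(two), (97 * 0.2 + 0.8) / 98)
  # equal sizes: weighted equals unweighted
  eq <- list(ClassAccuracy("a", c(0.1, 0.3)), ClassAccuracy("b", c(0.5, 0.9)))
  expect_equal(weightedAverage(eq), unweightedAverage(eq))
  expect_error(unweightedAverage(list()), "at least one")
  expect_error(ClassAccuracy("a", numeric(0)), "size")
  expect_error(ClassAccuracy("a", 0.5, similarity = 1.2), "similarity")
})

test_that("S-weighted average hits its two limit identities on random configs", {
  set.seed(43)
  for (k in 1:25) {
    n <- sample(2:8, 1)
    sizes <- sample(1:50, n, replace = TRUE)
    cls0 <- lapply(seq_len(n), function(i)
      ClassAccuracy(paste0("c", i), stats::runif(sizes[i]), similarity = 0))
    expect_equal(sWeightedAverage(cls0), weightedAverage(cls0),
                 tolerance = 1e-12)
    cls1 <- lapply(cls0, function(cl) { cl@similarity <- 1; cl })
    expect_equal(sWeightedAverage(cls1), unweightedAverage(cls1),
                 tolerance = 1e-12)
    # equal size and similarity: all three coincide
    m <- sample(2:10, 1)
    s <- stats::runif(1)
    clsE <- lapply(seq_len(n), function(i)
      ClassAccuracy(paste0("c", i), stats::runif(m), similarity = s))
    expect_equal(sWeightedAverage(clsE), unweightedAverage(clsE),
                 tolerance = 1e-12)
    expect_equal(weightedAverage(clsE), unweightedAverage(clsE),
                 tolerance = 1e-12)
  }
})

test_that("normalized similarity is 1 on identity, symmetric, and in [0,1]", {
  r1 <- makeRecord("GGGAAACCC", "(((...)))")
  expect_equal(normalizedSimilarity(r1, r1), 1)
  set.seed(47)
  for (k in 1:10) {
    a <- randomRecord(sample(20:50, 1), seed = 500 + k)
    b <- randomRecord(sample(20:50, 1), seed = 600 + k)
    s1 <- normalizedSimilarity(a, b)
    s2 <- normalizedSimilarity(b, a)
    expect_identical(s1, s2)
    expect_gte(s1, 0)
    expect_lte(s1, 1)
  }
  # disjoint pair sets and dissimilar sequences score low
  a <- makeRecord("GGGGAAAACCCCAAAAAAA", "((((....)))).......")
  b <- makeRecord("AAAAAAAAUUGGGAAACCC", "........((((...))))")
  expect_lt(normalizedSimilarity(a, b), 0.5)
})

test_that("class similarity averages pairwise scores and honors conventions", {
  recs <- replicate(3, makeRecord("GGGAAACCC", "(((...)))"), simplify = FALSE)
  expect_equal(classSimilarity(recs), 1)
  expect_equal(classSimilarity(recs[1]), 1)  # size-1 convention
  expect_error(classSimilarity(list()), "empty")
  # the mean over unordered pairs, checked through a stubbed similarity
  stub <- function(a, b) {
    key <- sort(c(a@sequence@id, b@sequence@id))
    c("r1 r2" = 0.2, "r1 r3" = 0.4, "r2 r3" = 0.6)[[paste(key, collapse = " ")]]
  }
  recs3 <- lapply(1:3, function(i) makeRecord("GGGAAACCC", "(((...)))", paste0("r", i)))
  expect_equal(classSimilarity(recs3, simFun = stub), 0.4)
})

test_that("replacing a member by a copy of another never decreases class similarity", {
  set.seed(53)
  for (k in 1:8) {
    recs <- lapply(1:4, function(i) randomRecord(25, seed = 700 + 10 * k + i))
    s0 <- classSimilarity(recs)
    recs[[4]] <- recs[[1]]
    expect_gte(classSimilarity(recs) + 1e-9, s0)
  }
})
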