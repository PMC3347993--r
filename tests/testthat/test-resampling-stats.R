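test_that("bootstrap CI collapses on constant data and is seeded-deterministic", {
  r <- bootstrapPercentileCI(rep(0.7, 50), nResamples = 200, seed = 1)
  expect_equal(r@lower, 0.7)
  expect_equal(r@upper, 0.7)
  expect_equal(r@pointEstimate, 0.7)
  expect_equal(r@normalityFlag, "degenerate")
  set.seed(99)
  v <- stats::runif(80)
  r1 <- bootstrapPercentileCI(v, nResamples = 250, seed = 4)
  r2 <- bootstrapPercentileCI(v, nResamples = 250, seed = 4)
  expect_identical(r1@distribution, r2@distribution)
  expect_identical(r1@seed, 4L)
  expect_error(bootstrapPercentileCI(numeric(0)), "non-empty")
  expect_error(bootstrapPercentileCI(1:5, level = 1.2), "level")
})

test_that("bootstrap width matches the normal approximation on a binary sample", {
  vals <- rep(c(0, 1), each = 500)
  r <- bootstrapPercentileCI(vals, nResamples = 4000, level = 0.95, seed = 7)
  expect_gt(r@lower, 0.4)
  expect_lt(r@upper, 0.6)
  # analytic width 2 * 1.96 * 0.5 / sqrt(1000) ~ 0.062
  expect_equal(r@upper - r@lower, 0.062, tolerance = 0.17)
  # n = 2000 from Normal(0.68, 0.15^2): width ~ 2*1.96*0.15/sqrt(2000) ~ 0.013
  set.seed(8)
  v2 <- stats::rnorm(2000, 0.68, 0.15)
  r2 <- bootstrapPercentileCI(v2, nResamples = 4000, seed = 8)
  expect_equal(r2@upper - r2@lower, 2 * 1.96 * 0.15 / sqrt(2000),
               tolerance = 0.1)
})

test_that("bootstrap width shrinks like 1/sqrt(n)", {
  set.seed(12)
  widths <- sapply(1:4, function(k) {
    v1 <- stats::rnorm(1000, 0.7, 0.2)
    v4 <- stats::rnorm(4000, 0.7, 0.2)
    r1 <- bootstrapPercentileCI(v1, nResamples = 1500, seed = 20 + k)
    r4 <- bootstrapPercentileCI(v4, nResamples = 1500, seed = 50 + k)
    (r4@upper - r4@lower) / (r1@upper - r1@lower)
  })
  expect_gt(mean(widths), 0.45)
  expect_lt(mean(widths), 0.55)
})

test_that("class-aware bootstrap recomputes the requested average per resample", {
  set.seed(31)
  vals <- c(stats::rnorm(40, 0.6, 0.05), stats::rnorm(10, 0.9, 0.05))
  labs <- rep(c("big", "small"), c(40, 10))
  sims <- c(big = 0.9, small = 0.2)
  ru <- bootstrapPercentileCI(vals, labs, average = "unweighted",
                              nResamples = 800, seed = 3)
  rw <- bootstrapPercentileCI(vals, labs, average = "weighted",
                              nResamples = 800, seed = 3)
  # the unweighted point estimate sits near 0.75, the weighted near 0.66
  expect_equal(ru@pointEstimate,
               unweightedAverage(classAccuracyTable(vals, labs)), tolerance = 1e-12)
  expect_equal(rw@pointEstimate, mean(vals), tolerance = 1e-12)
  expect_gt(ru@pointEstimate, rw@pointEstimate)
  rs <- bootstrapPercentileCI(vals, labs, similarities = sims,
                              average = "s_weighted", nResamples = 400, seed = 3)
  expect_equal(rs@pointEstimate,
               sWeightedAverage(classAccuracyTable(vals, labs, sims)),
               tolerance = 1e-12)
  expect_error(bootstrapPercentileCI(vals, average = "unweighted"), "labels")
})

test_that("Anderson-Darling diagnostic calibrates on Gaussian and skewed samples", {
  set.seed(61)
  gauss <- replicate(100, andersonDarlingNormality(stats::rnorm(400))$rejected)
  expect_gte(mean(!gauss), 0.9)
  expo <- replicate(40, andersonDarlingNormality(stats::rexp(500))$rejected)
  expect_gte(mean(expo), 0.9)
  expect_equal(andersonDarlingNormality(rep(1, 20))$flag, "degenerate")
  expect_error(andersonDarlingNormality(1:5), "at least 8")
})

test_that("permutation test handles the textbook cases", {
  # identical constant sets: every permuted difference equals the observed 0
  r <- permutationTest(rep(1, 4), rep(1, 4), sided = "one",
                       alternative = "A_less", seed = 2)
  expect_equal(r@pValue, 1)
  # exhaustive two-sided on {1,2,3} vs {4,5,6}: only the two extreme splits
  r2 <- permutationTest(c(1, 2, 3), c(4, 5, 6), sided = "two",
                        exhaustive = "always")
  expect_identical(r2@pValue, 0.1)
  expect_true(r2@exhaustive)
  expect_equal(r2@observedDiff, -3)
  expect_equal(r2@nPermutations, 20L)
  # correctly oriented one-sided: half the enumeration p of the two-sided here
  r3 <- permutationTest(c(1, 2, 3), c(4, 5, 6), sided = "one",
                        alternative = "A_less", exhaustive = "always")
  expect_identical(r3@pValue, 0.05)
  expect_error(permutationTest(numeric(0), 1:3), "non-empty")
})

test_that("exhaustive and sampled modes agree within Monte-Carlo error", {
  set.seed(71)
  A <- stats::rnorm(6, 0.6, 0.2)
  B <- stats::rnorm(7, 0.75, 0.2)
  pe <- permutationTest(A, B, sided = "two", exhaustive = "always")@pValue
  ps <- permutationTest(A, B, sided = "two", exhaustive = "never",
                        nPermutations = 6000, seed = 5)@pValue
  expect_equal(ps, pe, tolerance = 0.05)
  # two-sided >= correctly oriented one-sided on seed-matched permutations
  p1 <- permutationTest(A, B, sided = "one", alternative = "A_less",
                        exhaustive = "never", nPermutations = 4000,
                        seed = 6)@pValue
  p2 <- permutationTest(A, B, sided = "two", exhaustive = "never",
                        nPermutations = 4000, seed = 6)@pValue
  expect_gte(p2 + 1e-12, p1)
})

test_that("add-one correction bounds p away from zero", {
  A <- 1:10 / 10
  B <- A + 5
  p0 <- permutationTest(A, B, sided = "two", exhaustive = "never",
                        nPermutations = 500, seed = 3)@pValue
  p1 <- permutationTest(A, B, sided = "two", exhaustive = "never",
                        nPermutations = 500, seed = 3, addOne = TRUE)@pValue
  expect_gte(p1, 1 / 501)
  expect_lte(p0, p1)
})
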