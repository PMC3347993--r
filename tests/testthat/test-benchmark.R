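smallConfig <- function(dir = tempfile("rep"), seed = 11) {
  specs <- list(ClassSpec("c1", 10, 45, 4, similarity = 0.85, accuracyMean = 0.7),
                ClassSpec("c2", 8, 70, 6, similarity = 0.6, accuracyMean = 0.65),
                ClassSpec("c3", 5, 55, 5, similarity = 0.7, accuracyMean = 0.6))
  BenchmarkConfig(specs = specs,
                  algorithms = list(simA = list(mean = 0.72, sd = 0.1),
                                    simB = list(mean = 0.6, sd = 0.1)),
                  nResamples = 400L, nPermutations = 400L, seed = seed,
                  outputDir = dir)
}

test_that("a benchmark run emits all five report artifacts with consistent shapes", {
  dir <- tempfile("rep")
  rep <- runBenchmark(smallConfig(dir))
  expect_true(all(file.exists(file.path(dir,
    c("per_record_metrics.tsv", "class_summary.tsv", "ci_table.tsv",
      "pvalues_one_sided.tsv", "pvalues_two_sided.tsv", "run_log.txt",
      "report.json")))))
  cs <- rep$classSummary
  expect_equal(nrow(cs), 3 + 3)  # class rows + the three average rows
  expect_equal(cs$class[4:6], c("Unweighted Average", "Weighted Average",
                                "S-Weighted Average"))
  expect_equal(nrow(rep$perRecord), 23 * 2)
  expect_equal(nrow(rep$ciTable), (3 + 1) * 2)  # classes + ALL, per algorithm
  expect_true(all(rep$ciTable$lower <= rep$ciTable$upper))
  expect_true(all(is.na(diag(rep$pOneSided))))
  expect_true(all(rep$pTwoSided[!is.na(rep$pTwoSided)] >= 0 &
                  rep$pTwoSided[!is.na(rep$pTwoSided)] <= 1))
})

test_that("the average rows obey their defining relations to the class rows", {
  rep <- runBenchmark(smallConfig(tempfile("rep"), seed = 13))
  cs <- rep$classSummary
  for (alg in c("simA", "simB")) {
    classRows <- cs[1:3, ]
    m <- classRows[[alg]]
    sz <- classRows$size
    s <- classRows$similarity
    expect_equal(cs[[alg]][4], mean(m), tolerance = 1e-12)
    expect_equal(cs[[alg]][5], sum(m * sz) / sum(sz), tolerance = 1e-12)
    w <- sz^(1 - s)
    expect_equal(cs[[alg]][6], sum(w * m) / sum(w), tolerance = 1e-12)
  }
})

test_that("reruns with the same seed are byte-identical", {
  d1 <- tempfile("rep1")
  d2 <- tempfile("rep2")
  runBenchmark(smallConfig(d1, seed = 17))
  runBenchmark(smallConfig(d2, seed = 17))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("externally supplied class similarities are used verbatim", {
  cfg <- smallConfig(tempfile("rep"), seed = 19)
  cfg@classSimilarities <- c(c1 = 0.11, c2 = 0.22, c3 = 0.33)
  rep <- runBenchmark(cfg)
  expect_equal(unname(rep$similarities), c(0.11, 0.22, 0.33))
  cs <- rep$classSummary
  expect_equal(cs$similarity[1:3], c(0.11, 0.22, 0.33))
  # and they flow into the S-weighted row
  m <- cs[["simA"]][1:3]
  w <- cs$size[1:3]^(1 - c(0.11, 0.22, 0.33))
  expect_equal(cs[["simA"]][6], sum(w * m) / sum(w), tolerance = 1e-12)
  cfg@classSimilarities <- c(c1 = 0.5)
  expect_error(runBenchmark(cfg), "missing class")
})

test_that("file-mode evaluation scores predictions against references", {
  sb <- generateBenchmark(list(ClassSpec("c1", 5, 40, 0, similarity = 0.9),
                               ClassSpec("c2", 4, 55, 0, similarity = 0.8)),
                          algorithms = list(sim = list(mean = 0.7, sd = 0.1)),
                          seed = 23)
  ref <- tempfile(fileext = ".fa")
  prd <- tempfile(fileext = ".fa")
  writeBenchmarkDataset(sb@dataset, ref)
  # prediction file identical to the reference: every measure is 1
  writeBenchmarkDataset(sb@dataset, prd)
  ev <- evaluateFiles(ref, prd)
  expect_true(all(ev$perRecord$f == 1))
  expect_true(all(ev$summary$f == 1))
  # the simulated predictions score below 1 but above 0
  writeBenchmarkDataset(sb@dataset, prd, predictions = "sim")
  ev2 <- evaluateFiles(ref, prd)
  expect_true(all(ev2$perRecord$f <= 1))
  expect_gt(mean(ev2$perRecord$f), 0.3)
  expect_equal(ev2$summary$class[3:5],
               c("Unweighted Average", "Weighted Average", "S-Weighted Average"))
  # a missing record is an error naming it
  ds2 <- sb@dataset
  ds2@records <- ds2@records[-3]
  ds2@classes <- list(c1 = 1:4, c2 = 5:8)
  writeBenchmarkDataset(ds2, prd)
  expect_error(evaluateFiles(ref, prd), "c1_003")
})

test_that("real predictors can drive a file-mode benchmark", {
  sb <- generateBenchmark(list(ClassSpec("c1", 5, 60, 0, similarity = 0.9),
                               ClassSpec("c2", 5, 70, 0, similarity = 0.8)),
                          algorithms = list(sim = list(mean = 0.7, sd = 0.1)),
                          seed = 29)
  ref <- tempfile(fileext = ".fa")
  writeBenchmarkDataset(sb@dataset, ref)
  cfg <- BenchmarkConfig(datasetPath = ref,
                         algorithms = list(mfe = "mfe", mea = "mea"),
                         nResamples = 200L, nPermutations = 200L, seed = 31)
  rep <- runBenchmark(cfg)
  expect_equal(sort(unique(rep$perRecord$algorithm)), c("mea", "mfe"))
  expect_true(all(rep$perRecord$f >= 0 & rep$perRecord$f <= 1))
  # references are Boltzmann draws from the same model family the predictors
  # assume, so predictions should recover a nontrivial share of true pairs
  expect_gt(mean(rep$perRecord$f), 0.1)
})
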