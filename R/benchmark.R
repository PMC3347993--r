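## End-to-end orchestration: fold/simulate, evaluate, aggregate with the three
## averaging schemes, attach bootstrap confidence intervals and permutation
## tests, and emit report tables shaped like a benchmark study report.

#' Construct a benchmark configuration
#'
#' Either `specs` (synthetic mode) or `datasetPath` (file mode) must be
#' given. In file mode each algorithm is a character name of a built-in
#' predictor (`"mfe"`, `"mea"`, `"centroid"`, `"pseudo_mea"`) or a function
#' `(sequence, params) -> FoldResult`; in synthetic mode simulated-accuracy
#' descriptors (see [generateBenchmark()]) are also allowed.
#'
#' @param specs List of [ClassSpec-class] (synthetic mode).
#' @param datasetPath,manifestPath Reference files (file mode).
#' @param algorithms Named list (see above); defaults to the two simulated
#'   algorithms of [mtSimulatedAlgorithms()] in synthetic mode.
#' @param params An [NNParameterSet-class].
#' @param averages Subset of `c("unweighted", "weighted", "s_weighted")`.
#' @param nResamples,nPermutations,level,seed Statistical settings (defaults
#'   10000, 10000, 0.95; the seed is mandatory).
#' @param alternative One-sided permutation orientation (`"A_less"` or
#'   `"A_greater"`, with A the row algorithm of the p-value table).
#' @param classSimilarities Optional named numeric `s_i` used verbatim.
#' @param similarityMaxPairs Subsample cap for computed class similarities.
#' @param outputDir Optional report directory; created if missing.
#' @return A validated [BenchmarkConfig-class].
#' @export
BenchmarkConfig <- function(specs = list(), datasetPath = character(),
                            manifestPath = character(), algorithms = NULL,
                            params = loadParameters("toy37"),
                            averages = c("unweighted", "weighted", "s_weighted"),
                            nResamples = 10000L, nPermutations = 10000L,
                            level = 0.95, seed = 1L,
                            alternative = "A_less",
                            classSimilarities = numeric(),
                            similarityMaxPairs = 200L,
                            outputDir = character()) {
  if (is.null(algorithms))
    algorithms <- if (length(specs)) mtSimulatedAlgorithms() else list(mfe = "mfe")
  new("BenchmarkConfig", specs = specs, datasetPath = datasetPath,
      manifestPath = manifestPath, algorithms = algorithms, params = params,
      averages = averages, nResamples = as.integer(nResamples),
      nPermutations = as.integer(nPermutations), level = level,
      seed = as.integer(seed), alternative = alternative,
      classSimilarities = classSimilarities,
      similarityMaxPairs = as.integer(similarityMaxPairs),
      outputDir = outputDir)
}

.builtin_predictor <- function(name) {
  force(name)
  function(sequence, params) predictStructure(sequence, params, algorithm = name)
}

#' Run a configured benchmark end to end
#'
#' Produces (a) a per-record metrics table, (b) a per-class summary with the
#' three average rows, (c) a bootstrap CI table per class and overall,
#' (d) pairwise one- and two-sided permutation p-value tables, and (e) a run
#' log with versions and seeds. When `outputDir` is set, the tables are
#' written as TSV (3 decimals, mirroring the usual report layout) with a
#' full-precision JSON sidecar; reruns with the same configuration are
#' byte-identical. The three average rows of every emitted summary are
#' checked against the per-class rows above them before the report is
#' returned.
#'
#' @param config A [BenchmarkConfig-class].
#' @return Invisibly, a list with elements `perRecord`, `classSummary`,
#'   `ciTable`, `pOneSided`, `pTwoSided`, `similarities`, `dataset`, and
#'   (synthetic mode) `manifest`.
#' @export
runBenchmark <- function(config) {
  stopifnot(is(config, "BenchmarkConfig"))
  set.seed(config@seed)
  manifest <- NULL
  if (length(config@specs)) {
    bench <- generateBenchmark(config@specs, algorithms = config@algorithms,
                               params = config@params, seed = config@seed,
                               similarityMaxPairs = config@similarityMaxPairs)
    dataset <- bench@dataset
    manifest <- bench@manifest
    algNames <- names(config@algorithms)
  } else {
    dataset <- readBenchmarkDataset(
      config@datasetPath,
      manifest = if (length(config@manifestPath)) config@manifestPath else NULL)
    algNames <- names(config@algorithms)
    for (nm in algNames) {
      alg <- config@algorithms[[nm]]
      fun <- if (is.character(alg)) .builtin_predictor(alg) else alg
      if (!is.function(fun))
        stop("algorithm '", nm, "' must be a function or built-in name in file mode")
      for (k in seq_along(dataset@records)) {
        fr <- fun(dataset@records[[k]]@sequence, config@params)
        dataset@records[[k]]@predictions[[nm]] <- fr@structure
      }
    }
  }
  .benchmark_report(dataset, algNames, config, manifest)
}

.benchmark_report <- function(dataset, algNames, config, manifest = NULL) {
  recs <- dataset@records
  labs <- vapply(recs, function(r) r@sequence@classLabel, character(1))
  ids <- vapply(recs, function(r) r@sequence@id, character(1))
  ## per-record metrics
  rows <- list()
  fvals <- list()
  for (nm in algNames) {
    tr <- t(vapply(recs, function(r) {
      if (is.null(r@predictions[[nm]]))
        stop("record '", r@sequence@id, "' has no prediction for '", nm, "'")
      compareStructures(r@reference, r@predictions[[nm]])
    }, numeric(3)))
    fvals[[nm]] <- tr[, "f"]
    rows[[nm]] <- data.frame(record_id = ids, class = labs, algorithm = nm,
                             params = config@params@name,
                             sensitivity = tr[, "sensitivity"],
                             ppv = tr[, "ppv"], f = tr[, "f"],
                             stringsAsFactors = FALSE)
  }
  perRecord <- do.call(rbind, rows)
  rownames(perRecord) <- NULL
  ## class similarities: supplied verbatim or computed from the references
  classLabs <- names(dataset@classes)
  if (length(config@classSimilarities)) {
    miss <- setdiff(classLabs, names(config@classSimilarities))
    if (length(miss))
      stop("classSimilarities missing class(es): ", paste(miss, collapse = ", "))
    sims <- config@classSimilarities[classLabs]
  } else {
    sims <- vapply(classLabs, function(lab)
      classSimilarity(recs[dataset@classes[[lab]]],
                      maxPairs = config@similarityMaxPairs,
                      seed = config@seed), numeric(1))
    names(sims) <- classLabs
  }
  ## class summary (classes x algorithms) + three average rows
  classMeans <- vapply(algNames, function(nm)
    vapply(classLabs, function(lab)
      mean(fvals[[nm]][dataset@classes[[lab]]]), numeric(1)),
    numeric(length(classLabs)))
  classMeans <- matrix(classMeans, nrow = length(classLabs),
                       dimnames = list(classLabs, algNames))
  avgRows <- c(unweighted = "Unweighted Average",
               weighted = "Weighted Average",
               s_weighted = "S-Weighted Average")
  avgs <- vapply(algNames, function(nm) {
    cls <- classAccuracyTable(fvals[[nm]], labs, sims)
    c(unweighted = unweightedAverage(cls), weighted = weightedAverage(cls),
      s_weighted = sWeightedAverage(cls))
  }, numeric(3))
  avgs <- matrix(avgs, nrow = 3,
                 dimnames = list(names(avgRows), algNames))
  ## self-consistency of the average rows against the per-class rows
  sizes <- vapply(dataset@classes, length, integer(1))
  for (nm in algNames) {
    stopifnot(abs(avgs["unweighted", nm] - mean(classMeans[, nm])) < 1e-9,
              abs(avgs["weighted", nm] -
                  sum(classMeans[, nm] * sizes) / sum(sizes)) < 1e-9)
    w <- sizes^(1 - sims)
    stopifnot(abs(avgs["s_weighted", nm] -
                  sum(w * classMeans[, nm]) / sum(w)) < 1e-9)
  }
  classSummary <- data.frame(class = c(classLabs, unname(avgRows)),
                             size = c(sizes, NA, NA, NA),
                             similarity = c(unname(sims), NA, NA, NA),
                             rbind(classMeans, avgs),
                             check.names = FALSE, stringsAsFactors = FALSE)
  rownames(classSummary) <- NULL
  ## bootstrap CIs per class and overall
  ciRows <- list()
  groupSeeds <- config@seed + seq_len(length(classLabs) + 1L)
  for (nm in algNames) {
    for (g in seq_along(classLabs)) {
      lab <- classLabs[g]
      idx <- dataset@classes[[lab]]
      b <- bootstrapPercentileCI(fvals[[nm]][idx], average = "plain",
                                 nResamples = config@nResamples,
                                 level = config@level, seed = groupSeeds[g])
      ciRows[[length(ciRows) + 1L]] <- data.frame(
        class = lab, size = length(idx), algorithm = nm,
        estimate = b@pointEstimate, lower = b@lower, upper = b@upper,
        width = b@upper - b@lower, normality = b@normalityFlag,
        stringsAsFactors = FALSE)
    }
    b <- bootstrapPercentileCI(fvals[[nm]], classLabels = labs,
                               similarities = sims, average = "weighted",
                               nResamples = config@nResamples,
                               level = config@level,
                               seed = groupSeeds[length(groupSeeds)])
    ciRows[[length(ciRows) + 1L]] <- data.frame(
      class = "ALL", size = length(recs), algorithm = nm,
      estimate = b@pointEstimate, lower = b@lower, upper = b@upper,
      width = b@upper - b@lower, normality = b@normalityFlag,
      stringsAsFactors = FALSE)
  }
  ciTable <- do.call(rbind, ciRows)
  rownames(ciTable) <- NULL
  ## pairwise permutation tests on pooled per-record F values
  nAlg <- length(algNames)
  pOne <- matrix(NA_real_, nAlg, nAlg, dimnames = list(algNames, algNames))
  pTwo <- pOne
  for (a in seq_len(nAlg)) for (b in seq_len(nAlg)) {
    if (a == b) next
    pOne[a, b] <- permutationTest(fvals[[algNames[a]]], fvals[[algNames[b]]],
                                  sided = "one",
                                  alternative = config@alternative,
                                  nPermutations = config@nPermutations,
                                  seed = config@seed + 100L + a * nAlg + b,
                                  exhaustive = "never")@pValue
    pTwo[a, b] <- permutationTest(fvals[[algNames[a]]], fvals[[algNames[b]]],
                                  sided = "two",
                                  nPermutations = config@nPermutations,
                                  seed = config@seed + 100L + a * nAlg + b,
                                  exhaustive = "never")@pValue
  }
  report <- list(perRecord = perRecord, classSummary = classSummary,
                 ciTable = ciTable, pOneSided = pOne, pTwoSided = pTwo,
                 similarities = sims, dataset = dataset, manifest = manifest)
  if (length(config@outputDir)) .write_report(report, config)
  invisible(report)
}

.fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))

.write_report <- function(report, config) {
  dir <- config@outputDir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wtsv <- function(df, file, digits3 = names(df)[vapply(df, is.numeric, logical(1))]) {
    out <- df
    for (nm in digits3) out[[nm]] <- .fmt_num(df[[nm]])
    utils::write.table(out, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wtsv(report$perRecord, "per_record_metrics.tsv",
       c("sensitivity", "ppv", "f"))
  wtsv(report$classSummary, "class_summary.tsv",
       setdiff(names(report$classSummary), c("class", "size")))
  wtsv(report$ciTable, "ci_table.tsv",
       c("estimate", "lower", "upper", "width"))
  wmat <- function(m, file) {
    df <- data.frame(algorithm = rownames(m),
                     apply(m, 2, .fmt_num), check.names = FALSE)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wmat(report$pOneSided, "pvalues_one_sided.tsv")
  wmat(report$pTwoSided, "pvalues_two_sided.tsv")
  ## full-precision sidecar
  side <- list(classSummary = report$classSummary, ciTable = report$ciTable,
               pOneSided = report$pOneSided, pTwoSided = report$pTwoSided,
               similarities = as.list(report$similarities),
               manifest = report$manifest[c("seed", "classSeeds", "name",
                                            "params", "achievedAccuracy")])
  jsonlite::write_json(side, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  log <- c(sprintf("RNAfoldBench %s", utils::packageVersion("RNAfoldBench")),
           sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("seed: %d", config@seed),
           sprintf("params: %s", config@params@name),
           sprintf("algorithms: %s", paste(names(config@algorithms), collapse = ", ")),
           sprintf("records: %d in %d classes", nrow(report$perRecord) /
                     max(1L, length(names(config@algorithms))),
                   length(report$similarities)),
           sprintf("nResamples: %d, nPermutations: %d, level: %g",
                   config@nResamples, config@nPermutations, config@level))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Evaluate a prediction file against a reference file
#'
#' Both files are FASTA-with-structure; records are matched by identifier
#' (an unmatched record is an error naming it). Class labels come from the
#' reference file or the optional manifest.
#'
#' @param referencePath,predictionPath FASTA-with-structure files.
#' @param manifest Optional record/class manifest TSV.
#' @param similarities Optional named per-class `s_i` for the S-weighted row.
#' @return List with `perRecord` (data.frame of per-record triples),
#'   `classes` (list of [ClassAccuracy-class]) and `summary` (data.frame with
#'   per-class mean F rows and the three average rows).
#' @export
evaluateFiles <- function(referencePath, predictionPath, manifest = NULL,
                          similarities = NULL) {
  ref <- readBenchmarkDataset(referencePath, manifest = manifest)
  pred <- readBenchmarkDataset(predictionPath)
  refIds <- vapply(ref@records, function(r) r@sequence@id, character(1))
  predIds <- vapply(pred@records, function(r) r@sequence@id, character(1))
  miss <- setdiff(refIds, predIds)
  if (length(miss))
    stop("prediction file is missing record(s): ", paste(miss, collapse = ", "))
  hit <- match(refIds, predIds)
  tr <- t(vapply(seq_along(refIds), function(k)
    compareStructures(ref@records[[k]]@reference,
                      pred@records[[hit[k]]]@reference), numeric(3)))
  labs <- vapply(ref@records, function(r) r@sequence@classLabel, character(1))
  perRecord <- data.frame(record_id = refIds, class = labs,
                          sensitivity = tr[, "sensitivity"], ppv = tr[, "ppv"],
                          f = tr[, "f"], stringsAsFactors = FALSE)
  if (is.null(similarities)) {
    labsU <- names(ref@classes)
    similarities <- vapply(labsU, function(lab)
      classSimilarity(ref@records[ref@classes[[lab]]], maxPairs = 200L),
      numeric(1))
    names(similarities) <- labsU
  }
  classes <- classAccuracyTable(tr[, "f"], labs, similarities)
  means <- vapply(classes, function(cl) mean(cl@values), numeric(1))
  sizes <- vapply(classes, function(cl) cl@size, integer(1))
  summary <- data.frame(
    class = c(vapply(classes, function(cl) cl@label, character(1)),
              "Unweighted Average", "Weighted Average", "S-Weighted Average"),
    size = c(sizes, NA, NA, NA),
    f = c(means, unweightedAverage(classes), weightedAverage(classes),
          sWeightedAverage(classes)),
    stringsAsFactors = FALSE)
  list(perRecord = perRecord, classes = classes, summary = summary)
}
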