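## Generics for the core verbs. Accessors and show methods live here too.

#' Dot-bracket representation of a structure
#' @param x A [SecondaryStructure-class] or [FoldResult-class].
#' @return A dot-bracket string.
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' Base pairs of a structure
#' @param x A [SecondaryStructure-class] or [FoldResult-class].
#' @return Two-column integer matrix of 1-based pair positions.
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' Free energy of a structure under a nearest-neighbor model
#' @param sequence An [RnaSequence-class] (or character).
#' @param structure A [SecondaryStructure-class].
#' @param params An [NNParameterSet-class].
#' @return Free energy in kcal/mol; exactly 0 for the empty structure.
#' @export
setGeneric("freeEnergy",
           function(sequence, structure, params) standardGeneric("freeEnergy"))

#' Compare a predicted structure against a reference
#'
#' Sensitivity is the fraction of reference base pairs predicted, PPV the
#' fraction of predicted pairs that are in the reference (exact index match),
#' and F their harmonic mean. Conventions for empty structures: both empty
#' gives (1,1,1); exactly one empty gives 0 for the undefined ratio and F = 0.
#'
#' @param reference,predicted [SecondaryStructure-class] objects of equal length.
#' @return Named numeric `c(sensitivity, ppv, f)`.
#' @export
setGeneric("compareStructures",
           function(reference, predicted) standardGeneric("compareStructures"))

#' @export
#' @rdname dotBracket
setMethod("dotBracket", "SecondaryStructure", function(x) {
  s <- rep(".", x@n)
  if (nrow(x@pairs)) {
    s[x@pairs[, 1L]] <- "("
    s[x@pairs[, 2L]] <- ")"
  }
  paste(s, collapse = "")
})

#' @export
#' @rdname dotBracket
setMethod("dotBracket", "FoldResult", function(x) dotBracket(x@structure))

#' @export
#' @rdname basePairs
setMethod("basePairs", "SecondaryStructure", function(x) x@pairs)

#' @export
#' @rdname basePairs
setMethod("basePairs", "FoldResult", function(x) x@structure@pairs)

#' @export
setMethod("length", "SecondaryStructure", function(x) x@n)

#' @export
setMethod("length", "RnaSequence", function(x) nchar(x@residues))

#' @export
setMethod("length", "BenchmarkDataset", function(x) length(x@records))

#' Number of base pairs
#' @param x A [SecondaryStructure-class].
#' @export
nPairs <- function(x) nrow(x@pairs)

#' Residue string of an RnaSequence
#' @param x An [RnaSequence-class].
#' @export
residues <- function(x) x@residues

#' Pair probability matrix accessor
#' @param x A [BasePairProbMatrix-class].
#' @export
pairProbs <- function(x) x@p

#' Unpaired probabilities q(i) = 1 - sum_j p(i,j)
#' @param x A [BasePairProbMatrix-class].
#' @return Numeric vector of per-position unpaired probabilities (clamped at 0).
#' @export
unpairedProbs <- function(x) pmax(0, 1 - rowSums(x@p))

#' Partition function accessors
#'
#' `logZ` is the safe representation; `partitionZ` exponentiates and may
#' overflow to `Inf` for long, stable sequences.
#' @param x A [PartitionResult-class].
#' @export
logZ <- function(x) x@logZ

#' @rdname logZ
#' @export
partitionZ <- function(x) exp(x@logZ)

#' FoldResult accessors
#' @param x A [FoldResult-class].
#' @export
foldScore <- function(x) x@score

#' @rdname foldScore
#' @export
foldGamma <- function(x) x@gamma

#' @rdname foldScore
#' @export
foldAlgorithm <- function(x) x@algorithm

#' Records and classes of a dataset
#' @param x A [BenchmarkDataset-class].
#' @export
datasetRecords <- function(x) x@records

#' @rdname datasetRecords
#' @export
datasetClasses <- function(x) x@classes

#' Sequences of a dataset as a Biostrings RNAStringSet
#'
#' Convenience interoperability accessor; `N` residues are preserved.
#' @param x A [BenchmarkDataset-class].
#' @export
asRNAStringSet <- function(x) {
  seqs <- vapply(x@records, function(r) r@sequence@residues, character(1))
  names(seqs) <- vapply(x@records, function(r) r@sequence@id, character(1))
  Biostrings::RNAStringSet(seqs)
}

## ---------------------------------------------------------------------------
## show methods

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure of length %d with %d base pairs\n",
              object@n, nrow(object@pairs)))
  if (object@n <= 120L) cat(" ", dotBracket(object), "\n")
})

setMethod("show", "RnaSequence", function(object) {
  cat(sprintf("RnaSequence '%s' (%s), %d nt\n", object@id,
              ifelse(is.na(object@classLabel), "unclassified", object@classLabel),
              nchar(object@residues)))
})

setMethod("show", "BenchmarkDataset", function(object) {
  cat(sprintf("BenchmarkDataset '%s': %d records in %d classes\n",
              object@name, length(object@records), length(object@classes)))
  if (length(object@classes)) {
    sizes <- vapply(object@classes, length, integer(1))
    for (lab in names(sizes)) cat(sprintf("  %-28s %5d\n", lab, sizes[[lab]]))
  }
})

setMethod("show", "NNParameterSet", function(object) {
  cat(sprintf("NNParameterSet '%s' (RT = %.4f kcal/mol)\n", object@name, object@RT))
  cat(sprintf("  multiloop a=%.2f b=%.2f c=%.2f, terminal AU %.2f\n",
              object@multiloop["a"], object@multiloop["b"],
              object@multiloop["c"], object@terminalAU))
})

setMethod("show", "FoldResult", function(object) {
  unit <- if (object@algorithm == "mfe") " kcal/mol" else ""
  cat(sprintf("FoldResult [%s]: score %.4f%s%s\n", object@algorithm,
              object@score, unit,
              ifelse(is.na(object@gamma), "", sprintf(", gamma %.4g", object@gamma))))
  show(object@structure)
})

setMethod("show", "PartitionResult", function(object) {
  cat(sprintf("PartitionResult: n = %d, logZ = %.6f\n", object@n, object@logZ))
})

setMethod("show", "ClassAccuracy", function(object) {
  cat(sprintf("ClassAccuracy '%s': l = %d, s = %.2f, mean M = %.4f\n",
              object@label, object@size, object@similarity, mean(object@values)))
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("Bootstrap %d%% percentile CI: %.4f (%.4f, %.4f), %d resamples\n",
              round(100 * object@level), object@pointEstimate, object@lower,
              object@upper, object@nResamples))
  cat(sprintf("  normality: %s", object@normalityFlag))
  if (!is.na(object@normalityP)) cat(sprintf(" (AD p = %.3g)", object@normalityP))
  cat("\n")
})

setMethod("show", "PermutationResult", function(object) {
  alt <- if (object@sided == "one") sprintf(" (%s)", object@alternative) else ""
  cat(sprintf("Permutation test (%s-sided%s): diff = %.4f, p = %.4g [%s, %d perms]\n",
              object@sided, alt, object@observedDiff, object@pValue,
              ifelse(object@exhaustive, "exhaustive", "sampled"),
              object@nPermutations))
})

setMethod("show", "ClassSpec", function(object) {
  cat(sprintf("ClassSpec '%s': n=%d, len %.0f+/-%.0f nt, sim %.2f, F %.2f+/-%.2f\n",
              object@label, object@size, object@lengthMean, object@lengthStd,
              object@similarity, object@accuracyMean, object@accuracySd))
})

setMethod("show", "SyntheticBenchmark", function(object) {
  cat("SyntheticBenchmark (seed", object@manifest$seed, ")\n")
  show(object@dataset)
})
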