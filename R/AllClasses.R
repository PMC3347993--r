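#' @import methods
NULL

.PAIR_LEVELS <- c("AU", "UA", "CG", "GC", "GU", "UG")
.MIN_HAIRPIN <- 3L

## ---------------------------------------------------------------------------
## SecondaryStructure

#' Pseudoknot-free RNA secondary structure
#'
#' A set of base pairs over a sequence of given length. Pairs are stored as a
#' two-column integer matrix of 1-based positions with `i < j`. Every object is
#' validated on construction: positions in range, each position in at most one
#' pair, no two pairs crossing (pseudoknot-free), and a minimum hairpin loop of
#' 3 unpaired bases (`j - i >= 4`).
#'
#' @slot n Integer, sequence length in nucleotides.
#' @slot pairs Integer matrix with columns `i`, `j`.
#' @export
setClass("SecondaryStructure",
         representation(n = "integer", pairs = "matrix"))

.crossing_pairs <- function(pairs) {
  m <- nrow(pairs)
  if (m < 2L) return(FALSE)
  ord <- order(pairs[, 1L])
  pi <- pairs[ord, 1L]; pj <- pairs[ord, 2L]
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      if (pi[b] >= pj[a]) break           # disjoint from here on
      if (pj[b] > pj[a]) return(TRUE)     # pi[a] < pi[b] < pj[a] < pj[b]
    }
  }
  FALSE
}

setValidity("SecondaryStructure", function(object) {
  n <- object@n
  p <- object@pairs
  if (length(n) != 1L || is.na(n) || n < 0L) return("length must be a single non-negative integer")
  if (!is.matrix(p) || ncol(p) != 2L) return("pairs must be a two-column matrix")
  if (nrow(p) == 0L) return(TRUE)
  if (!is.numeric(p) || any(is.na(p))) return("pairs must be numeric without NA")
  if (any(p < 1L) || any(p > n)) return("pair index out of range")
  if (any(p[, 2L] <= p[, 1L])) return("pairs must satisfy i < j")
  if (any(p[, 2L] - p[, 1L] < .MIN_HAIRPIN + 1L))
    return(sprintf("hairpin loop shorter than %d unpaired bases", .MIN_HAIRPIN))
  if (anyDuplicated(as.vector(p)) > 0L) return("a position occurs in more than one pair")
  if (.crossing_pairs(p)) return("crossing base pairs (pseudoknot) not allowed")
  TRUE
})

#' Construct a SecondaryStructure
#'
#' @param n Sequence length (nt).
#' @param pairs Two-column matrix (or empty) of 1-based pair positions `i < j`.
#' @return A validated [SecondaryStructure-class] object.
#' @examples
#' SecondaryStructure(7, rbind(c(1, 7), c(2, 6)))
#' @export
SecondaryStructure <- function(n, pairs = matrix(integer(), ncol = 2L)) {
  if (is.null(pairs) || length(pairs) == 0L)
    pairs <- matrix(integer(), ncol = 2L)
  pairs <- matrix(as.integer(round(pairs)), ncol = 2L)
  if (nrow(pairs) > 1L) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  new("SecondaryStructure", n = as.integer(n), pairs = pairs)
}

## ---------------------------------------------------------------------------
## RnaSequence

#' An RNA sequence with an identifier and class label
#'
#' Residues are normalized on construction: `T` becomes `U` and lowercase is
#' raised to uppercase. Only the alphabet `A,C,G,U,N` is accepted; `N` never
#' pairs.
#'
#' @slot id Character identifier.
#' @slot classLabel Character RNA class label (may be `NA`).
#' @slot residues Character scalar over `A,C,G,U,N`.
#' @export
setClass("RnaSequence",
         representation(id = "character", classLabel = "character",
                        residues = "character"))

setValidity("RnaSequence", function(object) {
  if (length(object@residues) != 1L) return("residues must be a single string")
  if (nchar(object@residues) < 1L) return("sequence must be non-empty")
  if (!grepl("^[ACGUN]+$", object@residues))
    return("residues must be over the alphabet A,C,G,U,N (after T->U, case normalization)")
  TRUE
})

#' @param id,classLabel,residues See slot descriptions.
#' @rdname RnaSequence-class
#' @export
RnaSequence <- function(residues, id = "seq", classLabel = NA_character_) {
  residues <- chartr("tT", "uU", as.character(residues))
  residues <- toupper(residues)
  new("RnaSequence", id = as.character(id),
      classLabel = as.character(classLabel), residues = residues)
}

## ---------------------------------------------------------------------------
## ReferenceRecord and BenchmarkDataset

#' A benchmark record: sequence, reference structure, optional predictions
#'
#' @slot sequence An [RnaSequence-class].
#' @slot reference The reference [SecondaryStructure-class].
#' @slot predictions Named list of predicted structures keyed by algorithm.
#' @export
setClass("ReferenceRecord",
         representation(sequence = "RnaSequence",
                        reference = "SecondaryStructure",
                        predictions = "list"))

setValidity("ReferenceRecord", function(object) {
  if (nchar(object@sequence@residues) != object@reference@n)
    return("reference structure length differs from sequence length")
  preds <- object@predictions
  if (length(preds)) {
    if (is.null(names(preds)) || any(names(preds) == ""))
      return("predictions must be a named list")
    for (p in preds) {
      if (!is(p, "SecondaryStructure")) return("predictions must be SecondaryStructure objects")
      if (p@n != object@reference@n) return("prediction length differs from sequence length")
    }
  }
  TRUE
})

#' @param sequence,reference,predictions See slot descriptions.
#' @rdname ReferenceRecord-class
#' @export
ReferenceRecord <- function(sequence, reference, predictions = list()) {
  new("ReferenceRecord", sequence = sequence, reference = reference,
      predictions = predictions)
}

#' A class-labelled benchmark dataset
#'
#' An ordered collection of [ReferenceRecord-class] objects together with a
#' mapping from class label to record indices.
#'
#' @slot name Character dataset name.
#' @slot records List of [ReferenceRecord-class].
#' @slot classes Named list, class label to integer record indices.
#' @export
setClass("BenchmarkDataset",
         representation(name = "character", records = "list",
                        classes = "list"))

setValidity("BenchmarkDataset", function(object) {
  nrec <- length(object@records)
  idx <- unlist(object@classes, use.names = FALSE)
  if (length(idx) != nrec) return("class sizes must sum to the record count")
  if (nrec && (anyDuplicated(idx) || any(idx < 1L) || any(idx > nrec)))
    return("class index mapping invalid")
  for (lab in names(object@classes)) {
    for (i in object@classes[[lab]]) {
      rl <- object@records[[i]]@sequence@classLabel
      if (!is.na(rl) && rl != lab)
        return(sprintf("record %d labelled '%s' but mapped to class '%s'", i, rl, lab))
    }
  }
  TRUE
})

#' @param name,records,classes See slot descriptions; if `classes` is missing
#'   it is derived from the records' class labels (order of first appearance).
#' @rdname BenchmarkDataset-class
#' @export
BenchmarkDataset <- function(records, name = "dataset", classes = NULL) {
  if (is.null(classes)) {
    labs <- vapply(records, function(r) r@sequence@classLabel, character(1))
    labs[is.na(labs)] <- "unlabelled"
    classes <- split(seq_along(records), factor(labs, levels = unique(labs)))
    classes <- lapply(classes, as.integer)
  }
  new("BenchmarkDataset", name = name, records = records, classes = classes)
}

## ---------------------------------------------------------------------------
## NNParameterSet

#' Reduced nearest-neighbor thermodynamic parameter set
#'
#' A deliberately small additive nearest-neighbor free-energy model: stacking
#' energies for the 36 ordered pairs of allowed base pairs, length-dependent
#' hairpin/bulge/internal loop penalties for sizes 0..30 with logarithmic
#' extrapolation beyond, affine multiloop terms, and a terminal AU/GU penalty
#' applied per helix end. This is not a Turner-parameter reimplementation;
#' packaged values are illustrative.
#'
#' @slot name Character.
#' @slot RT Thermal energy, kcal/mol (0.6163 at 37 degrees C).
#' @slot stack 6x6 numeric matrix (kcal/mol), rows = outer (closing) pair,
#'   columns = inner pair, in the order AU, UA, CG, GC, GU, UG.
#' @slot hairpin,bulge,internal Numeric length-31 penalty vectors indexed by
#'   loop size 0..30 (kcal/mol).
#' @slot multiloop Named numeric `c(a, b, c)`: offset, per-branch, per-unpaired.
#' @slot terminalAU Penalty for an AU/GU helix end (kcal/mol).
#' @slot lnCoeff Coefficient of the `ln(len/30)` long-loop extrapolation.
#' @export
setClass("NNParameterSet",
         representation(name = "character", RT = "numeric", stack = "matrix",
                        hairpin = "numeric", bulge = "numeric",
                        internal = "numeric", multiloop = "numeric",
                        terminalAU = "numeric", lnCoeff = "numeric"))

setValidity("NNParameterSet", function(object) {
  if (!identical(dim(object@stack), c(6L, 6L))) return("stack must be 6x6")
  if (!identical(rownames(object@stack), .PAIR_LEVELS) ||
      !identical(colnames(object@stack), .PAIR_LEVELS))
    return("stack dimnames must be AU,UA,CG,GC,GU,UG")
  for (nm in c("hairpin", "bulge", "internal"))
    if (length(slot(object, nm)) != 31L)
      return(sprintf("%s must cover loop sizes 0..30 (length 31)", nm))
  if (!identical(names(object@multiloop), c("a", "b", "c")))
    return("multiloop must be a named numeric c(a, b, c)")
  if (length(object@RT) != 1L || object@RT <= 0) return("RT must be a positive scalar")
  vals <- c(object@stack, object@hairpin, object@bulge, object@internal,
            object@multiloop, object@terminalAU, object@lnCoeff)
  if (any(is.na(vals))) return("non-numeric parameter entry")
  TRUE
})

#' @param name,RT,stack,hairpin,bulge,internal,multiloop,terminalAU,lnCoeff
#'   See slot descriptions. Defaults give the all-zero model (every structure
#'   has energy 0), useful as a degenerate test model.
#' @rdname NNParameterSet-class
#' @export
NNParameterSet <- function(name = "zero", RT = 0.6163,
                           stack = matrix(0, 6, 6,
                                          dimnames = list(.PAIR_LEVELS, .PAIR_LEVELS)),
                           hairpin = numeric(31), bulge = numeric(31),
                           internal = numeric(31),
                           multiloop = c(a = 0, b = 0, c = 0),
                           terminalAU = 0, lnCoeff = 0) {
  new("NNParameterSet", name = name, RT = RT, stack = stack,
      hairpin = hairpin, bulge = bulge, internal = internal,
      multiloop = multiloop, terminalAU = terminalAU, lnCoeff = lnCoeff)
}

## ---------------------------------------------------------------------------
## BasePairProbMatrix

#' Base-pair probability matrix
#'
#' Symmetric matrix of pair probabilities `p(i,j)` from the partition function,
#' with `p(i,j) = 0` whenever `j - i < 4`. Unpaired probabilities
#' `q(i) = 1 - sum_j p(i,j)` are available through [unpairedProbs()].
#'
#' @slot p Numeric matrix.
#' @export
setClass("BasePairProbMatrix", representation(p = "matrix"))

setValidity("BasePairProbMatrix", function(object) {
  p <- object@p
  if (nrow(p) != ncol(p)) return("matrix must be square")
  if (any(p < -1e-9) || any(p > 1 + 1e-9)) return("entries must lie in [0, 1]")
  if (max(abs(p - t(p))) > 1e-9) return("matrix must be symmetric")
  n <- nrow(p)
  if (n > 1L) {
    near <- abs(row(p) - col(p)) < .MIN_HAIRPIN + 1L
    if (any(p[near] != 0)) return("p(i,j) must be 0 for j - i < 4")
  }
  if (n && any(rowSums(p) > 1 + 1e-9)) return("row sums must not exceed 1")
  TRUE
})

#' @param p Symmetric probability matrix.
#' @rdname BasePairProbMatrix-class
#' @export
BasePairProbMatrix <- function(p) new("BasePairProbMatrix", p = as.matrix(p))

## ---------------------------------------------------------------------------
## FoldResult and PartitionResult

#' Result of a structure prediction
#'
#' @slot structure Predicted [SecondaryStructure-class].
#' @slot algorithm One of `mfe`, `mea`, `centroid`, `pseudo_mea`.
#' @slot score Objective value (kcal/mol for `mfe`, dimensionless otherwise).
#' @slot gamma Gamma used, or `NA` for `mfe`.
#' @export
setClass("FoldResult",
         representation(structure = "SecondaryStructure",
                        algorithm = "character", score = "numeric",
                        gamma = "numeric"))

#' Partition function result
#'
#' `logZ` is the numerically safe representation; [partitionZ()] exponentiates
#' and can overflow to `Inf` for long, very stable sequences.
#'
#' @slot n Sequence length.
#' @slot logZ Log partition function (dimensionless).
#' @export
setClass("PartitionResult", representation(n = "integer", logZ = "numeric"))

## ---------------------------------------------------------------------------
## ClassAccuracy

#' Per-class accuracy bookkeeping
#'
#' One RNA class: label, cardinality `l`, mean normalized structural
#' similarity `s` in `[0,1]`, and the per-record measure values (typically
#' F-measures), the inputs of the three class-averaging schemes.
#'
#' @slot label Character.
#' @slot size Integer `l >= 1`.
#' @slot similarity Numeric `s` in `[0, 1]`.
#' @slot values Numeric vector of per-record measure values, length `size`.
#' @export
setClass("ClassAccuracy",
         representation(label = "character", size = "integer",
                        similarity = "numeric", values = "numeric"))

setValidity("ClassAccuracy", function(object) {
  if (object@size < 1L) return("class size must be >= 1")
  if (length(object@values) != object@size)
    return("values length must equal class size")
  if (is.na(object@similarity) || object@similarity < 0 || object@similarity > 1)
    return("similarity must lie in [0, 1]")
  TRUE
})

#' @param label,size,similarity,values See slot descriptions; `size` defaults
#'   to `length(values)`.
#' @rdname ClassAccuracy-class
#' @export
ClassAccuracy <- function(label, values, similarity = 1, size = length(values)) {
  new("ClassAccuracy", label = as.character(label), size = as.integer(size),
      similarity = as.numeric(similarity), values = as.numeric(values))
}

## ---------------------------------------------------------------------------
## Resampling results

#' Bootstrap percentile confidence interval result
#'
#' @slot pointEstimate Average on the original sample.
#' @slot lower,upper Percentile CI bounds.
#' @slot level Confidence level.
#' @slot nResamples Number of bootstrap resamples.
#' @slot normalityP Anderson-Darling p-value for the bootstrap distribution
#'   (`NA` when degenerate).
#' @slot normalityFlag `"ok"` or `"degenerate"`.
#' @slot seed Integer seed used.
#' @slot distribution The bootstrap distribution of resample averages.
#' @export
setClass("BootstrapResult",
         representation(pointEstimate = "numeric", lower = "numeric",
                        upper = "numeric", level = "numeric",
                        nResamples = "integer", normalityP = "numeric",
                        normalityFlag = "character", seed = "integer",
                        distribution = "numeric"))

setValidity("BootstrapResult", function(object) {
  if (object@lower > object@upper + 1e-12) return("lower bound exceeds upper bound")
  if (object@level <= 0 || object@level >= 1) return("level must be in (0, 1)")
  TRUE
})

#' Permutation test result
#'
#' @slot observedDiff Observed `mean(A) - mean(B)`.
#' @slot pValue In `[0, 1]`; may be exactly 0 under the proportion convention.
#' @slot sided `"one"` or `"two"`.
#' @slot alternative For one-sided tests, `"A_less"` or `"A_greater"`.
#' @slot nPermutations Number of permutations actually evaluated.
#' @slot nA,nB Group sizes.
#' @slot seed Integer seed used (NA in exhaustive mode).
#' @slot exhaustive Logical, whether all splits were enumerated.
#' @export
setClass("PermutationResult",
         representation(observedDiff = "numeric", pValue = "numeric",
                        sided = "character", alternative = "character",
                        nPermutations = "integer", nA = "integer",
                        nB = "integer", seed = "integer",
                        exhaustive = "logical"))

setValidity("PermutationResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("p-value must lie in [0, 1]")
  if (object@nA < 1L || object@nB < 1L) return("both groups must be non-empty")
  TRUE
})

## ---------------------------------------------------------------------------
## Synthetic data specs

#' Specification of one synthetic RNA class
#'
#' @slot label Class name.
#' @slot size Number of records to generate.
#' @slot lengthMean,lengthStd Sequence length distribution (nt); lengths are
#'   drawn from this normal and clamped to `[20, 700]`.
#' @slot similarity Target mean within-class normalized similarity in `[0,1]`.
#' @slot accuracyMean,accuracySd Target F-measure distribution for simulated
#'   predictions on this class.
#' @export
setClass("ClassSpec",
         representation(label = "character", size = "integer",
                        lengthMean = "numeric", lengthStd = "numeric",
                        similarity = "numeric", accuracyMean = "numeric",
                        accuracySd = "numeric"))

setValidity("ClassSpec", function(object) {
  if (object@size < 1L) return("size must be >= 1")
  if (object@lengthMean > 700) return("lengthMean must be <= 700 nt")
  if (object@lengthMean < 20) return("lengthMean must be >= 20 nt")
  if (object@similarity < 0 || object@similarity > 1)
    return("similarity target must lie in [0, 1]")
  if (object@accuracyMean <= 0 || object@accuracyMean > 1)
    return("accuracyMean must lie in (0, 1]")
  TRUE
})

#' @param label,size,lengthMean,lengthStd,similarity,accuracyMean,accuracySd
#'   See slot descriptions.
#' @rdname ClassSpec-class
#' @export
ClassSpec <- function(label, size, lengthMean, lengthStd = 0,
                      similarity = 0.7, accuracyMean = 0.7, accuracySd = 0.15) {
  new("ClassSpec", label = as.character(label), size = as.integer(size),
      lengthMean = as.numeric(lengthMean), lengthStd = as.numeric(lengthStd),
      similarity = as.numeric(similarity),
      accuracyMean = as.numeric(accuracyMean), accuracySd = as.numeric(accuracySd))
}

#' A generated benchmark plus its generation manifest
#'
#' The manifest (seed, specs, achieved statistics, package version) suffices
#' to regenerate the benchmark bit-identically via [generateBenchmark()].
#'
#' @slot dataset The generated [BenchmarkDataset-class] with predictions.
#' @slot manifest Named list.
#' @export
setClass("SyntheticBenchmark",
         representation(dataset = "BenchmarkDataset", manifest = "list"))

## ---------------------------------------------------------------------------
## BenchmarkConfig

#' Configuration of an end-to-end benchmark run
#'
#' @slot specs List of [ClassSpec-class] for synthetic generation (empty when
#'   reading from files).
#' @slot datasetPath Path to a FASTA-with-structure reference file (file mode).
#' @slot manifestPath Optional path to a record/class manifest TSV.
#' @slot algorithms Named list: each element either a list with `mean` (scalar
#'   or per-class numeric) and `sd` for simulated predictions, or a function
#'   `(sequence, params) -> FoldResult` for a real predictor.
#' @slot params An [NNParameterSet-class].
#' @slot averages Character subset of `unweighted`, `weighted`, `s_weighted`.
#' @slot nResamples,nPermutations,level,seed Statistical settings.
#' @slot alternative Orientation of the one-sided permutation test.
#' @slot classSimilarities Optional named numeric: externally supplied `s_i`
#'   values used verbatim in the S-weighted average.
#' @slot similarityMaxPairs Cap on the number of record pairs sampled when
#'   estimating a class similarity (seeded subsample).
#' @slot outputDir Directory for report files.
#' @export
setClass("BenchmarkConfig",
         representation(specs = "list", datasetPath = "character",
                        manifestPath = "character", algorithms = "list",
                        params = "NNParameterSet", averages = "character",
                        nResamples = "integer", nPermutations = "integer",
                        level = "numeric", seed = "integer",
                        alternative = "character",
                        classSimilarities = "numeric",
                        similarityMaxPairs = "integer",
                        outputDir = "character"))

setValidity("BenchmarkConfig", function(object) {
  if (length(object@specs) == 0L && !length(object@datasetPath))
    return("either synthetic specs or a dataset path is required")
  if (length(object@datasetPath) && !file.exists(object@datasetPath))
    return(sprintf("dataset file not found: %s", object@datasetPath))
  if (length(object@manifestPath) && !file.exists(object@manifestPath))
    return(sprintf("manifest file not found: %s", object@manifestPath))
  if (object@level <= 0 || object@level >= 1) return("level must be in (0, 1)")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("a seed is mandatory for stochastic stages")
  TRUE
})
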