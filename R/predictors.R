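## The four estimators benchmarked by the analysis layer: MFE folding,
## partition-function base-pair probabilities, MEA, gamma-centroid and
## pseudo-MEA (automatic gamma) prediction, plus an exhaustive enumeration
## oracle used by the test suite.

.DEFAULT_GAMMA_GRID <- 2^(-5:10)

#' Exhaustively enumerate all valid secondary structures
#'
#' Test oracle: enumerates every pseudoknot-free structure over the allowed
#' base pairs (AU, UA, CG, GC, GU, UG; N never pairs) with a minimum hairpin
#' loop of 3 unpaired bases. Guarded to short inputs since the count grows
#' exponentially.
#'
#' @param sequence An [RnaSequence-class] or character. Alternatively pass
#'   `n` to enumerate over a given length with every pair allowed (used when
#'   the substrate is a probability matrix rather than a sequence).
#' @param n Length for the all-pairs-allowed variant.
#' @param maxLength Guard (default 16).
#' @return List of [SecondaryStructure-class] objects (the empty structure
#'   included), without duplicates.
#' @export
enumerateStructures <- function(sequence = NULL, n = NULL, maxLength = 16L) {
  if (is.null(sequence) == is.null(n))
    stop("provide exactly one of sequence or n")
  if (!is.null(sequence)) {
    codes <- .encode_sequence(sequence)
    n <- length(codes)
    canPair <- function(i, j) !is.na(.pair_of_codes(codes[i], codes[j]))
  } else {
    n <- as.integer(n)
    canPair <- function(i, j) TRUE
  }
  if (n > maxLength)
    stop("length ", n, " exceeds the enumeration guard (", maxLength, ")")
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i + 1L < .MIN_HAIRPIN + 2L) return(list(matrix(integer(), ncol = 2L)))
    key <- paste0(i, "_", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- rec(i + 1L, j)  # i unpaired
    for (k in (i + .MIN_HAIRPIN + 1L):j) {
      if (!canPair(i, k)) next
      left <- rec(i + 1L, k - 1L)
      right <- rec(k + 1L, j)
      for (L in left) for (R in right)
        out[[length(out) + 1L]] <- rbind(c(i, k), L, R)
    }
    memo[[key]] <- out
    out
  }
  lapply(rec(1L, n), function(p) SecondaryStructure(n, p))
}

.pair_of_codes <- function(a, b) {
  key <- paste0(a, "_", b)
  hit <- c("0_3" = 1L, "3_0" = 2L, "1_2" = 3L, "2_1" = 4L, "2_3" = 5L, "3_2" = 6L)[key]
  if (is.na(hit)) NA_integer_ else hit
}

#' Minimum free energy folding
#'
#' Zuker-style dynamic programming over the reduced nearest-neighbor model.
#' The traceback structure's [freeEnergy()] equals the DP optimum; ties prefer
#' leaving bases unpaired, then candidates in a fixed scan order, so identical
#' inputs always give identical structures.
#'
#' @param sequence An [RnaSequence-class] or character.
#' @param params An [NNParameterSet-class].
#' @param maxLoop Internal/bulge loop span cap in the DP (default 30).
#' @return A [FoldResult-class] with `algorithm = "mfe"` and the energy in
#'   kcal/mol as score.
#' @examples
#' mfeFold("GGGGAAAACCCC", loadParameters("toy37"))
#' @export
mfeFold <- function(sequence, params, maxLoop = 30L) {
  codes <- .encode_sequence(sequence)
  res <- c_mfe_fold(codes, .model_list(params, maxLoop))
  new("FoldResult",
      structure = SecondaryStructure(length(codes), res$pairs),
      algorithm = "mfe", score = res$energy, gamma = NA_real_)
}

#' Partition function over all secondary structures
#'
#' McCaskill-style recursions computed in a scaled linear domain so that
#' lengths up to 700 nt stay finite in `logZ`. The empty structure contributes
#' weight 1, so `Z >= 1` whenever exterior bases are free.
#'
#' @inheritParams mfeFold
#' @return A [PartitionResult-class]; see [logZ()] and [partitionZ()].
#' @export
partitionFunction <- function(sequence, params, maxLoop = 30L) {
  codes <- .encode_sequence(sequence)
  res <- c_partition(codes, .model_list(params, maxLoop))
  new("PartitionResult", n = length(codes), logZ = res$logZ)
}

#' Base-pair probabilities from the partition function
#'
#' Inside-outside computation of `p(i,j)`, the Boltzmann probability that
#' positions i and j pair. Row sums never exceed 1; `q(i) = 1 - sum_j p(i,j)`
#' is the unpaired probability.
#'
#' @inheritParams mfeFold
#' @return A [BasePairProbMatrix-class].
#' @export
basePairProbabilities <- function(sequence, params, maxLoop = 30L) {
  codes <- .encode_sequence(sequence)
  p <- c_basepair_probs(codes, .model_list(params, maxLoop))
  p <- (p + t(p)) / 2
  p[p < 0] <- 0
  ## guard against accumulated rounding pushing a row sum over 1
  rs <- rowSums(p)
  if (any(rs > 1)) {
    over <- rs > 1
    p[over, ] <- p[over, ] / rs[over]
    p <- pmin(p, t(p))  # keep symmetric: take the smaller adjustment
  }
  BasePairProbMatrix(p)
}

#' Write base-pair probabilities as tab-separated triples
#'
#' Upper-triangle `i j p` rows (1-based), one per nonzero entry.
#' @param bpp A [BasePairProbMatrix-class].
#' @param path Output file.
#' @export
writeBasePairProbs <- function(bpp, path) {
  p <- bpp@p
  idx <- which(upper.tri(p) & p > 0, arr.ind = TRUE)
  lines <- sprintf("%d\t%d\t%.10g", idx[, 1L], idx[, 2L], p[idx])
  writeLines(lines, path)
  invisible(path)
}

#' Maximum expected accuracy (MEA) structure
#'
#' Maximizes the Lu-style expected-accuracy objective
#' `sum_{(i,j) in S} 2 gamma p(i,j) + sum_{i unpaired in S} q(i)`
#' over all valid structures, by interval dynamic programming on the
#' probability matrix. `gamma` trades sensitivity against PPV; the benchmark
#' default is `gamma = 1`.
#'
#' @param bpp A [BasePairProbMatrix-class].
#' @param gamma Positive weight on base pairs.
#' @return A [FoldResult-class] with the objective value as score.
#' @export
meaFold <- function(bpp, gamma = 1) {
  if (gamma <= 0) stop("gamma must be positive")
  p <- bpp@p
  res <- c_max_weight_struct(2 * gamma * p, unpairedProbs(bpp))
  new("FoldResult", structure = SecondaryStructure(nrow(p), res$pairs),
      algorithm = "mea", score = res$score, gamma = gamma)
}

#' Gamma-centroid structure
#'
#' Maximizes `sum_{(i,j) in S} ((gamma + 1) p(i,j) - 1)`; only pairs with
#' `p(i,j) > 1/(gamma+1)` can contribute positively, so the predicted pair set
#' is always a subset of those.
#'
#' @inheritParams meaFold
#' @export
centroidFold <- function(bpp, gamma = 1) {
  if (gamma <= 0) stop("gamma must be positive")
  p <- bpp@p
  res <- c_max_weight_struct((gamma + 1) * p - 1, numeric(nrow(p)))
  new("FoldResult", structure = SecondaryStructure(nrow(p), res$pairs),
      algorithm = "centroid", score = res$score, gamma = gamma)
}

#' Pseudo-expected accuracy of a candidate structure
#'
#' Reference-free accuracy estimate computed from the probability matrix
#' alone: with `eTP = sum_{(i,j) in S} p(i,j)`, pseudo-sensitivity is
#' `eTP / sum_{i<j} p(i,j)`, pseudo-PPV is `eTP / |S|`, and pseudo-F their
#' harmonic mean. Conventions mirror [compareStructures()]: when both the
#' matrix mass and `S` are empty the triple is (1,1,1); when exactly one is
#' empty the undefined ratio is 0 and pseudo-F is 0.
#'
#' @param bpp A [BasePairProbMatrix-class].
#' @param structure A [SecondaryStructure-class] over the same length.
#' @return Named numeric `c(sensitivity, ppv, f)` of pseudo measures.
#' @export
pseudoExpectedAccuracy <- function(bpp, structure) {
  p <- bpp@p
  if (structure@n != nrow(p)) stop("structure length differs from matrix size")
  mass <- sum(p[upper.tri(p)])
  npair <- nrow(structure@pairs)
  etp <- if (npair) sum(p[structure@pairs]) else 0
  if (mass == 0 && npair == 0L) return(c(sensitivity = 1, ppv = 1, f = 1))
  sens <- if (mass > 0) etp / mass else 0
  ppv <- if (npair > 0L) etp / npair else 0
  f <- if (sens + ppv > 0) 2 * sens * ppv / (sens + ppv) else 0
  c(sensitivity = sens, ppv = ppv, f = f)
}

#' Pseudo-MEA prediction with automatic gamma selection
#'
#' Generalizes the centroid estimator: folds at every gamma in the grid,
#' scores each candidate by its pseudo-expected F-measure, and returns the
#' centroid structure of the best gamma. Ties are broken toward the smaller
#' gamma, so the result is deterministic.
#'
#' @param bpp A [BasePairProbMatrix-class].
#' @param gammaGrid Positive gamma values; default `2^k, k = -5..10`.
#' @return A [FoldResult-class] with `algorithm = "pseudo_mea"`, the achieved
#'   pseudo-F as score and the selected gamma.
#' @export
pseudoMeaFold <- function(bpp, gammaGrid = .DEFAULT_GAMMA_GRID) {
  if (!length(gammaGrid)) stop("gamma grid must be non-empty")
  if (any(gammaGrid <= 0)) stop("gamma values must be positive")
  gammaGrid <- sort(gammaGrid)
  best <- NULL
  bestF <- -1
  for (g in gammaGrid) {
    cand <- centroidFold(bpp, g)
    f <- pseudoExpectedAccuracy(bpp, cand@structure)[["f"]]
    if (f > bestF + 1e-12) {  # strict improvement: ties keep the smaller gamma
      bestF <- f
      best <- new("FoldResult", structure = cand@structure,
                  algorithm = "pseudo_mea", score = f, gamma = g)
    }
  }
  best
}

#' Run a named predictor on a sequence
#'
#' Convenience dispatcher used by the benchmark layer.
#' @param sequence An [RnaSequence-class] or character.
#' @param params An [NNParameterSet-class].
#' @param algorithm One of `"mfe"`, `"mea"`, `"centroid"`, `"pseudo_mea"`.
#' @param gamma Gamma for `mea`/`centroid` (default 1).
#' @param maxLoop Loop span cap for the thermodynamic DPs.
#' @return A [FoldResult-class].
#' @export
predictStructure <- function(sequence, params,
                             algorithm = c("mfe", "mea", "centroid", "pseudo_mea"),
                             gamma = 1, maxLoop = 30L) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "mfe") return(mfeFold(sequence, params, maxLoop))
  bpp <- basePairProbabilities(sequence, params, maxLoop)
  switch(algorithm,
         mea = meaFold(bpp, gamma),
         centroid = centroidFold(bpp, gamma),
         pseudo_mea = pseudoMeaFold(bpp))
}
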