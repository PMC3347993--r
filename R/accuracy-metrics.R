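## Accuracy layer: sensitivity / PPV / F-measure per prediction, normalized
## structural similarity, per-class bookkeeping, and the three averaging
## schemes (unweighted, weighted, similarity-weighted).

.pair_keys <- function(pairs) {
  if (!nrow(pairs)) return(character(0))
  paste(pairs[, 1L], pairs[, 2L], sep = "_")
}

#' @rdname compareStructures
#' @examples
#' ref <- parseDotBracket("((....))")
#' compareStructures(ref, ref)
#' @export
setMethod("compareStructures",
          signature("SecondaryStructure", "SecondaryStructure"),
          function(reference, predicted) {
  if (reference@n != predicted@n)
    stop("reference and predicted structures have different lengths")
  nref <- nrow(reference@pairs)
  npred <- nrow(predicted@pairs)
  if (nref == 0L && npred == 0L) return(c(sensitivity = 1, ppv = 1, f = 1))
  tp <- length(intersect(.pair_keys(reference@pairs), .pair_keys(predicted@pairs)))
  sens <- if (nref > 0L) tp / nref else 0
  ppv <- if (npred > 0L) tp / npred else 0
  f <- if (sens + ppv > 0) 2 * sens * ppv / (sens + ppv) else 0
  c(sensitivity = sens, ppv = ppv, f = f)
})

#' Class-averaging schemes for an accuracy measure
#'
#' Given RNA classes `C_1..C_n` with cardinalities `l_i`, mean normalized
#' similarities `s_i` and per-record measure values `M(C_ij)`:
#'
#' * `unweightedAverage` counts each class equally:
#'   `(1/n) sum_i mean_j M(C_ij)`.
#' * `weightedAverage` counts each sequence equally:
#'   `sum_ij M(C_ij) / sum_i l_i` (the plain mean over pooled values).
#' * `sWeightedAverage` discounts internally similar classes with weights
#'   `l_i^(1 - s_i)`:
#'   `sum_i l_i^(1-s_i) mean_j M(C_ij) / sum_i l_i^(1-s_i)`.
#'
#' The S-weighted average equals the weighted average when all `s_i = 0` and
#' the unweighted average when all `s_i = 1`. For mixed `s_i` it typically
#' falls between the two, but that is not a theorem and is not enforced.
#'
#' @param classes Non-empty list of [ClassAccuracy-class] objects.
#' @return A single dimensionless average.
#' @examples
#' cls <- list(ClassAccuracy("a", c(0.2, 0.2)), ClassAccuracy("b", 0.8))
#' unweightedAverage(cls)  # 0.5
#' weightedAverage(cls)    # 0.4
#' @export
unweightedAverage <- function(classes) {
  .check_classes(classes)
  mean(vapply(classes, function(cl) mean(cl@values), numeric(1)))
}

#' @rdname unweightedAverage
#' @export
weightedAverage <- function(classes) {
  .check_classes(classes)
  sum(vapply(classes, function(cl) sum(cl@values), numeric(1))) /
    sum(vapply(classes, function(cl) cl@size, numeric(1)))
}

#' @rdname unweightedAverage
#' @export
sWeightedAverage <- function(classes) {
  .check_classes(classes)
  w <- vapply(classes, function(cl) cl@size^(1 - cl@similarity), numeric(1))
  m <- vapply(classes, function(cl) mean(cl@values), numeric(1))
  sum(w * m) / sum(w)
}

.check_classes <- function(classes) {
  if (!length(classes)) stop("at least one class is required")
  ok <- vapply(classes, function(cl) is(cl, "ClassAccuracy"), logical(1))
  if (!all(ok)) stop("classes must be ClassAccuracy objects")
  invisible(TRUE)
}

#' Normalized similarity between two (sequence, structure) records
#'
#' A documented stand-in for tree-alignment similarity scores: when the two
#' records have equal length, positions are aligned by identical indexing;
#' otherwise their dot-bracket strings are globally aligned with a banded
#' Needleman-Wunsch (match +1, mismatch -1, gap -2; band = length difference
#' + 30). The score blends, 50/50, the sequence identity over mutually
#' aligned columns with the matched-base-pair F-measure (a pair of `a` counts
#' as matched when both its endpoints align to the endpoints of a pair of
#' `b`; the F denominator is the total pair count of both records, so length
#' differences lower the score). The result is symmetric (the argument order
#' is canonicalized before alignment), equals 1 for identical records, and
#' lies in `[0, 1]`.
#'
#' The measure is pluggable throughout the package: any function with this
#' signature can replace it (e.g. externally computed tree-alignment scores),
#' and class similarities can also be supplied verbatim via a benchmark
#' configuration.
#'
#' @param a,b [ReferenceRecord-class] objects (lengths may differ).
#' @return Similarity in `[0, 1]`.
#' @export
normalizedSimilarity <- function(a, b) {
  ## canonical order so the score is exactly symmetric
  ka <- paste(a@sequence@residues, dotBracket(a@reference))
  kb <- paste(b@sequence@residues, dotBracket(b@reference))
  if (ka > kb) { tmp <- a; a <- b; b <- tmp }
  sa <- a@sequence@residues; sb <- b@sequence@residues
  na <- nchar(sa); nb <- nchar(sb)
  pa <- a@reference@pairs; pb <- b@reference@pairs
  if (na == nb) {
    mapA <- mapB <- seq_len(na)
    ncol_aln <- na
  } else {
    dbcode <- function(x) match(strsplit(dotBracket(x), "")[[1L]], c(".", "(", ")"))
    aln <- c_band_align(dbcode(a@reference), dbcode(b@reference),
                        band = abs(na - nb) + 30L,
                        match = 1, mismatch = -1, gap = -2)
    ncol_aln <- aln$ncol
    mapA <- aln$mapA  # original position -> alignment column
    mapB <- aln$mapB
  }
  ## sequence identity over mutually aligned columns
  colsA <- rep(NA_character_, ncol_aln)
  colsB <- rep(NA_character_, ncol_aln)
  colsA[mapA] <- strsplit(sa, "")[[1L]]
  colsB[mapB] <- strsplit(sb, "")[[1L]]
  both <- !is.na(colsA) & !is.na(colsB)
  ident <- if (any(both)) sum(both & colsA == colsB) / sum(both) else 0
  ## matched-pair F over the alignment
  if (nrow(pa) == 0L && nrow(pb) == 0L) {
    fmeas <- 1
  } else if (nrow(pa) == 0L || nrow(pb) == 0L) {
    fmeas <- 0
  } else {
    keyB <- paste(mapB[pb[, 1L]], mapB[pb[, 2L]], sep = "_")
    keyA <- paste(mapA[pa[, 1L]], mapA[pa[, 2L]], sep = "_")
    tp <- length(intersect(keyA, keyB))
    fmeas <- 2 * tp / (nrow(pa) + nrow(pb))
  }
  0.5 * ident + 0.5 * fmeas
}

#' Mean within-class normalized similarity
#'
#' `s_i`: the mean of the normalized similarities between the reference
#' structures of every unordered pair of records in a class. Classes of size
#' 1 have `s_i = 1` by convention. For large classes the all-pairs mean can be
#' estimated from a seeded subsample of pairs via `maxPairs`.
#'
#' @param records List of [ReferenceRecord-class] objects (the class members).
#' @param simFun Pairwise similarity function; defaults to
#'   [normalizedSimilarity()] and is pluggable.
#' @param maxPairs Cap on the number of pairs evaluated (default all).
#' @param seed Seed for the pair subsample when `maxPairs` binds.
#' @return `s_i` in `[0, 1]`.
#' @export
classSimilarity <- function(records, simFun = normalizedSimilarity,
                            maxPairs = Inf, seed = 1L) {
  m <- length(records)
  if (m == 0L) stop("empty class")
  if (m == 1L) return(1)
  idx <- utils::combn(m, 2L)
  if (ncol(idx) > maxPairs) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
    idx <- idx[, sample.int(ncol(idx), maxPairs), drop = FALSE]
  }
  mean(vapply(seq_len(ncol(idx)), function(k)
    simFun(records[[idx[1L, k]]], records[[idx[2L, k]]]), numeric(1)))
}

## save/restore the global RNG state so seeded helpers do not disturb callers
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Build ClassAccuracy objects from a per-record metrics table
#'
#' @param values Numeric per-record measure values.
#' @param classLabels Character vector of class labels, same length.
#' @param similarities Named numeric of per-class `s_i`; classes absent from
#'   the vector get `s_i = 1` (the single-record convention).
#' @return List of [ClassAccuracy-class], in order of first appearance.
#' @export
classAccuracyTable <- function(values, classLabels, similarities = NULL) {
  if (length(values) != length(classLabels))
    stop("values and classLabels lengths differ")
  labs <- unique(classLabels)
  lapply(labs, function(lab) {
    v <- values[classLabels == lab]
    s <- if (!is.null(similarities) && lab %in% names(similarities))
      similarities[[lab]] else 1
    ClassAccuracy(lab, v, similarity = s)
  })
}
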