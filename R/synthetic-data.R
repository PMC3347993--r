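## Synthetic class-structured benchmarks: random sequences, Boltzmann-sampled
## reference structures, mutation-calibrated within-class similarity, and
## controlled-accuracy simulated predictions, so the whole analysis pipeline
## can be exercised without any external dataset.

#' Random RNA sequence with a target GC fraction
#'
#' G and C each get probability `gcFraction/2`; A and U share the rest.
#' @param length Sequence length (>= 1).
#' @param gcFraction Target GC content in `[0, 1]`.
#' @param seed Optional seed; the draw is reproducible given it.
#' @param id Identifier for the returned object.
#' @return An [RnaSequence-class].
#' @export
randomSequence <- function(length, gcFraction = 0.5, seed = NULL, id = "random") {
  if (gcFraction < 0 || gcFraction > 1) stop("gcFraction must lie in [0, 1]")
  if (length < 1L) stop("length must be >= 1")
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  res <- sample(c("A", "U", "G", "C"), length, replace = TRUE,
                prob = c((1 - gcFraction) / 2, (1 - gcFraction) / 2,
                         gcFraction / 2, gcFraction / 2))
  RnaSequence(paste(res, collapse = ""), id = id)
}

#' Model-free random nested structure
#'
#' Draws a valid pseudoknot-free structure without reference to any energy
#' model, by scanning candidate pairs in random order and accepting compatible
#' ones with probability `pairProb`. Used as the robustness alternative to
#' Boltzmann-sampled references.
#'
#' @param n Sequence length.
#' @param pairProb Acceptance probability per compatible candidate.
#' @param seed Optional seed.
#' @return A [SecondaryStructure-class].
#' @export
randomNestedStructure <- function(n, pairProb = 0.4, seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  cand <- which(outer(seq_len(n), seq_len(n),
                      function(i, j) j - i >= .MIN_HAIRPIN + 1L), arr.ind = TRUE)
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  used <- logical(n)
  pairs <- matrix(integer(), ncol = 2L)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (used[i] || used[j]) next
    if (!.compatible_pair(pairs, i, j)) next
    if (stats::runif(1) > pairProb) next
    pairs <- rbind(pairs, c(i, j))
    used[c(i, j)] <- TRUE
  }
  SecondaryStructure(n, pairs)
}

## nested-compatibility of candidate (i, j) with an existing pair set
.compatible_pair <- function(pairs, i, j) {
  if (!nrow(pairs)) return(TRUE)
  a <- pairs[, 1L]; b <- pairs[, 2L]
  disjoint <- b < i | a > j
  inside <- a > i & b < j
  outside <- a < i & b > j
  all(disjoint | inside | outside)
}

#' Sample reference structures from the Boltzmann ensemble
#'
#' Stochastic traceback of the partition function: each structure is drawn
#' with probability `exp(-E/RT)/Z`, so over many draws the pair frequencies
#' converge to [basePairProbabilities()].
#'
#' @param sequence An [RnaSequence-class] or character.
#' @param params An [NNParameterSet-class].
#' @param nSamples Number of structures to draw.
#' @param seed Optional seed.
#' @param maxLoop Loop span cap (as in the folding DPs).
#' @return A [SecondaryStructure-class] (or a list when `nSamples > 1`).
#' @export
sampleReferenceStructure <- function(sequence, params, nSamples = 1L,
                                     seed = NULL, maxLoop = 30L) {
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  codes <- .encode_sequence(sequence)
  raw <- c_sample_structures(codes, .model_list(params, maxLoop),
                             as.integer(nSamples))
  out <- lapply(raw, function(p) SecondaryStructure(length(codes), p))
  if (nSamples == 1L) out[[1L]] else out
}

#' Generate one synthetic RNA class
#'
#' Members are mutants of a common class ancestor. The ancestor sequence is
#' random (GC 0.5) at the class mean length and its reference structure is
#' Boltzmann-sampled under `params` (or model-free random nesting when
#' `referenceMode = "random"`). Each member draws its length from the class
#' normal (clamped to 20..700 nt), substitutes ancestor positions at a
#' mutation rate calibrated by bisection so the achieved within-class
#' similarity lands within 0.1 of the target, and inherits the ancestor
#' reference restricted to pairs that survive truncation and remain allowed
#' base pairs after mutation. A similarity target of exactly 1 yields
#' identical copies. Targets that are unattainable even at the extreme
#' mutation rates are reported via a warning carrying the achieved value,
#' never silently missed.
#'
#' @param spec A [ClassSpec-class].
#' @param params An [NNParameterSet-class].
#' @param seed Integer seed; the class regenerates bit-identically from it.
#' @param referenceMode `"boltzmann"` or `"random"`.
#' @param similarityMaxPairs Pair-subsample cap for the achieved-similarity
#'   estimate.
#' @return List with `records` (list of [ReferenceRecord-class]), `achieved`
#'   (named list: similarity, meanLength, mutationRate, attainable).
#' @export
makeClass <- function(spec, params, seed = 1L,
                      referenceMode = c("boltzmann", "random"),
                      similarityMaxPairs = 200L) {
  referenceMode <- match.arg(referenceMode)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  ancLen <- min(700L, max(20L, as.integer(round(spec@lengthMean))))
  anc <- randomSequence(ancLen, id = paste0(spec@label, "_ancestor"))
  ancStruct <- if (referenceMode == "boltzmann")
    sampleReferenceStructure(anc, params) else randomNestedStructure(ancLen)
  ancChars <- strsplit(anc@residues, "")[[1L]]

  member <- function(mu, k) {
    chars <- ancChars
    nMut <- stats::rbinom(1L, ancLen, mu)
    if (nMut > 0L) {
      at <- sample.int(ancLen, nMut)
      chars[at] <- vapply(chars[at], function(b)
        sample(setdiff(c("A", "C", "G", "U"), b), 1L), character(1))
    }
    L <- as.integer(round(stats::rnorm(1L, spec@lengthMean, spec@lengthStd)))
    L <- min(700L, max(20L, L))
    if (L <= ancLen) chars <- chars[seq_len(L)]
    else chars <- c(chars, sample(c("A", "C", "G", "U"), L - ancLen, replace = TRUE))
    p <- ancStruct@pairs
    if (nrow(p)) {
      p <- p[p[, 2L] <= L, , drop = FALSE]
      if (nrow(p)) {
        ok <- !is.na(.pair_name(chars[p[, 1L]], chars[p[, 2L]]))
        p <- p[ok, , drop = FALSE]
      }
    }
    ReferenceRecord(
      RnaSequence(paste(chars, collapse = ""),
                  id = sprintf("%s_%03d", spec@label, k),
                  classLabel = spec@label),
      SecondaryStructure(L, p))
  }

  generate <- function(mu) lapply(seq_len(spec@size), function(k) member(mu, k))
  achieved_of <- function(recs, cap = min(100L, similarityMaxPairs)) {
    if (spec@size == 1L) 1 else classSimilarity(recs, maxPairs = cap)
  }

  if (spec@similarity >= 1) {
    mu <- 0
    rec1 <- member(0, 1L)
    records <- lapply(seq_len(spec@size), function(k) {
      r <- rec1
      r@sequence@id <- sprintf("%s_%03d", spec@label, k)
      r
    })
  } else {
    ## bisect the mutation rate directly on the generated class's similarity,
    ## keeping the best-scoring candidate seen (single evaluations are jumpy
    ## when the ancestor structure has few pairs)
    best <- NULL
    evaluate <- function(mu) {
      recs <- generate(mu)
      s <- achieved_of(recs)
      if (is.null(best) ||
          abs(s - spec@similarity) < abs(best$sim - spec@similarity))
        best <<- list(mu = mu, records = recs, sim = s)
      s
    }
    s0 <- evaluate(0)
    if (s0 > spec@similarity && evaluate(0.5) <= spec@similarity) {
      lo <- 0; hi <- 0.5
      for (it in 1:8) {
        mid <- (lo + hi) / 2
        if (evaluate(mid) >= spec@similarity) lo <- mid else hi <- mid
      }
    }
    mu <- best$mu
    records <- best$records
  }
  achievedSim <- if (spec@size == 1L) 1
  else classSimilarity(records, maxPairs = similarityMaxPairs)
  attainable <- abs(achievedSim - spec@similarity) <= 0.1
  if (!attainable)
    warning(sprintf("class '%s': similarity target %.2f unattainable; achieved %.3f",
                    spec@label, spec@similarity, achievedSim))
  list(records = records,
       achieved = list(similarity = achievedSim,
                       meanLength = mean(vapply(records, function(r)
                         r@reference@n, numeric(1))),
                       mutationRate = mu, attainable = attainable))
}

#' Perturb a reference structure toward target accuracy
#'
#' Simulated predictor: keeps a random subset of true pairs sized to the
#' target sensitivity and inserts random compatible false pairs until the
#' target PPV is met (when combinatorially feasible; otherwise the achieved
#' values are reported via a warning). Targets (1, 1) return the reference
#' itself. The result is always a valid structure.
#'
#' @param reference Non-empty [SecondaryStructure-class].
#' @param targetSensitivity,targetPpv Targets in (0, 1].
#' @param seed Optional seed.
#' @param sequence Optional [RnaSequence-class]/character: restrict inserted
#'   false pairs to allowed base pairs of this sequence.
#' @return A [SecondaryStructure-class].
#' @export
perturbStructure <- function(reference, targetSensitivity, targetPpv,
                             seed = NULL, sequence = NULL) {
  if (targetSensitivity <= 0 || targetSensitivity > 1 ||
      targetPpv <= 0 || targetPpv > 1)
    stop("targets must lie in (0, 1]")
  R <- nrow(reference@pairs)
  if (R == 0L) stop("reference must be non-empty")
  if (targetSensitivity == 1 && targetPpv == 1) return(reference)
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  n <- reference@n
  chars <- if (!is.null(sequence)) {
    if (is(sequence, "RnaSequence")) sequence <- sequence@residues
    strsplit(toupper(chartr("tT", "uU", sequence)), "")[[1L]]
  } else NULL
  nTP <- round(targetSensitivity * R)
  keep <- if (nTP > 0L)
    reference@pairs[sample.int(R, nTP), , drop = FALSE]
  else matrix(integer(), ncol = 2L)
  nFP <- max(0L, round(nTP / targetPpv) - nTP)
  pairs <- keep
  used <- logical(n)
  if (nrow(pairs)) used[as.vector(pairs)] <- TRUE
  placed <- 0L
  tries <- 0L
  maxTries <- 200L * max(1L, nFP)
  refKeys <- .pair_keys(reference@pairs)
  while (placed < nFP && tries < maxTries) {
    tries <- tries + 1L
    i <- sample.int(n - .MIN_HAIRPIN - 1L, 1L)
    j <- i + .MIN_HAIRPIN + sample.int(n - i - .MIN_HAIRPIN, 1L)
    if (used[i] || used[j]) next
    if (paste(i, j, sep = "_") %in% refKeys) next  # must be a false pair
    if (!is.null(chars) && is.na(.pair_name(chars[i], chars[j]))) next
    if (!.compatible_pair(pairs, i, j)) next
    pairs <- rbind(pairs, c(i, j))
    used[c(i, j)] <- TRUE
    placed <- placed + 1L
  }
  out <- SecondaryStructure(n, pairs)
  if (placed < nFP) {
    ach <- compareStructures(reference, out)
    warning(sprintf(
      "target (sens %.2f, ppv %.2f) infeasible; achieved (%.2f, %.2f)",
      targetSensitivity, targetPpv, ach[["sensitivity"]], ach[["ppv"]]))
  }
  out
}

#' Generate a full synthetic benchmark
#'
#' Builds a class-structured dataset from the specs and attaches per-record
#' predictions for every named algorithm. An algorithm is either *simulated*
#' (a list with `mean` -- scalar or named per-class -- and `sd`: per-record
#' F-measure targets are drawn from that normal, clamped to `[0.05, 1]`, and
#' realized via [perturbStructure()] with equal sensitivity and PPV targets)
#' or *real* (a function `(sequence, params) -> FoldResult`). The generation
#' manifest records the seed, specs, achieved class statistics and simulated
#' algorithm descriptors, and suffices to regenerate the benchmark
#' bit-identically through [regenerateBenchmark()].
#'
#' @param specs Non-empty list of [ClassSpec-class].
#' @param algorithms Named list as described; `NULL` means one simulated
#'   algorithm `"sim"` using each spec's `accuracyMean`/`accuracySd`.
#' @param params An [NNParameterSet-class].
#' @param seed Integer seed.
#' @param referenceMode `"boltzmann"` or `"random"` (see [makeClass()]).
#' @param similarityMaxPairs Passed to [makeClass()].
#' @param name Dataset name.
#' @return A [SyntheticBenchmark-class].
#' @export
generateBenchmark <- function(specs, algorithms = NULL,
                              params = loadParameters("toy37"), seed = 1L,
                              referenceMode = c("boltzmann", "random"),
                              similarityMaxPairs = 200L, name = "synthetic") {
  referenceMode <- match.arg(referenceMode)
  if (!length(specs)) stop("at least one class spec is required")
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  classSeeds <- sample.int(2^30, length(specs))
  if (is.null(algorithms)) {
    means <- vapply(specs, function(s) s@accuracyMean, numeric(1))
    names(means) <- vapply(specs, function(s) s@label, character(1))
    algorithms <- list(sim = list(mean = means,
                                  sd = specs[[1L]]@accuracySd))
  }
  records <- list()
  achieved <- list()
  for (k in seq_along(specs)) {
    mc <- makeClass(specs[[k]], params, seed = classSeeds[k],
                    referenceMode = referenceMode,
                    similarityMaxPairs = similarityMaxPairs)
    records <- c(records, mc$records)
    achieved[[specs[[k]]@label]] <- mc$achieved
  }
  ## predictions
  set.seed(classSeeds[1L] + 1L)
  simDescr <- list()
  for (nm in names(algorithms)) {
    alg <- algorithms[[nm]]
    if (is.function(alg)) {
      for (k in seq_along(records)) {
        fr <- alg(records[[k]]@sequence, params)
        records[[k]]@predictions[[nm]] <- fr@structure
      }
      simDescr[[nm]] <- "external function"
    } else {
      mn <- alg$mean
      sd <- if (is.null(alg$sd)) 0.15 else alg$sd
      for (k in seq_along(records)) {
        lab <- records[[k]]@sequence@classLabel
        m <- if (length(mn) > 1L || !is.null(names(mn))) {
          if (!lab %in% names(mn))
            stop("algorithm '", nm, "' has no accuracy mean for class '", lab, "'")
          mn[[lab]]
        } else mn
        fTarget <- min(1, max(0.05, stats::rnorm(1L, m, sd)))
        ref <- records[[k]]@reference
        pred <- if (nrow(ref@pairs) == 0L) ref
        else suppressWarnings(
          perturbStructure(ref, fTarget, fTarget,
                           sequence = records[[k]]@sequence))
        records[[k]]@predictions[[nm]] <- pred
      }
      simDescr[[nm]] <- list(mean = mn, sd = sd)
    }
  }
  dataset <- BenchmarkDataset(records, name = name)
  ## achieved per-algorithm accuracy per class
  accStats <- list()
  for (nm in names(algorithms)) {
    accStats[[nm]] <- vapply(names(dataset@classes), function(lab) {
      idx <- dataset@classes[[lab]]
      mean(vapply(idx, function(i)
        compareStructures(dataset@records[[i]]@reference,
                          dataset@records[[i]]@predictions[[nm]])[["f"]],
        numeric(1)))
    }, numeric(1))
  }
  manifest <- list(seed = as.integer(seed), classSeeds = classSeeds,
                   referenceMode = referenceMode,
                   similarityMaxPairs = as.integer(similarityMaxPairs),
                   name = name, params = params@name,
                   specs = lapply(specs, function(s) list(
                     label = s@label, size = s@size,
                     lengthMean = s@lengthMean, lengthStd = s@lengthStd,
                     similarity = s@similarity,
                     accuracyMean = s@accuracyMean, accuracySd = s@accuracySd)),
                   algorithms = simDescr, achieved = achieved,
                   achievedAccuracy = accStats,
                   version = as.character(utils::packageVersion("RNAfoldBench")))
  new("SyntheticBenchmark", dataset = dataset, manifest = manifest)
}

#' Regenerate a synthetic benchmark from its manifest
#'
#' Bit-identical regeneration; only works when every algorithm in the
#' original run was simulated (external predictor functions cannot be stored
#' in a manifest).
#'
#' @param manifest The manifest list of a [SyntheticBenchmark-class] (or the
#'   benchmark itself).
#' @return A [SyntheticBenchmark-class].
#' @export
regenerateBenchmark <- function(manifest) {
  if (is(manifest, "SyntheticBenchmark")) manifest <- manifest@manifest
  if (any(vapply(manifest$algorithms, is.character, logical(1))))
    stop("manifest contains an external predictor; cannot regenerate")
  specs <- lapply(manifest$specs, function(s)
    ClassSpec(s$label, s$size, s$lengthMean, s$lengthStd, s$similarity,
              s$accuracyMean, s$accuracySd))
  generateBenchmark(specs, algorithms = manifest$algorithms,
                    params = loadParameters(manifest$params),
                    seed = manifest$seed,
                    referenceMode = manifest$referenceMode,
                    similarityMaxPairs = manifest$similarityMaxPairs,
                    name = manifest$name)
}
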