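# Shared fixtures: parameter sets, record builders, and brute-force scoring
# helpers used as independent oracles.

toyParams <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- loadParameters("toy37")
    cache
  }
})

zeroParams <- function() NNParameterSet()

makeRecord <- function(seq, db, id = "r", cls = "X") {
  ReferenceRecord(RnaSequence(seq, id = id, classLabel = cls),
                  parseDotBracket(db))
}

# random record with a valid nested reference structure (model-free)
randomRecord <- function(n, id = "r", cls = "X", seed = NULL) {
  s <- randomSequence(n, seed = seed, id = id)
  st <- randomNestedStructure(n, seed = if (is.null(seed)) NULL else seed + 1L)
  # keep only pairs allowed for the sequence, so records stay realistic
  chars <- strsplit(residues(s), "")[[1L]]
  pr <- basePairs(st)
  if (nrow(pr)) {
    allowed <- paste0(chars[pr[, 1L]], chars[pr[, 2L]]) %in%
      c("AU", "UA", "CG", "GC", "GU", "UG")
    pr <- pr[allowed, , drop = FALSE]
  }
  ReferenceRecord(RnaSequence(residues(s), id = id, classLabel = cls),
                  SecondaryStructure(n, pr))
}

# brute-force objective maxima over an enumerated structure list
bruteMeaScore <- function(structures, p, q, gamma = 1) {
  max(vapply(structures, function(st) {
    pr <- basePairs(st)
    unp <- setdiff(seq_along(q), as.vector(pr))
    2 * gamma * sum(p[pr]) + sum(q[unp])
  }, numeric(1)))
}

bruteCentroidScore <- function(structures, p, gamma = 1) {
  max(vapply(structures, function(st) {
    pr <- basePairs(st)
    sum((gamma + 1) * p[pr] - 1)
  }, numeric(1)))
}

# Boltzmann oracle quantities from exhaustive enumeration
enumBoltzmann <- function(seq, params) {
  structures <- enumerateStructures(seq)
  energies <- vapply(structures, function(st) freeEnergy(seq, st, params),
                     numeric(1))
  w <- exp(-energies / params@RT)
  n <- nchar(if (is(seq, "RnaSequence")) residues(seq) else seq)
  P <- matrix(0, n, n)
  for (k in seq_along(structures)) {
    pr <- basePairs(structures[[k]])
    if (nrow(pr)) P[pr] <- P[pr] + w[k]
  }
  P <- (P + t(P)) / sum(w)
  list(structures = structures, energies = energies, Z = sum(w), P = P)
}
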