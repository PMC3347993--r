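---
title: "Benchmarking energy-based RNA secondary structure prediction"
author: "RNAfoldBench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking energy-based RNA secondary structure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RNAfoldBench)
```

# Scope

RNAfoldBench implements the full evaluation pipeline used to benchmark
energy-based RNA secondary structure predictors: the predictors themselves
(MFE, MEA, gamma-centroid, pseudo-MEA) over a reduced nearest-neighbor
thermodynamic model, the accuracy layer (sensitivity, PPV, F-measure and
three class-averaging schemes), the significance machinery (bootstrap
percentile confidence intervals and permutation tests), and a seeded
synthetic benchmark generator that emulates the class structure of real
reference collections so that every stage can be exercised without any
external dataset.

The package deliberately does **not** ship real reference datasets (they are
user-suppliable through the FASTA-with-structure and CT readers) and its
thermodynamic parameter fixtures are illustrative, not measured values.

# The energy model

A secondary structure is a pseudoknot-free set of base pairs over
`{AU, UA, CG, GC, GU, UG}` with a minimum hairpin loop of 3 unpaired bases
(`j - i >= 4`); the minimum-loop convention is fixed package-wide. The free
energy of a structure is the sum of independent loop terms
(`loopDecomposition()` / `loopEnergy()`):

* **stacks**: a 6x6 table indexed by (closing pair, inner pair), kcal/mol;
* **hairpin / bulge / internal loops**: penalty arrays over loop sizes 0-30,
  extended beyond 30 by `penalty(30) + lnCoeff * log(len/30)`;
* **multiloops**: affine, `a + b` per branch (the closing pair counts as a
  branch) `+ c` per unpaired base;
* **terminal AU/GU penalty**: charged once for every AU/UA/GU/UG pair
  bordering a non-stack loop; a lone pair closing a hairpin in the exterior
  loop is charged twice (once per side), the standard convention;
* the exterior loop itself is free apart from its branches' AU penalties.

This is a reduced model of roughly a hundred parameters, in the spirit of the
small nearest-neighbor feature sets used when parameters are re-estimated
from data, rather than a full Turner implementation: dangles, coaxial
stacking, asymmetry terms and special hairpins are deliberately excluded so
that every loop energy remains hand-checkable and the exhaustive enumeration
oracle stays exact. Two parameter files ship with the package, `toy37` and
`toy37_alt` (a perturbed second set so that parameter-set comparisons can be
exercised); both use `RT = 0.6163` kcal/mol (37 degrees C). The stacking
values of `toy37` follow a simple hand-checkable rule,
`-(bonds(outer) + bonds(inner))/2` with `CG/GC = 3`, `AU/UA = 2`,
`GU/UG = 1` effective bonds, so e.g. `stack(GC on GC) = -3.0`.

```{r}
p <- loadParameters("toy37")
freeEnergy("GGAAACC", parseDotBracket("((...))"), p)  # -3.0 + 5.4
```

# Predictors

All four predictors operate over this model through dynamic programming in
compiled code:

* `mfeFold()` — Zuker-style minimum free energy with V (paired), M/M1
  (multiloop) and W (exterior) recursions. The interior-loop span is capped
  at 30 (`maxLoop`), and the enumeration oracle applies the same cap so oracle
  tests are exact (the cap cannot bind below 35 nt anyway).
* `partitionFunction()` — the same recursion set with sums in place of
  minima (McCaskill). To reach 700 nt without overflow the tables are kept
  in a *scaled linear* domain: every base carries a factor
  `exp(1.07 * E_mfe / (n * RT))`, the standard per-base rescaling, and the
  result is reported as `logZ` (the numerically safe representation; the `Z`
  accessor exponentiates and can overflow to `Inf` for long, stable
  sequences).
* `basePairProbabilities()` — inside-outside over the same decomposition.
  The multiloop outside term is implemented directly (quadratic per pair),
  which is exact and fast for the desk-scale lengths the benchmark uses
  (up to a few hundred nt); it is not intended for 700-nt probability
  matrices.
* `meaFold()` — maximizes the Lu-style expected-accuracy objective
  `sum 2*gamma*p(i,j) + sum q(i)` over valid structures, by interval DP on
  the probability matrix. The default `gamma = 1` is the benchmark setting.
* `centroidFold()` — maximizes `sum ((gamma+1) p(i,j) - 1)`; only pairs with
  `p > 1/(gamma+1)` can help, which the tests assert as an invariant. The
  gamma-centroid with `gamma = 1` is the `gC-g1` setting.
* `pseudoMeaFold()` — the automatic-gamma generalization: folds at every
  gamma on the grid `2^k, k = -5..10`, scores each candidate with its
  pseudo-expected F (`pseudoExpectedAccuracy()`, the reference-free estimate
  `eTP = sum_{(i,j) in S} p(i,j)`, pseudo-sens `= eTP / sum p`, pseudo-PPV
  `= eTP / |S|`), and keeps the best, ties toward the smaller gamma. The
  grid is a documented package choice; the construction follows the
  generalized-centroid pseudo-expected-accuracy recipe.

Tie-breaking in every traceback prefers leaving bases unpaired, then
candidates in a fixed ascending scan order, so identical inputs always give
identical structures.

**Correctness strategy.** The package carries its own independent oracle:
`enumerateStructures()` lists every valid structure for short inputs, and the
R-level `freeEnergy()` (loop decomposition, written independently of the C++
DP) scores them. The test suite checks MFE energies, partition functions,
every pair probability, MEA scores and centroid scores against this
enumeration on hundreds of random sequences up to 12 nt at 1e-9 tolerance,
and checks the Boltzmann sampler's pair frequencies against the
inside-outside probabilities.

# Accuracy layer

`compareStructures()` counts exact-index pair matches — no one-position
slippage, the strictest and most reproducible reading. Edge conventions
(documented because they are otherwise undefined): two empty structures
compare as (1, 1, 1); exactly one empty gives 0 for the undefined ratio and
F = 0.

Three averages summarize a measure over classes `C_i` with sizes `l_i` and
mean within-class similarities `s_i`:

* unweighted — every class counts equally: `(1/n) sum_i mean_i`;
* weighted — every sequence counts equally: the pooled mean;
* S-weighted — classes are discounted by internal similarity with weights
  `l_i^(1 - s_i)`: `sum_i l_i^(1-s_i) mean_i / sum_i l_i^(1-s_i)`.

The S-weighted form equals the weighted average when all `s_i = 0` and the
unweighted average when all `s_i = 1`; both limits are asserted to 1e-12.
The often-stated intuition that it falls *between* the other two for mixed
`s_i` is not a theorem and is deliberately not enforced.

**Similarity stand-in.** True tree-alignment similarity scores are not
reimplemented; `normalizedSimilarity()` is a fully documented stand-in:
equal-length records align by identical indexing, unequal lengths by a
banded Needleman-Wunsch on the dot-bracket strings (match +1, mismatch -1,
gap -2, band = length difference + 30), and the score blends 50/50 the
sequence identity over mutually aligned columns with the matched-pair
F-measure (denominator = both records' pair counts, so length differences
lower the score). It is symmetric by canonicalizing the argument order,
1 for identical records, and pluggable: `classSimilarity(simFun = ...)`
accepts any pairwise function, and benchmark configurations accept external
per-class `s_i` used verbatim. Classes of size 1 have `s_i = 1` by
convention. For large classes the all-pairs mean is estimated from a seeded
subsample of pairs (200 by default in benchmark runs) — the full quadratic
sweep is available by setting `maxPairs = Inf`.

# Resampling statistics

`bootstrapPercentileCI()` resamples records with replacement (default 10^4
resamples, each the size of the original sample; resampling through
`boot::boot`), recomputes the requested average per resample — class labels
travel with the records so class-aware averages are recomputed honestly —
and takes the empirical 2.5th/97.5th percentiles (`stats::quantile` type 7,
i.e. order statistics with linear interpolation, chosen for bit-stability).
An Anderson-Darling test on the bootstrap distribution serves as a
normality diagnostic; constant distributions are flagged `degenerate`
rather than tested.

`permutationTest()` pools the two sets and re-splits them into the original
sizes (default 10^4 sampled splits, or exhaustively when
`choose(nA+nB, nA) <= 1e5`). Because the usual verbal recipe leaves the
one-sided orientation ambiguous, the package requires an explicit
`alternative`: `"A_less"` counts permuted differences `<=` the observed one
(small p is evidence A's mean is genuinely below B's), `"A_greater"` the
mirror image; the two-sided p counts `|permuted| >= |observed|`. The plain
proportion convention is the default — p may be exactly 0 — with the
`(k+1)/(N+1)` estimator available via `addOne = TRUE`.

Both routines are deterministic given their seed, and both are calibrated in
the test suite: 95% CI coverage within 95 +/- 3% over 300 simulated
datasets, type-I error of the two-sided test within [0.03, 0.07] at
alpha = 0.05 over 500 null trials (n = 50 per arm, 2000 permutations —
sizes chosen to keep the default suite a few minutes long while leaving the
Monte-Carlo error well inside the asserted bands), and the textbook
exhaustive case A = {1,2,3}, B = {4,5,6} giving exactly p = 0.1 two-sided.

# The synthetic benchmark generator

`generateBenchmark()` produces class-structured datasets with the
statistical features the analysis assumes. Its default class specifications
(`mtBenchmarkSpecs()`) mirror the published MT benchmark collection's class
structure — eight classes, sizes 88/27/309/16/3/6/91/484, the corresponding
length means and standard deviations, and the published within-class
similarities — and its default simulated algorithms
(`mtSimulatedAlgorithms()`) target the published per-class MEA and MFE
(BL*) F-measure columns with a per-record spread of 0.18, a typical
per-molecule F-measure dispersion for such classes.

Per class:

1. a random ancestor sequence (GC 0.5) is drawn at the class mean length and
   its reference structure is **Boltzmann-sampled** under the energy model
   (stochastic traceback of the partition function), so references share the
   thermodynamic structure the predictors assume; a `referenceMode = "random"`
   flag switches to model-free random nesting for robustness tests;
2. members mutate the ancestor at a substitution rate calibrated by
   bisection directly against the achieved class similarity (the best
   evaluated candidate is kept, because single evaluations are coarse when
   the ancestor structure has few pairs); member lengths are drawn from the
   class normal, clamped to 20-700 nt, realized by truncating or extending
   the ancestor; member references inherit the ancestor pairs that survive
   truncation and remain allowed after mutation. A similarity target of
   exactly 1 produces identical copies. A target the mutation mechanism
   cannot reach within 0.1 is reported with the achieved value via a
   warning, never silently missed;
3. simulated predictions realize per-record F targets (normal draws, clamped
   to [0.05, 1]) through `perturbStructure()`, which deletes true pairs to
   the sensitivity target and inserts random compatible false pairs to the
   PPV target, reporting infeasible combinations with their achieved
   values; real predictors can be attached instead.

The generation manifest (seed, per-class seeds, specs, achieved statistics)
regenerates the benchmark bit-identically (`regenerateBenchmark()`).

What the generator does **not** emulate: family covariation and phylogenetic
structure, lowercase-constraint annotations, pseudoknots, and any 3D
realism. Passing tests on synthetic data therefore demonstrate that the
pipeline's arithmetic, calibration and determinism are correct — not that
any predictor reaches a particular accuracy on real RNA families; published
headline accuracies additionally require the real reference collections and
measured parameter sets, which are out of scope by design.

# Benchmark orchestration and report

`runBenchmark(BenchmarkConfig(...))` runs the pipeline end to end and emits
the report: per-record metrics, a per-class summary whose bottom three rows
are the three averages (self-checked against the class rows on every run),
bootstrap CI tables per class and pooled, one- and two-sided permutation
p-value tables for every algorithm pair, and a run log with versions and
seeds. TSVs print at 3 decimals; a JSON sidecar keeps full precision.
Reruns with the same configuration are byte-identical. The interface of the
package is these functions plus the readers/writers; there is no separate
shell tool.

# Numerical choices and problem sizes

* Oracle tests run at lengths 6-12 where enumeration is exact; 200 random
  sequences in the acceptance suite.
* The default full-size synthetic benchmark (1024 records, lengths up to
  ~670 nt) generates in seconds because only one partition-function fill per
  class ancestor is needed; its statistical layer uses the study defaults
  (10^4 resamples, 10^4 permutations).
* Bootstrap/permutation calibration uses 300 and 500 seeded trials with
  reduced resample counts; these sizes keep the whole default test suite
  around four minutes.
* All randomness flows through explicit integer seeds; helpers save and
  restore the caller's RNG state.

# Known limitations

* The energy model is reduced; absolute energies and probabilities are not
  comparable to Turner-model implementations.
* `basePairProbabilities()` scales steeply with length (outside multiloop
  term); use desk-scale sequences for probability-based predictors.
* The similarity stand-in is a proxy; where tree-alignment scores exist they
  should be supplied externally (per-class `s_i` in the benchmark config).
* Class-similarity targeting is calibrated, not solved: granularity is
  limited by the ancestor structure's pair count, and targets outside the
  mechanism's reachable range are reported rather than met.
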