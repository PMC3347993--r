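## Significance machinery: bootstrap percentile confidence intervals (with an
## Anderson-Darling normality diagnostic on the bootstrap distribution) and
## one-/two-sided permutation tests on per-record measure values.

#' Bootstrap percentile confidence interval for an average measure
#'
#' Resamples records with replacement (10^4 resamples by default, each the
#' size of the original sample), recomputes the requested average on every
#' resample, and reports the empirical `(1-level)/2` and `1-(1-level)/2`
#' percentiles of the resulting bootstrap distribution. Class labels are
#' carried along with each resampled record, so class-aware averages
#' (unweighted / weighted / S-weighted) are recomputed per resample. The
#' resampling itself is delegated to [boot::boot()]; percentiles use the
#' empirical order-statistic convention with linear interpolation
#' (`stats::quantile` type 7), which keeps results bit-stable across versions.
#'
#' The Anderson-Darling test ([nortest::ad.test()]) is run on the bootstrap
#' distribution as a diagnostic of how close it is to Gaussian; a degenerate
#' (constant) distribution is flagged rather than tested.
#'
#' @param values Numeric per-record measure values (e.g. F-measures).
#' @param classLabels Optional class labels, required for class-aware averages.
#' @param similarities Optional named numeric `s_i` per class (S-weighted).
#' @param average One of `"plain"`, `"unweighted"`, `"weighted"`,
#'   `"s_weighted"`. `"plain"` and `"weighted"` coincide (the pooled mean).
#' @param nResamples Number of bootstrap resamples (default 10000).
#' @param level Confidence level in (0, 1) (default 0.95).
#' @param seed Integer seed; the run is deterministic given it.
#' @return A [BootstrapResult-class].
#' @examples
#' r <- bootstrapPercentileCI(rnorm(200, 0.7, 0.1), nResamples = 500, seed = 1)
#' r
#' @export
bootstrapPercentileCI <- function(values, classLabels = NULL,
                                  similarities = NULL,
                                  average = c("plain", "unweighted",
                                              "weighted", "s_weighted"),
                                  nResamples = 10000L, level = 0.95,
                                  seed = 1L) {
  average <- match.arg(average)
  if (!length(values)) stop("values must be non-empty")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  if (average %in% c("unweighted", "s_weighted") && is.null(classLabels))
    stop("class labels are required for the ", average, " average")
  if (is.null(classLabels)) classLabels <- rep("all", length(values))
  if (length(classLabels) != length(values))
    stop("values and classLabels lengths differ")
  statistic <- function(data, idx) {
    v <- data$value[idx]
    cl <- data$label[idx]
    switch(average,
           plain = , weighted = mean(v),
           unweighted = unweightedAverage(classAccuracyTable(v, cl, similarities)),
           s_weighted = sWeightedAverage(classAccuracyTable(v, cl, similarities)))
  }
  data <- data.frame(value = values, label = classLabels,
                     stringsAsFactors = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  b <- boot::boot(data, statistic, R = nResamples)
  dist <- as.numeric(b$t)
  alpha <- (1 - level) / 2
  bounds <- stats::quantile(dist, c(alpha, 1 - alpha), names = FALSE, type = 7)
  if (stats::sd(dist) < 1e-12) {
    flag <- "degenerate"
    adp <- NA_real_
  } else {
    flag <- "ok"
    adp <- tryCatch(nortest::ad.test(dist)$p.value, error = function(e) NA_real_)
  }
  new("BootstrapResult", pointEstimate = as.numeric(b$t0),
      lower = bounds[1L], upper = bounds[2L], level = level,
      nResamples = as.integer(nResamples), normalityP = adp,
      normalityFlag = flag, seed = as.integer(seed), distribution = dist)
}

#' Anderson-Darling normality diagnostic
#'
#' Thin wrapper used to flag bootstrap distributions: reports the test
#' p-value and whether normality is rejected at the 5% level; constant input
#' is flagged `"degenerate"` instead of crashing.
#'
#' @param x Numeric distribution, length >= 8.
#' @return List with `statistic`, `p.value`, `rejected` (at 5%), `flag`.
#' @export
andersonDarlingNormality <- function(x) {
  if (length(x) < 8L) stop("need at least 8 values")
  if (stats::sd(x) < 1e-12)
    return(list(statistic = NA_real_, p.value = NA_real_,
                rejected = NA, flag = "degenerate"))
  t <- nortest::ad.test(x)
  list(statistic = unname(t$statistic), p.value = t$p.value,
       rejected = t$p.value < 0.05, flag = "ok")
}

#' Permutation test for a difference of means
#'
#' Pools the two sets, evaluates the mean difference (oriented as
#' `mean(A) - mean(B)`) over random re-divisions into groups of the original
#' sizes, and reports the proportion convention p-value:
#'
#' * one-sided, `alternative = "A_less"`: proportion of permuted differences
#'   `<=` the observed difference (small p is evidence that A's mean is
#'   genuinely below B's);
#' * one-sided, `alternative = "A_greater"`: proportion `>=` observed;
#' * two-sided: proportion with `|permuted| >= |observed|`.
#'
#' Under the plain proportion convention p may be exactly 0;
#' `addOne = TRUE` switches to the `(k+1)/(N+1)` estimator. When the number
#' of distinct splits `choose(nA+nB, nA)` is at most `exhaustiveLimit` and
#' `exhaustive` is `"auto"` or `"always"`, all splits are enumerated instead
#' of sampled and the result is exact.
#'
#' @param A,B Numeric vectors (both non-empty).
#' @param sided `"one"` or `"two"`.
#' @param alternative Orientation of the one-sided test (required there).
#' @param nPermutations Number of sampled permutations (default 10000).
#' @param seed Integer seed for the sampled mode.
#' @param exhaustive `"auto"`, `"never"` or `"always"`.
#' @param exhaustiveLimit Largest number of splits enumerated in auto mode.
#' @param addOne Use the add-one p-value estimator (default FALSE).
#' @return A [PermutationResult-class].
#' @examples
#' permutationTest(c(1, 2, 3), c(4, 5, 6), sided = "two",
#'                 exhaustive = "always")  # p = 0.1
#' @export
permutationTest <- function(A, B, sided = c("one", "two"),
                            alternative = c("A_less", "A_greater"),
                            nPermutations = 10000L, seed = 1L,
                            exhaustive = c("auto", "never", "always"),
                            exhaustiveLimit = 1e5, addOne = FALSE) {
  sided <- match.arg(sided)
  alternative <- match.arg(alternative)
  exhaustive <- match.arg(exhaustive)
  if (!length(A) || !length(B)) stop("both sets must be non-empty")
  nA <- length(A); nB <- length(B)
  pool <- c(A, B)
  tot <- sum(pool)
  n <- nA + nB
  obs <- mean(A) - mean(B)
  nsplits <- choose(n, nA)
  doExh <- exhaustive == "always" ||
    (exhaustive == "auto" && nsplits <= exhaustiveLimit && nPermutations >= nsplits)
  diff_of <- function(sumA) sumA / nA - (tot - sumA) / nB
  if (doExh) {
    sums <- utils::combn(pool, nA, FUN = sum)
    diffs <- diff_of(sums)
    nperm <- length(diffs)
    seedUsed <- NA_integer_
  } else {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
    diffs <- vapply(seq_len(nPermutations), function(k)
      diff_of(sum(pool[sample.int(n, nA)])), numeric(1))
    nperm <- as.integer(nPermutations)
    seedUsed <- as.integer(seed)
  }
  k <- if (sided == "two") sum(abs(diffs) >= abs(obs) - 1e-12)
  else if (alternative == "A_less") sum(diffs <= obs + 1e-12)
  else sum(diffs >= obs - 1e-12)
  p <- if (addOne) (k + 1) / (nperm + 1) else k / nperm
  p <- min(1, p)
  new("PermutationResult", observedDiff = obs, pValue = p, sided = sided,
      alternative = if (sided == "one") alternative else NA_character_,
      nPermutations = as.integer(nperm), nA = as.integer(nA),
      nB = as.integer(nB), seed = seedUsed, exhaustive = doExh)
}
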