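#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH procedure with monotonicity enforcement:
#' adjusted `p_(i) = min over j >= i of p_(j) * m / j`.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param alpha Significance level for the mask (default 0.05).
#' @return A tibble with `p_value`, `p_adjusted`, `significant`.
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  tibble::tibble(p_value = p, p_adjusted = adj, significant = adj <= alpha)
}

#' Sign-permutation test of subject-level statistics against chance
#'
#' Centers each subject's values on chance and builds the null by
#' multiplying the subject vector by random +/-1 signs and recomputing the
#' group mean, per timepoint (or layer). Two-tailed rank p-values include the
#' observed statistic in the null set, so `p >= 1 / (n_perm + 1)`. P-values
#' are BH-adjusted across points.
#'
#' @param values Subjects x points matrix (or a tibble of numeric columns).
#' @param chance Chance level to center on (e.g. 50 for percent accuracy,
#'   0 for correlations).
#' @param n_perm Number of sign permutations (default 10000).
#' @param alpha FDR level (default 0.05).
#' @param tail `"two"` (default), `"greater"` or `"less"`.
#' @param seed Integer seed.
#' @return A `timecourse_pvalues` tibble: `point`, `mean` (on the original
#'   scale), `p_value`, `p_adjusted`, `significant`.
#' @export
sign_permutation_test <- function(values, chance = 0, n_perm = 10000L,
                                  alpha = 0.05, tail = c("two", "greater", "less"),
                                  seed = 1L) {
  tail <- match.arg(tail)
  values <- as.matrix(values)
  S <- nrow(values)
  if (S < 2) stop("need at least 2 subjects")
  V <- values - chance
  obs <- colMeans(V)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * S, replace = TRUE), n_perm, S)
  null <- signs %*% V / S  # n_perm x points
  p <- vapply(seq_along(obs), function(j) rank_pvalue(obs[j], null[, j], tail),
              numeric(1))
  out <- dplyr::bind_cols(
    tibble::tibble(point = colnames(values) %||% seq_along(obs),
                   mean = obs + chance),
    fdr_bh(p, alpha))
  class(out) <- c("timecourse_pvalues", class(out))
  attr(out, "n_perm") <- n_perm
  attr(out, "tail") <- tail
  out
}

#' Condition-swap permutation test between two groups of subjects
#'
#' Pools the subjects of both conditions and rebuilds the two groups at
#' random (preserving group sizes); the statistic is the difference of group
#' means per point. Two-tailed rank p-values, BH-adjusted across points.
#'
#' @param values_a,values_b Subjects x points matrices for the two
#'   conditions (equal column counts; group sizes may differ).
#' @param n_perm Number of label swaps (default 10000).
#' @param alpha FDR level.
#' @param seed Integer seed.
#' @return A `timecourse_pvalues` tibble with the observed `difference` per
#'   point, `p_value`, `p_adjusted`, `significant`.
#' @export
condition_swap_test <- function(values_a, values_b, n_perm = 10000L,
                                alpha = 0.05, seed = 1L) {
  A <- as.matrix(values_a); B <- as.matrix(values_b)
  if (nrow(A) == 0 || nrow(B) == 0) stop("both groups must be non-empty")
  if (ncol(A) != ncol(B)) stop("conditions differ in points")
  pool <- rbind(A, B)
  na <- nrow(A); n <- nrow(pool)
  obs <- colMeans(A) - colMeans(B)
  set.seed(seed)
  null <- matrix(0, n_perm, ncol(pool))
  for (i in seq_len(n_perm)) {
    ia <- sample.int(n, na)
    null[i, ] <- colMeans(pool[ia, , drop = FALSE]) -
      colMeans(pool[-ia, , drop = FALSE])
  }
  p <- vapply(seq_along(obs), function(j) rank_pvalue(obs[j], null[, j], "two"),
              numeric(1))
  out <- dplyr::bind_cols(
    tibble::tibble(point = colnames(A) %||% seq_along(obs), difference = obs),
    fdr_bh(p, alpha))
  class(out) <- c("timecourse_pvalues", class(out))
  attr(out, "n_perm") <- n_perm
  out
}

#' Percentile bootstrap CI for a group mean
#'
#' @param x Subject-level values (length >= 2... a single value returns a
#'   degenerate zero-width interval).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param conf Confidence level (default 0.95: 2.5th and 97.5th percentiles).
#' @param seed Integer seed.
#' @return Named numeric `c(lo, hi)`.
#' @export
bootstrap_ci_mean <- function(x, n_boot = 10000L, conf = 0.95, seed = 1L) {
  if (length(x) == 0) stop("empty input")
  set.seed(seed)
  draws <- matrix(sample(x, n_boot * length(x), replace = TRUE), n_boot)
  means <- rowMeans(draws)
  qs <- quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  c(lo = qs[1], hi = qs[2])
}

#' Location of a curve's global maximum on its measurement grid
#'
#' Ties are broken toward the earliest grid point (shallowest layer).
#'
#' @param curve Numeric values (NA allowed unless all are NA).
#' @param grid Grid values (timepoints in ms, or layer indices/labels);
#'   defaults to `seq_along(curve)`.
#' @return The grid value at the maximum.
#' @export
peak_location <- function(curve, grid = seq_along(curve)) {
  if (length(curve) == 0 || all(is.na(curve))) stop("curve has no finite values")
  grid[which.max(curve)]
}

#' Bootstrap CI for the peak location of a group-mean curve
#'
#' Resamples subjects with replacement, recomputes the mean curve and its
#' peak location, and returns the percentile interval of the bootstrapped
#' peaks around the observed group-mean peak.
#'
#' @param curves Subjects x points matrix of individual curves.
#' @param grid Measurement grid (ms or layer index).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return A `peak_estimate`: tibble with `peak`, `lo`, `hi`, `n_boot`.
#' @export
bootstrap_peak_ci <- function(curves, grid = seq_len(ncol(curves)),
                              n_boot = 10000L, conf = 0.95, seed = 1L) {
  curves <- as.matrix(curves)
  if (nrow(curves) < 2) stop("need at least 2 subjects")
  obs <- peak_location(colMeans(curves), grid)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    rows <- sample.int(nrow(curves), replace = TRUE)
    peak_location(colMeans(curves[rows, , drop = FALSE]), grid)
  }, numeric(1))
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  out <- tibble::tibble(peak = obs, lo = qs[1], hi = qs[2], n_boot = n_boot)
  class(out) <- c("peak_estimate", class(out))
  attr(out, "boots") <- boots
  out
}

#' Bootstrap CI for the difference between two conditions' peak locations
#'
#' Subjects are resampled independently per condition (unpaired designs,
#' e.g. different participant groups per condition); the difference of the
#' two resampled peaks forms the bootstrap distribution. A difference whose
#' CI contains 0 is deemed non-significant.
#'
#' @param curves_a,curves_b Subjects x points matrices (same grid).
#' @param grid Measurement grid.
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return A tibble with `difference` (peak A - peak B), `lo`, `hi`, and
#'   `significant` (CI excludes 0).
#' @export
bootstrap_peak_difference <- function(curves_a, curves_b,
                                      grid = seq_len(ncol(curves_a)),
                                      n_boot = 10000L, conf = 0.95, seed = 1L) {
  A <- as.matrix(curves_a); B <- as.matrix(curves_b)
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty condition")
  if (ncol(A) != ncol(B)) stop("conditions differ in grid length")
  obs <- peak_location(colMeans(A), grid) - peak_location(colMeans(B), grid)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    ra <- sample.int(nrow(A), replace = TRUE)
    rb <- sample.int(nrow(B), replace = TRUE)
    peak_location(colMeans(A[ra, , drop = FALSE]), grid) -
      peak_location(colMeans(B[rb, , drop = FALSE]), grid)
  }, numeric(1))
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  tibble::tibble(difference = obs, lo = qs[1], hi = qs[2],
                 significant = !(qs[1] <= 0 && qs[2] >= 0))
}

#' Alignment between neural peak latencies and network peak layers
#'
#' Spearman correlation (average ranks on ties) between the per-feature EEG
#' encoding peak latencies and network peak layers, with a permutation
#' p-value obtained by exhaustively permuting the layer vector (n! orderings;
#' 5040 for the default 7 features). Above `max_exact` orderings a
#' Monte-Carlo sample of permutations is used instead and flagged. The
#' default test is one-sided for positive alignment.
#'
#' @param peak_latencies Per-feature EEG peak latencies (ms).
#' @param peak_layers Per-feature network peak layers (numeric indices).
#' @param alternative `"greater"` (default: positive alignment) or
#'   `"two.sided"`.
#' @param max_exact Largest n! that is enumerated exhaustively
#'   (default 40320 = 8!).
#' @param n_mc Monte-Carlo permutations beyond `max_exact`.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return A `hierarchy_correlation`: tibble with `rho`, `p_value`,
#'   `n_features`, `n_permutations`, `exact`.
#' @export
hierarchy_correlation <- function(peak_latencies, peak_layers,
                                  alternative = c("greater", "two.sided"),
                                  max_exact = 40320L, n_mc = 100000L,
                                  seed = 1L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(peak_latencies); y <- as.numeric(peak_layers)
  if (length(x) != length(y)) stop("vectors differ in length")
  n <- length(x)
  if (n < 3) stop("need at least 3 features")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)  # Pearson on average ranks = Spearman with ties
  exact <- factorial(n) <= max_exact
  if (exact) {
    perms <- all_permutations(n)
    null <- as.vector(cor(rx, t(matrix(ry[perms], nrow(perms)))))
    hits <- if (alternative == "greater") sum(null >= rho - 1e-12) else
      sum(abs(null) >= abs(rho) - 1e-12)
    p <- hits / nrow(perms)
    n_perm <- nrow(perms)
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_mc), function(i) cor(rx, ry[sample.int(n)]),
                   numeric(1))
    p <- rank_pvalue(rho, null,
                     if (alternative == "greater") "greater" else "two")
    n_perm <- n_mc
  }
  out <- tibble::tibble(rho = rho, p_value = p, n_features = n,
                        n_permutations = n_perm, exact = exact)
  class(out) <- c("hierarchy_correlation", class(out))
  attr(out, "alternative") <- alternative
  out
}
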