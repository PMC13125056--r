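#' @importFrom stats cor quantile rnorm runif sd prcomp p.adjust setNames
#' @importFrom utils head
#' @importFrom rlang .data %||%
NULL

# Named per-stage substreams derived from one master seed, so that e.g.
# changing the decoding seed never perturbs the simulation stream.
.stage_offsets <- c(
  design = 101L, annotations = 211L, eeg = 307L, layers = 401L,
  decode = 503L, encode = 601L, ceiling = 701L, stats = 809L,
  hierarchy = 907L, subjects = 1013L
)

#' Derive a per-stage seed from a master seed
#'
#' Each pipeline stage consumes its own deterministic substream of the master
#' seed, so reruns of one stage never perturb another.
#'
#' @param seed Master seed (integer).
#' @param stage Stage name, one of `names(eegencode:::.stage_offsets)`.
#' @param index Optional extra index (e.g. subject number).
#' @return An integer seed below 2^31.
#' @export
fan_seed <- function(seed, stage, index = 0L) {
  stopifnot(stage %in% names(.stage_offsets))
  off <- .stage_offsets[[stage]]
  as.integer((as.numeric(seed) * 48271 + off * 1009 + index * 7919) %% 2147483629)
}

# Pearson correlation between matching columns of two matrices.
# Columns with zero variance on either side give NA (callers decide policy).
col_pearson <- function(X, Y) {
  stopifnot(all(dim(X) == dim(Y)))
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  num <- colSums(Xc * Yc)
  den <- sqrt(colSums(Xc^2) * colSums(Yc^2))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}

# All permutations of 1..n as an n! x n matrix, lexicographic order.
all_permutations <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- matrix(rest[sub], nrow = nrow(sub))
    idx <- row:(row + nrow(sub) - 1L)
    out[idx, 1] <- k
    out[idx, -1] <- block
    row <- row + nrow(sub)
  }
  out
}

# Two-tailed (or one-tailed) rank p-value with the observed statistic included
# in the null set: p = (1 + #{null >= obs}) / (1 + n_perm), always > 0.
rank_pvalue <- function(observed, null, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  eps <- 1e-12
  n <- length(null)
  hits <- switch(tail,
    two     = sum(abs(null) >= abs(observed) - eps),
    greater = sum(null >= observed - eps),
    less    = sum(null <= observed + eps)
  )
  (1 + hits) / (1 + n)
}
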