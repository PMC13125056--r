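#' Average repetitions into pseudotrials
#'
#' Randomly partitions the repetitions of one stimulus into bins of
#' `bin_size` and returns the bin means, raising the signal-to-noise ratio
#' before decoding. Each repetition is used exactly once.
#'
#' @param repetitions Repetitions x channels x timepoints array (or a
#'   repetitions x channels matrix for a single timepoint).
#' @param bin_size Repetitions per bin; must divide the repetition count.
#' @param seed Integer seed for the random partition.
#' @return Pseudotrials x channels (x timepoints) array with
#'   `repetitions / bin_size` pseudotrials.
#' @export
make_pseudotrials <- function(repetitions, bin_size = 5L, seed = 1L) {
  d <- dim(repetitions)
  if (is.null(d)) stop("repetitions must be an array")
  if (length(d) == 2) {
    dim(repetitions) <- c(d, 1L)
    d <- dim(repetitions)
  }
  R <- d[1]
  if (R %% bin_size != 0) stop("repetition count not divisible by bin_size")
  n_bins <- R %/% bin_size
  set.seed(seed)
  ord <- sample.int(R)
  bin <- rep(seq_len(n_bins), each = bin_size)
  out <- array(0, c(n_bins, d[2], d[3]))
  for (b in seq_len(n_bins)) {
    rows <- ord[bin == b]
    out[b, , ] <- apply(repetitions[rows, , , drop = FALSE], c(2, 3), mean)
  }
  out
}

#' Pairwise decoding accuracy at one timepoint
#'
#' Stratified k-fold cross-validation of a linear support vector machine
#' (cost = 1, no feature scaling) on the channel patterns of two stimuli:
#' each fold holds out one pseudotrial per class at the defaults
#' (6 pseudotrials per class, 6 folds), trains on the rest, and the fold
#' accuracies are averaged.
#'
#' @param a,b Pseudotrials x channels matrices for the two stimuli; equal row
#'   counts, divisible by `n_folds`.
#' @param n_folds Number of stratified folds (default 6).
#' @param seed Integer seed for the fold assignment.
#' @param cost SVM regularization constant.
#' @return Mean cross-validated accuracy in percent.
#' @export
pairwise_decode_timepoint <- function(a, b, n_folds = 6L, seed = 1L, cost = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("unequal pseudotrial counts per class")
  P <- nrow(a)
  if (P < 2) stop("need at least 2 pseudotrials per class")
  if (P %% n_folds != 0) stop("pseudotrial count not divisible by n_folds")
  set.seed(seed)
  # one fold pattern shared by both classes: keeps folds stratified (one
  # pseudotrial per class per fold at the defaults) and makes the accuracy
  # exactly invariant under swapping the class labels
  fold_pattern <- sample(rep(seq_len(n_folds), length.out = P))
  x <- rbind(a, b)
  y <- factor(rep(c("a", "b"), each = P))
  fold <- c(fold_pattern, fold_pattern)
  acc <- vapply(seq_len(n_folds), function(k) {
    tr <- fold != k
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = cost, scale = FALSE)
    mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  100 * mean(acc)
}

#' Time-resolved pairwise decoding of one subject
#'
#' For every timepoint, decodes every unordered pair of test-split stimuli
#' from pseudotrial channel patterns and averages the lower triangle of the
#' pairwise accuracy matrix. The whole analysis is repeated `n_repeats` times
#' with freshly randomized pseudotrial bins and fold splits, and averaged.
#'
#' @param epochs A (whitened) `eeg_epochs` object with equal repetition
#'   counts per stimulus in the decoded split.
#' @param split Split to decode (default `"test"`, the split with the most
#'   repetitions).
#' @param bin_size Repetitions per pseudotrial bin (default 5).
#' @param n_folds Stratified folds per pair (default 6).
#' @param n_repeats Outer repetitions with fresh bins (default 6).
#' @param stimuli Optional vector of stimulus ids to decode (default all in
#'   the split); pairs are enumerated in ascending id order.
#' @param times Optional subset of timepoints (ms) to decode.
#' @param seed Integer seed controlling bins and folds.
#' @return A `decoding_timecourse` tibble with columns `time_ms` and
#'   `accuracy` (percent; chance = 50).
#' @export
decode_subject <- function(epochs, split = "test", bin_size = 5L,
                           n_folds = 6L, n_repeats = 6L, stimuli = NULL,
                           times = NULL, seed = 1L) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- which(epochs$trial_table$split == split)
  if (length(idx) == 0) stop("missing split: ", split)
  sid <- epochs$trial_table$stimulus_id[idx]
  stimuli <- sort(if (is.null(stimuli)) unique(sid) else stimuli)
  if (length(stimuli) < 2) stop("need at least 2 stimuli to decode")
  reps <- table(sid)[as.character(stimuli)]
  if (length(unique(as.vector(reps))) != 1) {
    stop("unequal repetition counts across stimuli")
  }
  tsel <- if (is.null(times)) seq_along(epochs$time_ms) else
    which(epochs$time_ms %in% times)
  pairs <- utils::combn(seq_along(stimuli), 2)
  C <- dim(epochs$data)[2]

  acc <- matrix(0, length(tsel), n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    rep_seed <- fan_seed(seed, "decode", rep_i)
    pseudo <- lapply(seq_along(stimuli), function(si) {
      rows <- idx[sid == stimuli[si]]
      make_pseudotrials(epochs$data[rows, , tsel, drop = FALSE], bin_size,
                        seed = rep_seed + si)
    })
    for (ti in seq_along(tsel)) {
      pair_acc <- vapply(seq_len(ncol(pairs)), function(pi) {
        i <- pairs[1, pi]; j <- pairs[2, pi]
        pairwise_decode_timepoint(
          pseudo[[i]][, , ti], pseudo[[j]][, , ti], n_folds = n_folds,
          seed = rep_seed + 31L * ti + 97L * pi)
      }, numeric(1))
      acc[ti, rep_i] <- mean(pair_acc)
    }
  }
  out <- tibble::tibble(time_ms = epochs$time_ms[tsel],
                        accuracy = rowMeans(acc))
  class(out) <- c("decoding_timecourse", class(out))
  attr(out, "chance") <- 50
  attr(out, "n_pairs") <- ncol(pairs)
  out
}

#' Difference between two decoding (or encoding) time courses
#'
#' @param a,b Tibbles with `time_ms` and a shared accuracy/statistic column;
#'   identical time axes required.
#' @param column Name of the column to subtract (default `"accuracy"`).
#' @return A tibble with `time_ms` and `difference = a - b`.
#' @export
difference_timecourse <- function(a, b, column = "accuracy") {
  if (!identical(a$time_ms, b$time_ms)) stop("time axes differ")
  tibble::tibble(time_ms = a$time_ms,
                 difference = a[[column]] - b[[column]])
}
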