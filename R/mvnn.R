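#' Baseline-correct epoched EEG
#'
#' Subtracts, per trial and channel, the mean over a pre-stimulus window
#' (default the 100 ms immediately before onset).
#'
#' @param epochs An `eeg_epochs` object.
#' @param window_ms Two-element window `c(from, to)` in ms; must lie on the
#'   time axis and end at or before 0 ms.
#' @return The baseline-corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, window_ms = c(-100, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (window_ms[2] > 0) stop("baseline window must end at or before 0 ms")
  sel <- which(epochs$time_ms >= window_ms[1] & epochs$time_ms <= window_ms[2])
  if (length(sel) == 0) stop("empty baseline window")
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over the time axis
  epochs$baseline_window <- window_ms
  epochs
}

# Ledoit-Wolf shrinkage covariance of pre-centered samples (rows).
# Mirrors the standard estimator with the n-denominator convention:
# shrinks the sample covariance toward mu * I with data-driven intensity.
ledoit_wolf <- function(X) {
  n <- nrow(X); p <- ncol(X)
  S <- crossprod(X) / n
  mu <- mean(diag(S))
  d2 <- sum((S - diag(mu, p))^2) / p
  if (d2 <= .Machine$double.eps) {
    return(list(matrix = S, shrinkage = 0, mu = mu))
  }
  b2bar <- (sum(rowSums(X^2)^2) - n * sum(S^2)) / (n^2 * p)
  b2 <- min(max(b2bar, 0), d2)
  delta <- b2 / d2
  list(matrix = delta * mu * diag(p) + (1 - delta) * S, shrinkage = delta,
       mu = mu)
}

#' Estimate the channel noise covariance from repeated trials
#'
#' Noise is defined as the deviation of each repetition from the mean over
#' that stimulus' repetitions at each timepoint (stimulus-evoked activity is
#' assumed constant across repetitions). With `method = "pooled"` (default)
#' the per-(stimulus, timepoint) residuals are pooled into one sample and a
#' single Ledoit-Wolf shrinkage is applied to the pooled covariance — with
#' equal repetition counts this equals averaging the per-cell sample
#' covariances before shrinking. `method = "per_cell"` instead shrinks every
#' (stimulus, timepoint) covariance separately and averages the shrunk
#' matrices; with few repetitions per stimulus this shrinks heavily toward
#' the identity and under-whitens, so it is not the default.
#'
#' @param epochs An `eeg_epochs` object.
#' @param split Split whose trials define the noise (default `"train"`).
#' @param method `"pooled"` or `"per_cell"` (see Details).
#' @param timepoints `"all"` or `"prestim"`: which timepoints contribute.
#' @return A `noise_covariance`: the channels x channels `matrix`, the
#'   shrinkage intensity, and sample bookkeeping.
#' @export
estimate_noise_covariance <- function(epochs, split = "train",
                                      method = c("pooled", "per_cell"),
                                      timepoints = c("all", "prestim")) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  method <- match.arg(method)
  timepoints <- match.arg(timepoints)
  idx <- which(epochs$trial_table$split == split)
  if (length(idx) == 0) stop("missing split: ", split)
  sid <- epochs$trial_table$stimulus_id[idx]
  if (any(table(sid) < 2)) {
    stop("every stimulus needs >= 2 repetitions to define noise")
  }
  tsel <- if (timepoints == "prestim") which(epochs$time_ms < 0) else
    seq_along(epochs$time_ms)
  d <- dim(epochs$data)
  C <- d[2]
  dat <- epochs$data[idx, , tsel, drop = FALSE]
  n <- length(idx); Tn <- length(tsel)

  # residuals: repetition minus its stimulus mean, per timepoint
  flat <- dat
  dim(flat) <- c(n, C * Tn)
  g <- rowsum(flat, sid)
  counts <- as.vector(table(sid)[rownames(g)])
  means <- g / counts
  res <- flat - means[match(sid, as.integer(rownames(g))), , drop = FALSE]
  dim(res) <- c(n, C, Tn)

  if (method == "pooled") {
    samples <- matrix(aperm(res, c(1, 3, 2)), n * Tn, C)
    lw <- ledoit_wolf(samples)
    out <- list(matrix = lw$matrix, shrinkage = lw$shrinkage,
                method = method, n_samples = n * Tn,
                n_cells = length(unique(sid)) * Tn)
  } else {
    acc <- matrix(0, C, C)
    shr <- 0
    stim_rows <- split(seq_len(n), sid)
    n_cells <- 0L
    for (rows in stim_rows) {
      for (t in seq_len(Tn)) {
        lw <- ledoit_wolf(res[rows, , t, drop = TRUE])
        acc <- acc + lw$matrix
        shr <- shr + lw$shrinkage
        n_cells <- n_cells + 1L
      }
    }
    out <- list(matrix = acc / n_cells, shrinkage = shr / n_cells,
                method = method, n_samples = n * Tn, n_cells = n_cells)
  }
  structure(out, class = "noise_covariance")
}

#' @export
print.noise_covariance <- function(x, ...) {
  cat("<noise_covariance> ", nrow(x$matrix), " channels, method=", x$method,
      ", shrinkage=", signif(x$shrinkage, 3), ", cells=", x$n_cells, "\n",
      sep = "")
  invisible(x)
}

#' Symmetric inverse matrix square root
#'
#' Eigendecomposition route: for SPD `Sigma = V L V'`, returns
#' `M = V L^{-1/2} V'`, the unique symmetric matrix with
#' `M %*% Sigma %*% M = I`.
#'
#' @param x A symmetric positive-definite matrix.
#' @param tol Relative eigenvalue floor; eigenvalues at or below
#'   `tol * max(eigenvalue)` raise an error.
#' @return The symmetric inverse square root of `x`.
#' @export
inverse_sqrt <- function(x, tol = 1e-12) {
  if (!is.matrix(x) || !isTRUE(all.equal(x, t(x), tolerance = 1e-8))) {
    stop("input must be a symmetric matrix")
  }
  e <- eigen((x + t(x)) / 2, symmetric = TRUE)
  if (any(e$values <= tol * max(e$values))) {
    stop("matrix is not positive-definite within tolerance")
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Whiten epoched EEG with a noise covariance
#'
#' Multiplies every (trial, timepoint) channel vector by the symmetric
#' inverse square root of the noise covariance. The covariance is estimated
#' once (on the training split) and the same whitener is applied to all
#' splits, so noise becomes decorrelated with approximately unit variance
#' across channels.
#'
#' @param epochs An `eeg_epochs` object.
#' @param noise_cov A `noise_covariance` from [estimate_noise_covariance()],
#'   or a plain SPD matrix.
#' @return The whitened `eeg_epochs` (a `whitener` attribute records the
#'   matrix applied).
#' @export
whiten <- function(epochs, noise_cov) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  M <- if (inherits(noise_cov, "noise_covariance")) noise_cov$matrix else noise_cov
  if (nrow(M) != dim(epochs$data)[2]) stop("channel count mismatch")
  W <- inverse_sqrt(M)
  d <- dim(epochs$data)
  for (t in seq_len(d[3])) {
    epochs$data[, , t] <- epochs$data[, , t] %*% W  # W symmetric
  }
  epochs$whitener <- W
  epochs
}

#' Multivariate noise normalization in one step
#'
#' Convenience wrapper: estimates the noise covariance on the training split
#' and whitens all splits with it.
#'
#' @inheritParams estimate_noise_covariance
#' @return The whitened `eeg_epochs`.
#' @export
mvnn <- function(epochs, method = c("pooled", "per_cell"),
                 timepoints = c("all", "prestim")) {
  nc <- estimate_noise_covariance(epochs, split = "train",
                                  method = match.arg(method),
                                  timepoints = match.arg(timepoints))
  out <- whiten(epochs, nc)
  out$noise_cov <- nc
  out
}
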