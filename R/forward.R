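#' Forward model for simulated epoched EEG
#'
#' Describes how planted feature signals reach the sensors. Each feature f
#' contributes `kappa_f(t) * (a_f(s)' P_f W_f)` to the channel pattern of
#' stimulus s: the flattened annotation is projected to a rank-`latent_rank`
#' feature signal, mixed into channels, and modulated by a Gaussian temporal
#' kernel `kappa_f(t) = exp(-(t - tau_f)^2 / (2 sigma_f^2))` truncated to
#' t >= 0 so the pre-stimulus window contains noise only. Every trial adds
#' spatially correlated Gaussian noise with channel covariance `Sigma_noise`.
#'
#' Default planted latencies follow the low-to-high feature ordering reported
#' for this class of experiments and sit on the 50 Hz sampling grid, 80 ms
#' (edges) to 420 ms (action identity).
#'
#' @param features Feature names; must match the annotation set.
#' @param tau_ms Planted peak latency per feature (ms).
#' @param sigma_ms Temporal kernel SD per feature (ms); recycled.
#' @param amplitude Per-feature signal amplitude; recycled.
#' @param latent_rank Rank of each feature's channel projection.
#' @param n_channels Number of channels (default 19 posterior channels).
#' @param time_ms Epoch time axis (default -400..980 ms at 50 Hz, 70 points).
#' @param reps Repetitions per stimulus per split
#'   (default 5 train / 30 test / 5 validation).
#' @param noise_corr Channel noise correlation; either a channels x channels
#'   SPD matrix or a scalar `r` giving `corr(c, c') = r^|c - c'|`.
#' @param noise_scale Per-channel noise SD.
#' @param ar1_phi Temporal AR(1) coefficient of the noise (0 = white).
#' @return A list of class `forward_model_spec`.
#' @export
forward_model_spec <- function(
    features = c("edges", "reflectance", "lighting", "world_normals",
                 "scene_depth", "skeleton", "action"),
    tau_ms = c(80, 120, 160, 180, 200, 260, 420),
    sigma_ms = 25,
    amplitude = 1,
    latent_rank = 5L,
    n_channels = 19L,
    time_ms = seq(-400, 980, by = 20),
    reps = c(train = 5L, test = 30L, validation = 5L),
    noise_corr = 0.5,
    noise_scale = 3,
    ar1_phi = 0) {
  nf <- length(features)
  tau_ms <- rep_len(tau_ms, nf)
  sigma_ms <- rep_len(sigma_ms, nf)
  amplitude <- rep_len(amplitude, nf)
  if (is.matrix(noise_corr)) {
    if (!isTRUE(all.equal(noise_corr, t(noise_corr))) ||
        any(eigen(noise_corr, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
      stop("noise_corr matrix must be symmetric positive-definite")
    }
    Sigma <- noise_corr
  } else {
    Sigma <- noise_corr^abs(outer(seq_len(n_channels), seq_len(n_channels), "-"))
  }
  structure(
    list(features = features, tau_ms = setNames(tau_ms, features),
         sigma_ms = setNames(sigma_ms, features),
         amplitude = setNames(amplitude, features),
         latent_rank = as.integer(latent_rank),
         n_channels = as.integer(n_channels), time_ms = time_ms,
         reps = reps, Sigma_noise = Sigma * noise_scale^2,
         noise_scale = noise_scale, ar1_phi = ar1_phi),
    class = "forward_model_spec"
  )
}

# Gaussian temporal response kernel, truncated to post-onset samples.
response_kernel <- function(time_ms, tau_ms, sigma_ms) {
  k <- exp(-(time_ms - tau_ms)^2 / (2 * sigma_ms^2))
  k[time_ms < 0] <- 0
  k
}

# Noise-free per-stimulus channel signal for each feature:
# standardized annotation projection a' P (stimuli x rank), mixed by W into
# channels, scaled by the feature amplitude. Returns list of S x C matrices.
feature_signals <- function(annotations, spec) {
  purrr::map(setNames(spec$features, spec$features), function(fname) {
    f <- annotations$features[[fname]]
    if (is.null(f)) stop("annotations missing feature: ", fname)
    M <- f$data
    if (annotations$mode == "video") M <- apply(M, c(1, 3), mean)
    D <- ncol(M); k <- spec$latent_rank
    P <- matrix(rnorm(D * k), D, k) / sqrt(D)
    X <- M %*% P
    X <- scale(X)                     # unit-variance latent signal
    X[is.nan(X)] <- 0
    W <- matrix(rnorm(k * spec$n_channels), k, spec$n_channels) / sqrt(k)
    spec$amplitude[[fname]] * (X %*% W)
  })
}

#' Simulate epoched EEG from a stimulus design and annotations
#'
#' Implements the forward model of [forward_model_spec()]: each trial is the
#' stimulus' deterministic feature signal plus a fresh spatially correlated
#' noise draw. Trial counts per split follow `spec$reps` (defaults give
#' 5400 train / 5400 test / 900 validation trials for the 1080/180/180 design).
#'
#' @param design Stimulus design from [make_design()].
#' @param annotations Matching `annotation_set`.
#' @param spec A [forward_model_spec()].
#' @param seed Integer seed; identical seeds give bit-identical epochs.
#' @return An `eeg_epochs` object: `data` (trials x channels x timepoints),
#'   `time_ms`, `channels`, and a `trial_table` tibble linking every trial to
#'   its stimulus and split.
#' @export
simulate_eeg <- function(design, annotations, spec = forward_model_spec(),
                         seed = 1L) {
  stopifnot(inherits(spec, "forward_model_spec"))
  if (nrow(design) != length(annotations$stimulus_id)) {
    stop("annotations missing stimuli from the design")
  }
  set.seed(seed)
  S <- nrow(design); C <- spec$n_channels; Tn <- length(spec$time_ms)

  sig_f <- feature_signals(annotations, spec)
  signal <- array(0, c(S, C, Tn))
  for (fname in spec$features) {
    kappa <- response_kernel(spec$time_ms, spec$tau_ms[[fname]],
                             spec$sigma_ms[[fname]])
    signal <- signal + outer(sig_f[[fname]], kappa)
  }

  split_chr <- as.character(design$split)
  reps <- spec$reps[split_chr]
  trial_table <- tibble::tibble(
    stimulus_id = rep(design$stimulus_id, reps),
    split = factor(rep(split_chr, reps), levels = c("train", "test", "validation"))
  )
  trial_table <- dplyr::mutate(trial_table, trial = dplyr::row_number(),
                               .before = 1)
  n_trials <- nrow(trial_table)
  stim_row <- match(trial_table$stimulus_id, design$stimulus_id)

  noiseless <- max(abs(spec$Sigma_noise)) == 0
  R <- if (noiseless) NULL else chol(spec$Sigma_noise)
  data <- array(0, c(n_trials, C, Tn))
  noise_t <- matrix(0, n_trials, C)
  for (t in seq_len(Tn)) {
    if (noiseless) {
      data[, , t] <- signal[stim_row, , t]
      next
    }
    z <- matrix(rnorm(n_trials * C), n_trials, C)
    if (spec$ar1_phi != 0 && t > 1) {
      noise_t <- spec$ar1_phi * noise_t + sqrt(1 - spec$ar1_phi^2) * z
    } else {
      noise_t <- z
    }
    data[, , t] <- signal[stim_row, , t] + noise_t %*% R
  }

  structure(
    list(data = data, time_ms = spec$time_ms,
         channels = paste0("ch", seq_len(C)), trial_table = trial_table,
         spec = spec, seed = seed),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("<eeg_epochs> ", dim(x$data)[1], " trials x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " timepoints (",
      min(x$time_ms), "..", max(x$time_ms), " ms)\n", sep = "")
  print(table(x$trial_table$split))
  invisible(x)
}

# Subset an eeg_epochs object by trial indices.
subset_trials <- function(epochs, idx) {
  out <- epochs
  out$data <- epochs$data[idx, , , drop = FALSE]
  out$trial_table <- dplyr::mutate(epochs$trial_table[idx, ],
                                   trial = dplyr::row_number())
  out
}

# Stimulus-averaged responses of one split as a matrix
# (stimuli x (channels * timepoints), channel varying fastest), plus ids.
split_stimulus_means <- function(epochs, split) {
  idx <- which(epochs$trial_table$split == split)
  if (length(idx) == 0) stop("missing split: ", split)
  d <- dim(epochs$data)
  flat <- epochs$data[idx, , , drop = FALSE]
  dim(flat) <- c(length(idx), d[2] * d[3])
  sid <- epochs$trial_table$stimulus_id[idx]
  g <- rowsum(flat, sid)
  counts <- as.vector(table(sid)[rownames(g)])
  list(mean = g / counts, stimulus_id = as.integer(rownames(g)))
}
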