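# Shared desk-scale fixtures, built once per test run and cached in this
# environment so individual files stay fast.
.fixtures <- new.env(parent = emptyenv())

# A small but structurally complete experiment: 4 rooms (1 held out),
# 3 actions, 2 characters, 2 cameras -> 48 stimuli (36/6/6 split).
tiny_design <- function(seed = 42) {
  make_design(n_rooms = 4, n_actions = 3, n_characters = 2, n_cameras = 2,
              split_spec = design_split_spec(n_holdout_rooms = 1,
                                             n_test_cameras = 1),
              seed = seed)
}

tiny_annotation_spec <- function(rho = 0.1) {
  annotation_spec(
    features = default_feature_set(map_dim = c(8L, 6L), n_actions = 3L),
    latent_rank = 5L, rho = rho, pixel_noise = 0.05)
}

tiny_forward_spec <- function(...) {
  args <- utils::modifyList(
    list(tau_ms = c(80, 120, 160, 180, 200, 260, 420), sigma_ms = 25,
         latent_rank = 3L, n_channels = 8L,
         reps = c(train = 4L, test = 12L, validation = 4L),
         noise_scale = 1.5),
    list(...))
  do.call(forward_model_spec, args)
}

tiny_layer_spec <- function() {
  layer_model_spec(units_per_layer = 20L, noise_scale = 0.4)
}

# Full tiny experiment (design + annotations + whitened epochs + matrices),
# cached across test files.
tiny_experiment <- function() {
  if (!is.null(.fixtures$tiny)) return(.fixtures$tiny)
  design <- tiny_design()
  ann <- simulate_annotations(design, tiny_annotation_spec(), seed = 11)
  eeg <- simulate_eeg(design, ann, tiny_forward_spec(), seed = 12)
  white <- mvnn(baseline_correct(eeg))
  dm <- prepare_design_matrices(ann, design, n_components = 20)
  .fixtures$tiny <- list(design = design, annotations = ann, eeg = eeg,
                         white = white, dm = dm)
  .fixtures$tiny
}

# Random SPD matrix with a given size and condition spread.
random_spd <- function(p, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(p) * 0.5
}

# brute-force step-up oracle used to validate the BH implementation
bh_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(m) / m)
  reject_sorted <- rep(FALSE, m)
  if (length(k) > 0) reject_sorted[seq_len(max(k))] <- TRUE
  reject <- logical(m)
  reject[o] <- reject_sorted
  adj_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- numeric(m)
  adj[o] <- pmin(adj_sorted, 1)
  list(adjusted = adj, reject = reject)
}


# empirical channel covariance of whitened within-stimulus residuals
whitened_residual_cov <- function(ep, split = "train") {
  idx <- which(ep$trial_table$split == split)
  sid <- ep$trial_table$stimulus_id[idx]
  d <- dim(ep$data)
  flat <- ep$data[idx, , , drop = FALSE]
  dim(flat) <- c(length(idx), d[2] * d[3])
  g <- rowsum(flat, sid)
  cnt <- as.vector(table(sid))
  res <- flat - (g / cnt)[match(sid, as.integer(rownames(g))), ]
  dim(res) <- c(length(idx), d[2], d[3])
  samples <- matrix(aperm(res, c(1, 3, 2)), length(idx) * d[3], d[2])
  crossprod(samples) / nrow(samples)
}
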