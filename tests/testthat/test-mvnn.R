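test_that("baseline correction zeroes the pre-stimulus window mean", {
  fx <- tiny_experiment()
  bc <- baseline_correct(fx$eeg, c(-100, 0))
  sel <- which(bc$time_ms >= -100 & bc$time_ms <= 0)
  base_means <- apply(bc$data[, , sel], c(1, 2), mean)
  expect_lt(max(abs(base_means)), 1e-10)
  # constant trial becomes all zeros
  ep <- fx$eeg
  ep$data[1, , ] <- 3
  bc2 <- baseline_correct(ep)
  expect_equal(max(abs(bc2$data[1, , ])), 0)
  expect_error(baseline_correct(fx$eeg, c(100, 200)), "before 0 ms")
})

test_that("Ledoit-Wolf shrinkage matches the scikit-learn estimator on a frozen fixture", {
  X <- matrix(c(
    0.002, -1.983, 0.98, 1.391, -3.683, -0.374, -3.06, -1.615,
    0.448, 0.09, 0.535, -2.016, -0.353, -3.775, -0.717, -0.049,
    -0.274, 1.34, 0.105, -0.458, -1.267, -0.539, -0.979, 0.884,
    -0.623, -0.345, -0.651, -1.331, 0.19, -0.034, -0.566, -0.409,
    -0.227, -0.31, -0.015, -0.645, 0.078, 0.057, 0.53, -0.056), nrow = 8)
  Xc <- sweep(X, 2, colMeans(X))
  lw <- eegencode:::ledoit_wolf(Xc)
  expect_equal(lw$shrinkage, 0.4493584656671326, tolerance = 1e-12)
  oracle <- matrix(c(
    2.16441763567538, -0.2449637445107312, 0.13802477061856158,
    -0.2774679766220167, -0.18933175920271164,
    -0.2449637445107312, 1.5715862481140175, 0.22377793193010978,
    -0.016378600136833846, 0.007826302542568945,
    0.13802477061856158, 0.22377793193010978, 0.9079645053516571,
    -0.023395210114488217, -0.05813453062872682,
    -0.2774679766220167, -0.016378600136833846, -0.023395210114488217,
    0.6258285081412033, 0.03960595922486427,
    -0.18933175920271164, 0.007826302542568945, -0.05813453062872682,
    0.03960595922486427, 0.5819348839677424), 5, 5, byrow = TRUE)
  expect_equal(lw$matrix, oracle, tolerance = 1e-12)
})

test_that("noise covariance estimation recovers known structure and converges", {
  # iid N(0, I) noise: estimate approaches the identity as data grow
  make_noise_epochs <- function(n_rep, seed) {
    design <- make_design(3, 2, 2, 2, design_split_spec(0, 1), seed = 1)
    ann <- simulate_annotations(design, tiny_annotation_spec(), seed = 2)
    spec <- forward_model_spec(amplitude = 0, latent_rank = 2, n_channels = 6,
                               time_ms = seq(-100, 300, 20),
                               reps = c(train = n_rep, test = 2, validation = 2),
                               noise_corr = 1e-9, noise_scale = 1)
    simulate_eeg(design, ann, spec, seed = seed)
  }
  err <- sapply(c(3, 24), function(nr) {
    est <- estimate_noise_covariance(make_noise_epochs(nr, 5))
    norm(est$matrix - diag(6), "F")
  })
  expect_lt(err[2], err[1])    # Frobenius error shrinks with repetitions
  expect_lt(err[2], 0.25)
  # exponentially decaying structure is recovered
  fx <- tiny_experiment()
  est <- estimate_noise_covariance(fx$eeg)
  truth <- fx$eeg$spec$Sigma_noise
  expect_gt(cor(est$matrix[upper.tri(truth)], truth[upper.tri(truth)]), 0.9)
  expect_error(estimate_noise_covariance(fx$eeg, split = "nope"),
               "missing split")
})

test_that("identical repetitions give a near-zero noise covariance", {
  design <- make_design(2, 2, 1, 1, design_split_spec(0, 0), seed = 1)
  ann <- simulate_annotations(design, tiny_annotation_spec(), seed = 2)
  spec <- forward_model_spec(latent_rank = 2, n_channels = 5,
                             time_ms = seq(-100, 300, 20),
                             reps = c(train = 4, test = 2, validation = 2),
                             noise_scale = 0)
  ep <- simulate_eeg(design, ann, spec, seed = 3)
  est <- estimate_noise_covariance(ep)
  expect_lt(max(abs(est$matrix)), 1e-20)
})

test_that("inverse_sqrt satisfies its defining identity", {
  expect_equal(inverse_sqrt(diag(3)), diag(3))
  expect_equal(inverse_sqrt(diag(c(4, 9))), diag(c(0.5, 1 / 3)))
  S <- random_spd(12, seed = 6)
  M <- inverse_sqrt(S)
  expect_lt(norm(M %*% S %*% M - diag(12), "F"), 1e-8)
  expect_equal(M, t(M), tolerance = 1e-10)
  expect_error(inverse_sqrt(matrix(1:4, 2)), "symmetric")
  sing <- diag(c(1, 0))
  expect_error(inverse_sqrt(sing), "positive-definite")
})

test_that("whitening scales and decorrelates as expected", {
  fx <- tiny_experiment()
  ep <- fx$eeg
  C <- dim(ep$data)[2]
  expect_equal(whiten(ep, diag(C))$data, ep$data)
  expect_equal(whiten(ep, 4 * diag(C))$data, ep$data / 2)
  # whitening commutes with averaging repetitions
  w <- whiten(ep, estimate_noise_covariance(ep))
  m_raw <- eegencode:::split_stimulus_means(ep, "train")$mean
  m_white <- eegencode:::split_stimulus_means(w, "train")$mean
  Tn <- dim(ep$data)[3]
  m_raw_white <- matrix(0, nrow(m_raw), ncol(m_raw))
  for (t in seq_len(Tn)) {
    cols <- ((t - 1) * C + 1):(t * C)
    m_raw_white[, cols] <- m_raw[, cols] %*% w$whitener
  }
  expect_equal(m_white, m_raw_white, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("MVNN whitens synthetic correlated noise and is idempotent", {
  fx <- tiny_experiment()
  w <- mvnn(baseline_correct(fx$eeg))
  emp <- whitened_residual_cov(w)
  expect_lt(max(abs(emp - diag(diag(emp)))), 0.1)
  expect_lt(max(abs(diag(emp) - 1)), 0.1)
  # re-whitening already-white data changes almost nothing
  w2 <- mvnn(w)
  expect_lt(max(abs(w2$data - w$data)) / max(abs(w$data)), 0.05)
})

test_that("per-cell shrinkage is reported and much stronger than pooled", {
  fx <- tiny_experiment()
  pooled <- estimate_noise_covariance(fx$eeg, method = "pooled")
  cell <- estimate_noise_covariance(fx$eeg, method = "per_cell")
  expect_lt(pooled$shrinkage, 0.05)
  expect_gt(cell$shrinkage, pooled$shrinkage)
  expect_equal(cell$n_cells,
               36 * length(fx$eeg$time_ms))  # stimuli x timepoints
  # shrinkage guarantees invertibility even with channels > repetitions:
  # 4 repetitions against 8 channels, both estimators stay SPD
  expect_no_error(inverse_sqrt(pooled$matrix))
  expect_no_error(inverse_sqrt(cell$matrix))
})
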