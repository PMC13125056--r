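test_that("ridge at lambda -> 0 equals least squares and recovers exact linear data", {
  set.seed(1)
  X <- matrix(rnorm(60 * 5), 60, 5)
  B <- matrix(rnorm(5 * 3), 5, 3)
  Y <- X %*% B + 2
  fit0 <- fit_ridge(X, Y, 0)
  ols <- lm(Y ~ X)
  expect_lt(max(abs(fit0$beta - coef(ols)[-1, ])), 1e-6)
  expect_lt(max(abs(fit0$intercept - coef(ols)[1, ])), 1e-6)
  fit_small <- fit_ridge(X, Y, 1e-8)
  expect_lt(max(abs(fit_small$beta - B)), 1e-6)
  expect_lt(max(abs(predict(fit_small, X) - Y)), 1e-5)
})

test_that("ridge matches an independent penalized-loss minimizer", {
  set.seed(2)
  X <- matrix(rnorm(25 * 3), 25, 3)
  y <- X %*% c(1, -2, 0.5) + rnorm(25)
  lambda <- 4
  fit <- fit_ridge(X, y, lambda)
  # independent oracle: numeric minimization of the centered ridge loss
  xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  loss <- function(b) sum((yc - xc %*% b)^2) + lambda * sum(b^2)
  opt <- optim(rep(0, 3), loss, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_lt(max(abs(fit$beta - opt$par)), 1e-5)
})

test_that("infinite shrinkage sends coefficients to zero and predictions to the mean", {
  set.seed(3)
  X <- matrix(rnorm(40 * 4), 40, 4)
  Y <- matrix(rnorm(40 * 2), 40, 2)
  fit <- fit_ridge(X, Y, 1e12)
  expect_lt(max(abs(fit$beta)), 1e-8)
  expect_equal(predict(fit, X)[1, ], colMeans(Y), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(fit_ridge(X, Y, -1), "non-negative")
  Xn <- X; Xn[1, 1] <- NA
  expect_error(fit_ridge(Xn, Y, 1), "NaN/NA")
})

test_that("lambda selection maximizes validation correlation with ties to the smaller value", {
  set.seed(4)
  X <- matrix(rnorm(50 * 4), 50, 4)
  B <- matrix(rnorm(4 * 3), 4, 3)
  Xv <- matrix(rnorm(30 * 4), 30, 4)
  grid <- 10^seq(-5, 15, length.out = 30)
  # noiseless linear validation data: the smallest penalty wins
  sel <- select_lambda(X, X %*% B, Xv, Xv %*% B, grid)
  expect_equal(sel$lambda, grid[1])
  expect_equal(nrow(sel$curve), 30)
  # single-value grid returns that value
  expect_equal(select_lambda(X, X %*% B, Xv, Xv %*% B, 7)$lambda, 7)
  # pure-noise validation: all grid values admissible, result lies on the grid
  sel_null <- suppressWarnings(
    select_lambda(X, matrix(rnorm(150), 50, 3), Xv,
                  matrix(rnorm(90), 30, 3), grid))
  expect_true(sel_null$lambda %in% grid)
  # constant validation column warns and scores r = 0
  Yv_const <- cbind(Xv %*% B[, 1], 5)
  expect_warning(
    select_lambda(X, cbind(X %*% B[, 1], rnorm(50)), Xv, Yv_const, grid),
    "constant")
})

test_that("weighted component correlation reduces to the mean under equal weights", {
  expect_equal(weighted_correlation(c(0.9, 0.3), c(2, 1)), 0.7)
  r <- c(0.2, 0.5, 0.8)
  expect_equal(weighted_correlation(r, rep(3, 3)), mean(r))
  expect_error(weighted_correlation(r, c(1, 2)), "length")
  expect_error(weighted_correlation(r, c(1, -1, 2)), "non-negative")
})

test_that("EEG encoding recovers a single-feature forward model", {
  design <- tiny_design()
  ann <- simulate_annotations(design, tiny_annotation_spec(), seed = 41)
  # near-noiseless: the generative model is linear, so r at the planted
  # latency approaches 1 (and stays ~1 wherever any signal is present)
  spec0 <- tiny_forward_spec(noise_scale = 1e-4,
                             amplitude = c(1, 0, 0, 0, 0, 0, 0))
  ep0 <- simulate_eeg(design, ann, spec0, seed = 42)
  dm <- prepare_design_matrices(ann, design, n_components = 20)
  enc0 <- suppressWarnings(encode_eeg(dm, ep0))
  curve0 <- enc0$accuracy[enc0$accuracy$feature == "edges", ]
  expect_gt(curve0$r[curve0$time_ms == 80], 0.99)
  # with measurement noise the correlation curve is no longer flat over the
  # signal window, and its peak localizes the planted latency
  spec1 <- tiny_forward_spec(noise_scale = 1, amplitude = c(1, 0, 0, 0, 0, 0, 0))
  ep1 <- simulate_eeg(design, ann, spec1, seed = 43)
  enc1 <- suppressWarnings(encode_eeg(dm, mvnn(baseline_correct(ep1))))
  curve1 <- enc1$accuracy[enc1$accuracy$feature == "edges", ]
  # with only 6 test stimuli the peak is recovered to within one sample
  expect_lte(abs(peak_location(curve1$r, curve1$time_ms) - 80), 20)
  expect_gt(max(curve1$r), 0.8)
  # all surfaces bounded in [-1, 1]
  expect_true(all(vapply(enc1$surfaces, function(s) all(abs(s) <= 1 + 1e-12),
                         logical(1))))
})

test_that("penalty selection never sees the test split", {
  fx <- tiny_experiment()
  enc1 <- encode_eeg(fx$dm, fx$white)
  pert <- fx$white
  test_idx <- which(pert$trial_table$split == "test")
  pert$data[test_idx, , ] <- pert$data[test_idx, , ] + 50
  enc2 <- encode_eeg(fx$dm, pert)
  expect_identical(enc1$lambda, enc2$lambda)
})

test_that("shuffled predictors yield a flat near-zero encoding time course", {
  fx <- tiny_experiment()
  dm_shuf <- fx$dm
  set.seed(5)
  for (f in names(dm_shuf$features)) {
    for (s in c("train", "validation", "test")) {
      m <- dm_shuf$features[[f]][[s]]
      dm_shuf$features[[f]][[s]] <- m[sample(nrow(m)), , drop = FALSE]
    }
  }
  enc <- suppressWarnings(encode_eeg(dm_shuf, fx$white))
  expect_lt(max(abs(enc$accuracy$r)), 0.9)     # single surrogate, wide bound
  expect_lt(abs(mean(enc$accuracy$r)), 0.12)
})

test_that("layer encoding recovers planted peak layers and weights components correctly", {
  fx <- tiny_experiment()
  acts <- simulate_layer_activations(fx$design, fx$annotations,
                                     tiny_layer_spec(), seed = 51)
  expect_equal(names(acts$activations),
               c("1.0", "1.1", "2.0", "2.1", "3.0", "3.1", "4.0", "4.1"))
  la <- prepare_layer_activations(acts, fx$design, var_threshold = 0.9)
  for (l in la$layers) {
    ev <- l$pca$explained_variance
    expect_true(all(diff(ev) <= 1e-12))
  }
  le <- encode_layers(fx$dm, la)
  g <- glance(le)
  planted <- tiny_layer_spec()$peak_idx
  expect_equal(setNames(g$peak_index, g$feature)[names(planted)],
               planted, ignore_attr = TRUE)
  expect_error(layer_model_spec(peak_layer = "9.9"), "outside")
  expect_error(layer_model_spec(units_per_layer = 0), ">= 1")
})

test_that("noise ceiling bounds behave at the extremes and bound encoding accuracy", {
  # noiseless repetitions: lower = upper = 1 everywhere post-onset
  design <- tiny_design()
  ann <- simulate_annotations(design, tiny_annotation_spec(), seed = 61)
  spec <- tiny_forward_spec(noise_scale = 0)
  ep0 <- simulate_eeg(design, ann, spec, seed = 62)
  nc0 <- noise_ceiling(ep0, n_reps = 5, seed = 1)
  post <- which(ep0$time_ms >= 60 & ep0$time_ms <= 460)
  expect_true(all(abs(nc0$lower[, post] - 1) < 1e-8))
  expect_true(all(abs(nc0$upper[, post] - 1) < 1e-8))
  # stimulus-independent responses: the lower bound hovers near zero; the
  # upper bound sits near sqrt(1/2) because the half group's trials are
  # contained in the all-trials group, so their noise is shared
  pure <- tiny_forward_spec(amplitude = 0)
  ep_n <- simulate_eeg(design, ann, pure, seed = 63)
  nc_n <- noise_ceiling(ep_n, n_reps = 50, seed = 2)
  expect_lt(abs(mean(nc_n$summary$lower)), 0.15)
  expect_lt(max(abs(nc_n$summary$lower)), 0.4)
  expect_gt(mean(nc_n$summary$upper), 0.45)
  expect_lt(mean(nc_n$summary$upper), 0.85)
  # on noisy data the upper bound caps the channel-mean encoding accuracy
  fx <- tiny_experiment()
  nc <- noise_ceiling(fx$white, n_reps = 50, seed = 3)
  enc <- encode_eeg(fx$dm, fx$white)
  sig_win <- which(fx$white$time_ms >= 60 & fx$white$time_ms <= 460)
  for (f in names(enc$surfaces)) {
    feat_curve <- colMeans(enc$surfaces[[f]])[sig_win]
    expect_true(all(feat_curve <= nc$summary$upper[sig_win] + 0.1))
  }
  expect_error(noise_ceiling(ep0, split = "nope"), "missing split")
})
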