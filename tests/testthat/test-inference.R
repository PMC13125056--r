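test_that("BH adjustment matches a brute-force step-up oracle", {
  res <- fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05), alpha = 0.05)
  expect_true(all(res$significant))  # p(i) <= i * alpha / m for all i
  expect_false(any(fdr_bh(rep(1, 6))$significant))
  expect_equal(fdr_bh(0.031)$p_adjusted, 0.031)
  set.seed(1)
  for (m in 1:12) {
    for (rep_i in 1:25) {
      p <- round(runif(m)^sample(c(1, 3), 1), 3)
      res <- fdr_bh(p, alpha = 0.05)
      oracle <- bh_oracle(p, 0.05)
      expect_equal(res$p_adjusted, oracle$adjusted, tolerance = 1e-12)
      expect_identical(res$significant, oracle$reject)
    }
  }
  p20 <- runif(20)
  res20 <- fdr_bh(p20)
  expect_true(all(res20$p_adjusted >= res20$p_value))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("sign-permutation p-values hit the floor for strong effects and 1 at chance", {
  vals <- matrix(50, nrow = 8, ncol = 3)  # all subjects exactly at chance
  res <- sign_permutation_test(vals, chance = 50, n_perm = 500, seed = 1)
  expect_true(all(res$p_value == 1))
  # far-above-chance values: only all-same-sign draws match the observed mean,
  # so p sits at (or within a few draws of) the attainable floor 1/(n_perm+1)
  strong <- matrix(rnorm(15 * 3, mean = 60, sd = 0.01), 15, 3)
  res2 <- sign_permutation_test(strong, chance = 50, n_perm = 500, seed = 2)
  expect_true(all(res2$p_value <= 3 / 501))
  expect_true(all(res2$significant))
  expect_error(sign_permutation_test(matrix(1, 1, 3)), "2 subjects")
})

test_that("sign and swap tests are calibrated under a simulated null", {
  set.seed(3)
  n_rep <- 400
  rej_sign <- mean(vapply(seq_len(n_rep), function(i) {
    v <- matrix(rnorm(12), ncol = 1)
    sign_permutation_test(v, chance = 0, n_perm = 300, seed = i)$p_value <= 0.05
  }, logical(1)))
  expect_gte(rej_sign, 0.02)
  expect_lte(rej_sign, 0.09)
  rej_swap <- mean(vapply(seq_len(n_rep), function(i) {
    condition_swap_test(matrix(rnorm(8), ncol = 1), matrix(rnorm(10), ncol = 1),
                        n_perm = 300, seed = i)$p_value <= 0.05
  }, logical(1)))
  expect_gte(rej_swap, 0.02)
  expect_lte(rej_swap, 0.09)
})

test_that("condition-swap test separates shifted groups and accepts identical ones", {
  set.seed(4)
  a <- matrix(rnorm(10 * 2), 10, 2)
  res_same <- condition_swap_test(a, a, n_perm = 400, seed = 5)
  expect_true(all(res_same$p_value > 0.5))
  b <- a + 10  # 10 SDs apart
  res_far <- condition_swap_test(a[1:5, ], b, n_perm = 400, seed = 6)
  expect_true(all(res_far$p_value < 0.02))  # at or near the attainable floor
  expect_true(all(res_far$significant))
  expect_error(condition_swap_test(a[0, , drop = FALSE], a), "non-empty")
})

test_that("bootstrap mean CIs cover and transform correctly", {
  expect_equal(bootstrap_ci_mean(rep(2.5, 6), n_boot = 100),
               c(lo = 2.5, hi = 2.5))
  set.seed(7)
  x <- rnorm(20)
  ci <- bootstrap_ci_mean(x, n_boot = 2000, seed = 1)
  # affine equivariance: CI of 3x + 1 is 3*CI + 1
  ci2 <- bootstrap_ci_mean(3 * x + 1, n_boot = 2000, seed = 1)
  expect_equal(ci2, 3 * ci + 1, tolerance = 1e-10)
  # coverage simulation
  cover <- mean(vapply(1:300, function(i) {
    set.seed(i + 1000)
    ci_i <- bootstrap_ci_mean(rnorm(20), n_boot = 400, seed = i)
    ci_i["lo"] <= 0 && ci_i["hi"] >= 0
  }, logical(1)))
  expect_gte(cover, 0.90)
  expect_lte(cover, 0.99)
  # width shrinks with sample size
  set.seed(8)
  w5 <- diff(bootstrap_ci_mean(rnorm(5), n_boot = 1000, seed = 2))
  w50 <- diff(bootstrap_ci_mean(rnorm(50), n_boot = 1000, seed = 2))
  expect_gt(w5, w50)
  expect_error(bootstrap_ci_mean(numeric(0)), "empty")
})

test_that("peak extraction uses the grid and breaks ties to the earliest point", {
  grid <- seq(-400, 980, by = 20)
  curve <- rep(0, 70)
  curve[6] <- 1  # index 6 -> -400 + 5 * 20
  expect_equal(peak_location(curve, grid), -300)
  expect_equal(peak_location(rep(1, 70), grid), -400)
  expect_error(peak_location(rep(NA_real_, 3)), "finite")
})

test_that("bootstrap peak CIs cover planted structure", {
  grid <- seq(0, 200, 20)
  shared <- exp(-(grid - 120)^2 / 800)
  curves <- do.call(rbind, replicate(6, shared, simplify = FALSE))
  pe <- bootstrap_peak_ci(curves, grid, n_boot = 300, seed = 1)
  expect_equal(pe$peak, 120)
  expect_equal(pe$lo, 120)
  expect_equal(pe$hi, 120)  # zero-width CI for identical sharp peaks
  # planted 100 ms difference at high SNR: difference CI excludes 0
  set.seed(9)
  mk <- function(tau) do.call(rbind, lapply(1:8, function(i)
    exp(-(grid - tau)^2 / 800) + rnorm(length(grid), sd = 0.03)))
  d <- bootstrap_peak_difference(mk(60), mk(160), grid, n_boot = 500, seed = 2)
  expect_true(d$significant)
  expect_lt(d$hi, 0)
  same <- mk(100)
  d0 <- bootstrap_peak_difference(same, same, grid, n_boot = 500, seed = 3)
  expect_false(d0$significant)
})

test_that("hierarchy correlation enumerates all orderings exactly", {
  lat <- c(80, 120, 160, 180, 200, 260, 420)
  layers <- 1:7
  h <- hierarchy_correlation(lat, layers)
  expect_equal(h$rho, 1)
  expect_equal(h$n_permutations, 5040)  # 7! orderings
  expect_equal(h$p_value, 1 / 5040)     # only the identity reaches rho = 1
  expect_true(h$exact)
  rev_h <- hierarchy_correlation(lat, rev(layers), alternative = "two.sided")
  expect_equal(rev_h$rho, -1)
  expect_error(hierarchy_correlation(lat, 1:6), "length")
  expect_error(hierarchy_correlation(lat[1:2], layers[1:2]), "at least 3")
})

test_that("hierarchy correlation matches stats::cor and its Monte-Carlo p-value", {
  set.seed(10)
  lat <- c(100, 140, 120, 260, 230, 300, 420)
  layers <- c(2, 1, 3, 5, 4, 7, 6)
  h <- hierarchy_correlation(lat, layers)
  expect_equal(h$rho, cor(lat, layers, method = "spearman"))
  # Monte-Carlo estimate agrees with the exhaustive p within 3 SE
  n_mc <- 20000
  set.seed(11)
  rx <- rank(lat)
  null <- vapply(seq_len(n_mc), function(i) cor(rx, sample(rank(layers))),
                 numeric(1))
  p_mc <- mean(null >= h$rho - 1e-12)
  se <- sqrt(p_mc * (1 - p_mc) / n_mc)
  expect_lt(abs(p_mc - h$p_value), 3 * se + 1e-6)
  # ties are handled through average ranks
  h_tie <- hierarchy_correlation(c(1, 2, 2, 4), c(1, 2, 3, 4))
  expect_equal(h_tie$rho, cor(c(1, 2, 2, 4), 1:4, method = "spearman"))
})
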