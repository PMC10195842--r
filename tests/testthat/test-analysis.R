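mk_spikes <- function(df, n_trials, n_neurons, duration) {
  attr(df, "n_trials") <- n_trials
  attr(df, "n_neurons") <- n_neurons
  attr(df, "duration") <- duration
  df
}

test_that("compute_psth recovers known rates", {
  # periodic spikes every 100 ms -> 10 Hz everywhere after smoothing
  s <- mk_spikes(data.frame(trial = 1L, neuron = 1L,
                            time_ms = seq(10, 1990, by = 100)),
                 1, 1, 2000)
  p <- compute_psth(s, 1, bin_ms = 20, smooth_ms = 300)
  expect_equal(mean(p), 10, tolerance = 0.05)
  expect_true(all(abs(p - 10) <= 5))
  # smoothing window equal to the bin width is the identity
  p1 <- compute_psth(s, 1, bin_ms = 20, smooth_ms = 20)
  counts <- tabulate(floor(seq(10, 1990, 100) / 20) + 1, 100)
  expect_equal(as.numeric(p1), counts / 0.02)
})

test_that("compute_psth matches the Poisson oracle on many trials", {
  set.seed(2)
  n_trials <- 400
  lam <- 20 * 2  # 20 Hz for 2 s
  sp <- do.call(rbind, lapply(seq_len(n_trials), function(k) {
    n <- rpois(1, lam)
    if (n == 0) return(NULL)
    data.frame(trial = k, neuron = 1L, time_ms = sort(runif(n, 0, 2000)))
  }))
  p <- compute_psth(mk_spikes(sp, n_trials, 1, 2000), 1)
  se <- sqrt(20 / (n_trials * 0.3))  # 300 ms effective window
  expect_true(all(abs(p - 20) < 4 * se + 1))
})

test_that("PCA of PSTHs matches a direct SVD and its invariants", {
  set.seed(3)
  X <- matrix(rnorm(20), 5, 4)
  pc <- pca_psth(X)
  cen <- sweep(X, 2, colMeans(X))
  sv <- svd(cen)
  expect_equal(abs(pc$components), abs(sv$u), tolerance = 1e-10)
  expect_equal(pc$sing_values, sv$d, tolerance = 1e-10)
  expect_equal(sum(pc$var_frac), 1)
  expect_equal(crossprod(pc$components), diag(ncol(pc$components)),
               tolerance = 1e-10)
  # rank-1 input: a single component captures everything
  ramp <- outer(1:30, c(1, 2, 3, 4))
  pr <- pca_psth(ramp)
  expect_equal(pr$var_frac[1], 1, tolerance = 1e-12)
})

test_that("random-phase sine PSTHs yield the two Fourier components", {
  set.seed(4)
  t <- seq_len(100)
  phases <- runif(30, 0, 2 * pi)
  X <- sapply(phases, function(ph) 5 + 2 * sin(2 * pi * 2 * t / 100 + ph))
  pc <- pca_psth(X)
  expect_gt(sum(pc$var_frac[1:2]), 0.99)
})

test_that("transferred activity behaves under own and reference components", {
  set.seed(5)
  ramp <- outer(seq_len(50) / 50, rnorm(40, 1, 0.3)) + 1
  noise <- matrix(rnorm(50 * 40), 50, 40)
  expect_gt(transferred_activity(ramp + 0.01 * noise, k = 2), 0.95)
  # white-noise PSTHs against an arbitrary orthonormal reference: k/T
  Q <- qr.Q(qr(matrix(rnorm(50 * 6), 50, 6)))
  fr <- transferred_activity(noise, k = 6, reference_pcs = Q)
  expect_lt(abs(fr - 6 / 50), 0.05)
  expect_error(transferred_activity(ramp, k = 45), "rank")
})

test_that("pc_fidelity is one for identical activity and sign-invariant", {
  set.seed(6)
  X <- matrix(rnorm(200), 20, 10)
  pa <- pca_psth(X)
  pb <- pca_psth(X)
  expect_equal(pc_fidelity(pa, pb, k = 3), rep(1, 3), tolerance = 1e-10)
  pb$components <- -pb$components
  expect_equal(pc_fidelity(pa, pb, k = 3), rep(1, 3), tolerance = 1e-10)
})

test_that("shared variance against a duplicate population and a null", {
  set.seed(7)
  t <- seq_len(60)
  F <- sapply(1:12, function(i) sin(t / 8 + i) + 0.1 * rnorm(60))
  sv <- shared_variance(F, F)
  expect_equal(sum(sv$frac_alpha), 1)
  expect_equal(sum(sv$frac_beta), 1)
  expect_gt(abs(cor(sv$alpha[, 1], sv$beta[, 1])), 0.999)
  # independent white noise: leading shared fraction below permutation null
  set.seed(8)
  Fw <- matrix(rnorm(100 * 50), 100, 50)
  Gw <- matrix(rnorm(100 * 50), 100, 50)
  obs <- shared_variance(Fw, Gw)$d[1]
  null <- replicate(30, shared_variance(Fw[sample(100), ], Gw)$d[1])
  expect_lt(obs, quantile(null, 0.95) * 1.2)
})

test_that("zero-variance neurons are zeroed and logged in shared variance", {
  set.seed(9)
  F <- matrix(rnorm(40), 20, 2)
  F[, 2] <- 3
  G <- matrix(rnorm(60), 20, 3)
  sv <- shared_variance(F, G)
  expect_equal(sv$zero_variance$F, 2L)
  expect_true(all(sv$C[2, ] == 0))
})

test_that("choice selectivity hand cases", {
  t <- 100
  rL <- matrix(4, t, 3)
  rR <- 2 * rL
  cs <- choice_selectivity(rR, rL)
  expect_equal(unname(cs$index), rep(2 / 3, 3), tolerance = 1e-12)
  # identical conditions: zero; swapping negates
  expect_equal(choice_selectivity(rL, rL)$index, rep(0, 3))
  expect_equal(choice_selectivity(rL, rR)$index, -cs$index)
})

test_that("the choice mode has the stated normalization and hand value", {
  t <- seq(0.5, 999.5)
  mkr <- function(vals) lapply(1:4, function(k)
    matrix(vals, length(t), 2, byrow = TRUE) + rnorm(2 * length(t), 0, .01))
  set.seed(10)
  rr <- mkr(c(10, 2))
  rl <- mkr(c(4, 8))
  cm <- choice_mode(rr, rl, t - 1000, window = c(-1000, 0), min_neurons = 2)
  expect_equal(sqrt(sum(cm$C^2)), 1 / sqrt(2), tolerance = 1e-6)
  d <- c(6, -6) / sqrt(72) / sqrt(2)
  expect_equal(cm$C, d, tolerance = 0.02)
  pr <- project_modes(matrix(c(10, 2), 5, 2, byrow = TRUE), cm$C)
  expect_equal(pr$P_H, rep(6, 5))
  # uniform population: homogeneous projection equals the common rate
  expect_equal(project_modes(matrix(10, 3, 2), cm$C)$P_H, rep(10, 3))
})

test_that("identical R/L averages make the choice mode undefined", {
  t <- seq(0.5, 499.5)
  r <- lapply(1:3, function(k) matrix(5, length(t), 12))
  expect_error(choice_mode(r, r, t - 500, window = c(-500, 0)), "identical")
})
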