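test_that("solve_balance reproduces the hand linear-algebra solution", {
  Jbar <- matrix(c(0.3, 2.0, 1.5, 2.0), 2, 2)
  # hand 2x2 solve of 0.3 rE - 1.5 rI + 0.12 = 0; 2 rE - 2 rI + 0.08 = 0:
  # rI = rE + 0.04  =>  -1.2 rE + 0.06 = 0  =>  rE = 0.05, rI = 0.09
  sol <- solve_balance(Jbar, c(0.12, 0.08))
  expect_equal(unname(sol$rates), c(0.05, 0.09), tolerance = 1e-12)
  expect_lt(sol$residual, 1e-12)
  expect_true(sol$physical)
  # zero drive gives zero rates; doubling X doubles rates (homogeneity)
  expect_equal(unname(solve_balance(Jbar, c(0, 0))$rates), c(0, 0))
  sol2 <- solve_balance(Jbar, 2 * c(0.12, 0.08))
  expect_equal(sol2$rates, 2 * sol$rates)
  # simultaneous rescaling of J and X leaves the solution unchanged
  sol3 <- solve_balance(3 * Jbar, 3 * c(0.12, 0.08))
  expect_equal(sol3$rates, sol$rates)
})

test_that("non-physical solutions are flagged", {
  Jbar <- matrix(c(2.0, 0.3, 0.5, 2.0), 2, 2)
  sol <- solve_balance(Jbar, c(0.5, -0.9))
  expect_false(sol$physical)
})

test_that("quenched disorder matches hand arithmetic and scalings", {
  expect_equal(quenched_disorder(c(0, 0, 0), 2), 0)
  # 3-neuron toy in trace units (rate_unit 5 ms): rates 4, 8, 12 Hz
  r <- c(4, 8, 12)
  hand <- 2^2 * mean((r * 5 / 1000)^2)
  expect_equal(quenched_disorder(r, 2), hand)
  expect_equal(quenched_disorder(r, 4), 4 * quenched_disorder(r, 2))
})

test_that("predicted loading variances follow the trained spectrum", {
  set.seed(4)
  t <- seq_len(100)
  M <- 80
  ramp <- (t - mean(t)) / sqrt(sum((t - mean(t))^2))
  osc <- sin(t / 8) - mean(sin(t / 8))
  osc <- osc / sqrt(sum(osc^2))
  load1 <- rnorm(M, 0, 3)
  load2 <- rnorm(M, 0, 1)
  X <- 10 + 1000 / 5 * (outer(ramp, load1) + outer(osc, load2))
  pred <- predict_loading_distribution(X, Jbar = 2, k = 3)
  expect_equal(pred$modes$pred_var[1] / pred$modes$pred_var[2],
               var(load1) / var(load2), tolerance = 0.4)
  # zero modes predict zero variance
  expect_lt(pred$modes$lambda[3] / pred$modes$lambda[1], 1e-3)
})

test_that("selectivity spread prediction on a hand-built toy", {
  t <- seq_len(50)
  M <- 40
  set.seed(5)
  ramp <- (t - mean(t))
  ramp <- ramp / sqrt(sum(ramp^2))
  aR <- rnorm(M, 0, 2)
  baseR <- rnorm(M, 10, 2)
  R <- outer(rep(1, 50), baseR) + outer(ramp, aR) * 200
  L <- outer(rep(1, 50), baseR) + outer(ramp, rnorm(M, 0, 2)) * 200
  same <- selectivity_spread_prediction(R, R, Jbar = 2)
  expect_equal(same$A, 0, tolerance = 1e-10)
  expect_equal(same$B, 0, tolerance = 1e-6)
  dif <- selectivity_spread_prediction(R, L, Jbar = 2)
  expect_gt(dif$B, 0)
})

test_that("the weak-coupling control rescales weights and keeps adjacency", {
  strong <- tiny_net(N = 100, p = 0.3, seed = 6)
  weak <- weak_coupling_network(strong, sigma_ref = 0.4)
  expect_equal(weak$X_bal[1], 1.5 * 0.35 + 0)
  expect_equal(weak$X_bal[100], 0.8 * 0.35)
  # same support, values scaled by 1/sqrt(K) per presynaptic block
  expect_equal(which(as.matrix(weak$static$J) != 0),
               which(as.matrix(strong$static$J) != 0))
  K <- strong$syn$K
  i <- which(as.matrix(strong$static$J)[, 1] != 0)[1]
  ratio <- strong$static$J[i, 1] / weak$static$J[i, 1]
  expect_equal(unname(ratio), sqrt(K["E", "E"]))
  expect_gt(weak$noise_amp, 0)
})

test_that("the weak control without noise spikes near-deterministically", {
  strong <- tiny_net(N = 100, p = 0.3, seed = 6)
  weak <- weak_coupling_network(strong, noise_amp = 0,
                                X_gauss = rep(0.9, 100))
  drv <- make_drives(weak, T_target = 2000, stim_ms = 0, L_X = 0, seed = 7)
  sim <- simulate_network(weak, NULL, drv, n_trials = 2, seed = 8)
  st <- spike_stats(target_window_spikes(sim))
  expect_lt(st$cv, 0.3)
})
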