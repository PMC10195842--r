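test_that("a subthreshold network without weights emits no spikes", {
  params <- network_params(20, p = 0.3, X_scale = 0.02)  # X well below v_thr
  net <- balanced_network(params, seed = 1)
  net$static$J <- net$static$J * 0
  drv <- make_drives(net, T_target = 500, stim_ms = 0, L_X = 0, seed = 2)
  sim <- simulate_network(net, NULL, drv, n_trials = 1, seed = 3)
  expect_equal(nrow(target_window_spikes(sim)), 0)
})

test_that("an isolated neuron follows the closed-form LIF period", {
  params <- network_params(4, p = 0.5, X_scale = 0.02)
  net <- balanced_network(params, seed = 1)
  net$static$J <- net$static$J * 0
  X <- 1.5
  net$X_bal <- rep(X, 4)
  drv <- make_drives(net, T_target = 2000, stim_ms = 0, L_X = 0, seed = 2,
                     ign_amp = 0)
  sim <- simulate_network(net, NULL, drv, n_trials = 1, seed = 3)
  sp <- target_window_spikes(sim)
  isi <- diff(sp$time_ms[sp$neuron == 1])
  expected <- 10 * log((X - 0) / (X - 1))
  expect_true(all(abs(isi - expected) <= 0.2 + 1e-9))
})

test_that("the engine matches an independent per-step scalar oracle", {
  params <- network_params(4, p = 0.5, X_scale = 0.02, frac_exc = 0.75)
  net <- balanced_network(params, seed = 1)
  J <- matrix(0, 4, 4)
  J[2, 1] <- 0.4; J[3, 1] <- 0.3; J[1, 2] <- 0.2; J[3, 2] <- 0.5
  net$static$J <- methods::as(Matrix::Matrix(J, sparse = TRUE), "CsparseMatrix")
  net$X_bal <- c(1.4, 1.2, 0.9, 0.2)
  drv <- make_drives(net, T_target = 30, stim_ms = 0, burn_ms = 0, L_X = 0,
                     seed = 2, ign_amp = 0)
  seed <- 11
  sim <- simulate_network(net, NULL, drv, n_trials = 1, seed = seed)
  set.seed(seed + 1)
  v0 <- runif(4)
  orc <- lif_oracle(J, net$X_bal, v0, n_steps = 300, charge = net$charge)
  want <- do.call(rbind, lapply(seq_len(300), function(t)
    if (length(orc$spikes[[t]]))
      data.frame(n = orc$spikes[[t]], t = (t - 1) * 0.1) else NULL))
  expect_gt(nrow(want), 3)
  expect_equal(nrow(sim$spikes), nrow(want))
  ord <- order(want$t, want$n)
  expect_equal(sim$spikes$neuron, want$n[ord])
  expect_equal(sim$spikes$time_ms, want$t[ord], tolerance = 1e-12)
})

test_that("recorded input traces satisfy the additivity invariant", {
  net <- tiny_net(N = 120, p = 0.3, seed = 5)
  pl <- build_plastic_connectivity(net, 1:60, L_rec = 8, L_X = 5, seed = 6)
  drv <- make_drives(net, T_target = 400, L_X = 5, seed = 7)
  sim <- simulate_network(net, pl, drv, n_trials = 1, seed = 8,
                          record_neurons = c(3, 50, 80),
                          trace_trials = 1, record_groups = TRUE)
  tr <- sim$traces[["1"]]
  tot <- tr[, , "u_balE"] + tr[, , "u_balI"]
  # the trained-group split never exceeds its population component
  expect_true(all(tr[, , "u_from_trainedE"] >= -1e-12))
  expect_true(all(tr[, , "u_from_trainedE"] <= tr[, , "u_balE"] + 1e-9))
  expect_true(all(tr[, , "u_from_trainedI"] >= tr[, , "u_balI"] - 1e-9))
  expect_true(all(is.finite(tot)))
})

test_that("simulations are reproducible under a fixed seed", {
  net <- tiny_net(N = 80, seed = 2)
  drv <- make_drives(net, T_target = 300, L_X = 0, seed = 3)
  s1 <- simulate_network(net, NULL, drv, n_trials = 2, seed = 4)
  s2 <- simulate_network(net, NULL, drv, n_trials = 2, seed = 4)
  expect_identical(s1$spikes, s2$spikes)
  s3 <- simulate_network(net, NULL, drv, n_trials = 2, seed = 5)
  expect_false(identical(s1$spikes, s3$spikes))
})
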