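test_that("zero training iterations leave the network unchanged", {
  net <- tiny_net(N = 100, p = 0.3, seed = 1)
  pl <- build_plastic_connectivity(net, 1:50, L_rec = 8, L_X = 0, seed = 2)
  base <- suppressWarnings(untrained_baseline(net, 3000, seed = 3))
  tg <- make_sine_targets(1:50, base$baselines[1:50], seed = 4)
  drv <- make_drives(net, T_target = 2000, L_X = 0, seed = 5)
  tr <- train_subset(net, pl, tg, drv, training_config(n_iter = 0))
  expect_identical(tr$plastic$w, pl$w)
})

test_that("training touches only trained rows and conserves ROWSUMs", {
  net <- tiny_net(N = 200, p = 0.3, seed = 6)
  trained <- seq(1, 100)  # E subnetwork
  pl <- build_plastic_connectivity(net, trained, L_rec = 12, L_X = 0,
                                   seed = 7)
  base <- suppressWarnings(untrained_baseline(net, 3000, seed = 8))
  tg <- make_sine_targets(trained, base$baselines[trained], freq_hz = 2,
                          seed = 9)
  drv <- make_drives(net, T_target = 1000, L_X = 0, seed = 10)
  cfg <- training_config(n_iter = 8, T_target = 1000, seed = 11)
  tr <- suppressWarnings(train_subset(net, pl, tg, drv, cfg))
  # untrained neurons still have no plastic synapses (support contract)
  expect_true(all(tr$plastic$post_of %in% trained))
  expect_false(identical(tr$plastic$w, pl$w))
  # ROWSUM regularization suppresses drift of the aggregate E and I row
  # sums: a strong penalty pins them almost exactly, and the standard
  # penalty drifts less than unregularized training
  rs0 <- plastic_rowsums(pl)
  rs1 <- plastic_rowsums(tr$plastic)
  cfg0 <- training_config(n_iter = 8, T_target = 1000, mu = 0, seed = 11)
  rs_free <- plastic_rowsums(
    suppressWarnings(train_subset(net, pl, tg, drv, cfg0))$plastic)
  cfg_hi <- training_config(n_iter = 8, T_target = 1000, mu = 1e6, seed = 11)
  rs_hi <- plastic_rowsums(
    suppressWarnings(train_subset(net, pl, tg, drv, cfg_hi))$plastic)
  drift_mu <- mean(abs(rs1 - rs0))
  drift_free <- mean(abs(rs_free - rs0))
  drift_hi <- mean(abs(rs_hi - rs0))
  expect_lt(drift_hi, 0.05 * drift_free)
  expect_lt(drift_mu, drift_free)
})

test_that("training is reproducible under a fixed seed", {
  net <- tiny_net(N = 100, p = 0.3, seed = 1)
  pl <- build_plastic_connectivity(net, 1:50, L_rec = 8, L_X = 0, seed = 2)
  base <- suppressWarnings(untrained_baseline(net, 3000, seed = 3))
  tg <- make_sine_targets(1:50, base$baselines[1:50], seed = 4)
  drv <- make_drives(net, T_target = 500, L_X = 0, seed = 5)
  cfg <- training_config(n_iter = 3, T_target = 500, seed = 21)
  t1 <- suppressWarnings(train_subset(net, pl, tg, drv, cfg))
  t2 <- suppressWarnings(train_subset(net, pl, tg, drv, cfg))
  expect_identical(t1$plastic$w, t2$plastic$w)
  expect_identical(t1$diagnostics, t2$diagnostics)
})
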