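mk_spikes2 <- function(df, n_trials, n_neurons, duration) {
  attr(df, "n_trials") <- n_trials
  attr(df, "n_neurons") <- n_neurons
  attr(df, "duration") <- duration
  df
}

test_that("Poisson trains give unit Fano and CV; periodic trains give zero", {
  set.seed(1)
  sp <- do.call(rbind, lapply(1:60, function(k) {
    do.call(rbind, lapply(1:20, function(i) {
      n <- rpois(1, 30)
      if (n == 0) return(NULL)
      data.frame(trial = k, neuron = i, time_ms = sort(runif(n, 0, 3000)))
    }))
  }))
  st <- spike_stats(mk_spikes2(sp, 60, 20, 3000))
  expect_equal(st$fano, 1, tolerance = 0.15)
  expect_equal(st$cv, 1, tolerance = 0.1)

  per <- do.call(rbind, lapply(1:10, function(k)
    data.frame(trial = k, neuron = 1L, time_ms = seq(50, 2950, by = 100))))
  stp <- spike_stats(mk_spikes2(per, 10, 1, 3000))
  expect_equal(stp$fano, 0)
  expect_equal(stp$cv, 0, tolerance = 1e-12)
})

test_that("doubly stochastic Poisson matches the closed-form Fano excess", {
  set.seed(2)
  Tw <- 2      # seconds
  lam_mean <- 20
  lam_sd <- 6
  n_trials <- 2000
  counts <- rpois(n_trials, pmax(rnorm(n_trials, lam_mean, lam_sd), 0) * Tw)
  fano_closed <- 1 + lam_sd^2 * Tw / lam_mean
  expect_equal(var(counts) / mean(counts), fano_closed, tolerance = 0.12)
  # same construction through spike_stats
  sp <- do.call(rbind, lapply(seq_len(400), function(k) {
    n <- rpois(1, max(rnorm(1, lam_mean, lam_sd), 0) * Tw)
    if (n == 0) return(NULL)
    data.frame(trial = k, neuron = 1L, time_ms = sort(runif(n, 0, 2000)))
  }))
  st <- spike_stats(mk_spikes2(sp, 400, 1, 2000))
  expect_equal(st$fano, fano_closed, tolerance = 0.35 * fano_closed)
})

test_that("gaussian_loading_test calibrates and has power", {
  set.seed(3)
  rej <- mean(replicate(40, gaussian_loading_test(rnorm(300))$p_value < 0.01))
  expect_lt(rej, 0.12)
  rej_u <- mean(replicate(20,
    gaussian_loading_test(runif(500))$p_value < 0.01))
  expect_gt(rej_u, 0.9)
  out <- gaussian_loading_test(rep(1, 60))
  expect_true(out$degenerate)
  expect_error(gaussian_loading_test(rnorm(10)), "50")
})

test_that("input decomposition groups add up and expose modulations", {
  net <- tiny_net(N = 150, p = 0.3, seed = 6)
  pl <- build_plastic_connectivity(net, 1:75, L_rec = 8, L_X = 0, seed = 7)
  drv <- make_drives(net, T_target = 600, L_X = 0, seed = 8)
  sim <- simulate_network(net, pl, drv, n_trials = 1, seed = 9,
                          record_neurons = c(80, 100, 120),
                          trace_trials = 1, record_groups = TRUE)
  dec <- input_decomposition(sim$traces[["1"]],
                             X_bal = net$X_bal[c(80, 100, 120)])
  expect_equal(dec$from_trainedE + dec$from_untrainedE,
               t(sim$traces[["1"]][, , "u_balE"]), tolerance = 1e-12)
  expect_equal(unname(colMeans(dec$delta_trainedE)), rep(0, 3),
               tolerance = 1e-10)
  expect_s3_class(dec$pca, "ss_pca")
  expect_error(input_decomposition(sim$traces[["1"]][, , 1:3, drop = FALSE]),
               "record_groups")
})
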