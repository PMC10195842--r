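test_that("static weights follow the J/sqrt(K) table with Dale's law", {
  net <- tiny_net(N = 80, p = 0.5, seed = 2)
  J <- net$static$J
  K <- net$syn$K
  NE <- net$layout$N_E
  # excitatory columns positive, inhibitory negative, one value per block
  JEE <- J[1:NE, 1:NE]@x
  JIE <- J[(NE + 1):80, 1:NE]@x
  JEI <- J[1:NE, (NE + 1):80]@x
  expect_true(all(JEE > 0) && all(JEI < 0))
  expect_equal(unique(JEE), 0.15 * 2 / sqrt(K["E", "E"]))
  expect_equal(unique(JIE), 2 / sqrt(K["I", "E"]))
  expect_equal(unique(JEI), -0.75 * 2 / sqrt(K["E", "I"]))
  expect_true(all(Matrix::diag(J) == 0))
})

test_that("p = 1 gives the full bipartite block minus the diagonal", {
  layout <- population_layout(20)
  syn <- synapse_params(Jbar = matrix(1, 2, 2),
                        K = matrix(10, 2, 2))
  st <- build_static_connectivity(layout, syn, seed = 1)
  A <- st$J != 0
  expect_equal(sum(A), 20 * 20 - 20)
  expect_true(all(Matrix::diag(A) == 0))
})

test_that("realized in-degrees match the binomial sampling oracle", {
  layout <- population_layout(40)
  syn <- synapse_params(Jbar = matrix(1, 2, 2), K = matrix(8, 2, 2))
  n_seeds <- 400
  deg <- numeric(0)
  for (s in seq_len(n_seeds)) {
    st <- build_static_connectivity(layout, syn, seed = s)
    deg <- c(deg, Matrix::rowSums(st$J != 0))
  }
  # per-row in-degree ~ Binom(19, 0.4) + Binom(20, 0.4), mean 15.6
  se <- sd(deg) / sqrt(length(deg))
  expect_lt(abs(mean(deg) - 39 * 0.4), 3 * se)
})

test_that("in-degree larger than the presynaptic pool is rejected", {
  layout <- population_layout(20)
  syn <- synapse_params(Jbar = matrix(1, 2, 2), K = matrix(15, 2, 2))
  expect_error(build_static_connectivity(layout, syn),
               "exceeds")
})

test_that("plastic support is disjoint, feasible and follows the pool rule", {
  net <- tiny_net(N = 100, p = 0.3, seed = 4)
  trained <- 1:40  # E subnetwork (first half is E)
  pl <- build_plastic_connectivity(net, trained, L_rec = 10, L_X = 3,
                                   seed = 9)
  expect_silent(assert_disjoint_support(net, pl))
  # E partners come from other trained E neurons, I partners from any I
  rec <- pl$kind != 2L
  preE <- pl$pre_id[pl$kind == 0L]
  preI <- pl$pre_id[pl$kind == 1L]
  expect_true(all(preE %in% trained))
  expect_true(all(preI > net$layout$N_E))
  # no self-connections; fixed counts per neuron
  expect_true(all(pl$post_of[rec] != pl$pre_id[rec]))
  expect_equal(unname(diff(pl$w_off)), rep(13L, 40))
  # untrained neurons receive no plastic synapses
  expect_false(any(!(pl$post_of %in% trained)))
})

test_that("infeasible plastic in-degree raises an error naming the neuron", {
  net <- tiny_net(N = 40, p = 0.4, seed = 4)
  expect_error(build_plastic_connectivity(net, c(1, 2, 21), L_rec = 10),
               "neuron")
})

test_that("initial plastic signs follow presynaptic type and charge parity", {
  net <- tiny_net(N = 100, p = 0.3, seed = 4)
  pl <- build_plastic_connectivity(net, 1:50, L_rec = 8, L_X = 2, seed = 1,
                                   init_scales = list(E = 2, I = 1))
  chg <- net$neuron$tau_m / net$syn$tau_plas
  J_E <- 2 / sqrt(net$syn$K["E", "E"])
  expect_equal(unique(pl$w[pl$kind == 0L]), 2 * J_E * chg)
  expect_true(all(pl$w[pl$kind == 1L] < 0))
  expect_equal(unique(pl$w[pl$kind == 2L]), 2 * J_E * chg)
})
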