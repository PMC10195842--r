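# Independent quadrature oracle for the transfer function: the raw
# integrand written without the erfcx reformulation, integrated with
# Gauss-Kronrod quadrature.
phi_oracle <- function(m, sigma, tau_m = 10, v_thr = 1, v_reset = 0) {
  g <- function(w) exp(w^2) * (1 + pracma::erf(w))
  val <- pracma::quadgk(g, (v_reset - m) / sigma, (v_thr - m) / sigma,
                        tol = 1e-12)
  1000 / (tau_m * sqrt(pi) * val)
}

test_that("the transfer function is monotone and vanishes subthreshold", {
  grid <- seq(-2, 3, by = 0.1)
  r <- ricciardi_rate(grid, sigma = 0.4)
  expect_true(all(diff(r) > 0))
  expect_lt(ricciardi_rate(-5, 0.3), 1e-6)
  expect_equal(ricciardi_rate(-30, 0.3), 0)
})

test_that("the small-noise limit matches the deterministic LIF rate", {
  m <- 1.4
  det_rate <- 1000 / (10 * log((m - 0) / (m - 1)))
  expect_equal(ricciardi_rate(m, 1e-4), det_rate, tolerance = 1e-3)
})

test_that("ricciardi_rate agrees with an independent quadrature oracle", {
  for (case in list(c(0.9, 0.3), c(0.5, 0.5), c(1.2, 0.25), c(-0.5, 0.6))) {
    expect_equal(ricciardi_rate(case[1], case[2]),
                 phi_oracle(case[1], case[2]),
                 tolerance = 1e-8)
  }
})

test_that("inversion is the two-sided inverse on the bracket", {
  for (r in c(0.5, 4.2, 11, 40)) {
    m <- invert_transfer(r, sigma = 0.4)
    expect_equal(ricciardi_rate(m, 0.4), r, tolerance = 1e-6)
  }
  ms <- invert_transfer(c(1, 2, 5, 10, 20), sigma = 0.3)
  expect_true(all(diff(ms) > 0))
  expect_error(invert_transfer(0, 0.4), "bracket")
  expect_error(invert_transfer(-1, 0.4), "bracket")
})

test_that("the fast batch inverter matches the accurate inversion", {
  inv <- spikespread:::transfer_inverse_fun(0.35)
  rates <- c(0.2, 1, 4.2, 11, 60, 200)
  expect_equal(inv(rates), invert_transfer(rates, 0.35), tolerance = 1e-5)
})

test_that("estimate_sigma rejects short recordings and scales with coupling", {
  net <- balanced_network(network_params(1000, 0.2), seed = 3)
  expect_error(estimate_sigma(net, duration_ms = 1000), "short")
  s1 <- estimate_sigma(net, duration_ms = 5000, seed = 5)
  # scaling J and X together preserves the balanced rates but grows the
  # synaptic fluctuations with the weight scale
  net2 <- net
  net2$static$J <- net$static$J * 1.25
  net2$X_bal <- net$X_bal * 1.25
  s2 <- estimate_sigma(net2, duration_ms = 5000, seed = 5)
  expect_gt(s2$sigma_I, s1$sigma_I)
  # zero-weight network: only the constant drive remains
  net0 <- net
  net0$static$J <- net$static$J * 0
  s0 <- estimate_sigma(net0, duration_ms = 5000, seed = 5)
  expect_lt(s0$sigma_E, 1e-8)
})
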