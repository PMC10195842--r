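test_that("sine targets have the stated form and Fourier structure", {
  b <- c(0.4, 0.6, 0.5, 0.7, 0.45, 0.55, 0.5, 0.6, 0.42, 0.58)
  tg <- make_sine_targets(1:10, b, amp = 0.5, freq_hz = 2, T_target = 2000,
                          seed = 3)
  f <- tg$f[[1]]
  expect_equal(rowMeans(f), b, tolerance = 1e-10)
  expect_equal(apply(f, 1, max) - b, rep(0.5, 10), tolerance = 1e-3)
  # centered targets live in the 2-dimensional sine/cosine subspace
  cen <- sweep(f, 1, rowMeans(f))
  sv <- svd(cen)
  expect_gt(sum(sv$d[1:2]^2) / sum(sv$d^2), 0.999)
  # zero amplitude: constant baselines
  tg0 <- make_sine_targets(1:10, b, amp = 0, seed = 3)
  expect_true(all(abs(tg0$f[[1]] - b) < 1e-12))
})

test_that("PSTH-to-target conversion inverts the transfer function", {
  times <- seq(20, 2000, by = 20)
  rates <- outer(times, c(2, 5, 12), function(t, r0) r0 + 3 * t / 2000)
  tg <- psth_to_targets(rates, sigma = 0.4, neurons = 1:3, times = times)
  f <- tg$f[[1]]
  back <- ricciardi_rate(f[2, ], 0.4)
  expect_equal(back, rates[, 2], tolerance = 1e-4)
  # monotone-ramp PSTH gives a monotone target
  expect_true(all(diff(f[1, ]) > 0))
  # constant PSTH gives a constant target equal to a single inversion
  rc <- matrix(6, 10, 1)
  tgc <- psth_to_targets(rc, sigma = 0.4, neurons = 1,
                         times = seq(20, 200, 20))
  expect_equal(max(abs(tgc$f[[1]] - invert_transfer(6, 0.4))), 0,
               tolerance = 1e-5)
})

test_that("the synthetic generator reproduces its specified statistics", {
  spec <- synthetic_psth_spec()
  sy <- make_synthetic_psths(spec, M = 2000, seed = 11)
  # rate distribution matches the specified log-normal (two-sample KS)
  meanlog <- log(4.2) - 0.5
  ref <- rlnorm(2000, meanlog, 1)
  ks <- suppressWarnings(ks.test(sy$rates[, "R"], ref))
  expect_gt(ks$p.value, 0.01)
  # the D basis modes capture at least 95% of the centered variance
  R <- sy$R
  cen <- sweep(R, 2, colMeans(R))
  proj <- crossprod(sy$basis, cen)
  expect_gt(sum(proj^2) / sum(cen^2), 0.95)
  # the ramp dominates and loadings grow with rate
  pc <- pca_psth(R)
  expect_gt(pc$var_frac[1], 0.25)
  mod <- sqrt(colSums(cen^2))
  expect_gt(cor(mod, sy$rates[, "R"]), 0.5)
})

test_that("zero modulation gives flat PSTHs; selectivity is symmetric", {
  sy0 <- make_synthetic_psths(synthetic_psth_spec(multiplier = 0), 50,
                              seed = 2)
  expect_true(all(abs(apply(sy0$R, 2, sd)) < 1e-9))
  sy <- make_synthetic_psths(synthetic_psth_spec(), 800, seed = 5)
  cs <- choice_selectivity(sy$R, sy$L)
  idx <- cs$index[is.finite(cs$index)]
  # flooring at zero biases the lick-left member slightly; the index stays
  # centered well within a third of its spread
  expect_lt(abs(mean(idx)) / sd(idx), 0.35)
})

test_that("the inhibitory spec carries stronger modulation", {
  syE <- make_synthetic_psths(synthetic_psth_spec(), 500, seed = 9)
  syI <- make_synthetic_psths(synthetic_psth_spec_I(), 500, seed = 9)
  relmod <- function(sy) {
    cen <- sweep(sy$R, 2, colMeans(sy$R))
    mean(apply(cen, 2, sd) / colMeans(sy$R))
  }
  expect_gt(relmod(syI), relmod(syE))
})

test_that("rate matching is a greedy unique assignment", {
  # identical rate multisets match exactly
  m <- match_neurons_by_rate(c(3, 1, 7, 5), c(5, 1, 7, 3))
  expect_equal(m$score, 0)
  expect_equal(sort(m$model_idx), 1:4)
  # explicit greedy enumeration oracle on a 5x5 case
  set.seed(8)
  mr <- runif(5, 0, 20)
  tr <- runif(5, 0, 20)
  greedy <- integer(5)
  avail <- rep(TRUE, 5)
  for (k in order(tr, decreasing = TRUE)) {
    cand <- which(avail)
    pick <- cand[which.min(abs(mr[cand] - tr[k]))]
    greedy[k] <- pick
    avail[pick] <- FALSE
  }
  m2 <- match_neurons_by_rate(mr, tr)
  expect_equal(m2$model_idx, greedy)
  # disjoint supports still give a bijection
  m3 <- match_neurons_by_rate(c(0.1, 0.2, 0.3), c(100, 200, 300))
  expect_equal(sort(m3$model_idx), 1:3)
  expect_gt(m3$score, 0)
  expect_error(match_neurons_by_rate(1:2, 1:3), "pool")
})
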