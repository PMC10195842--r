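# Direct regularized batch solver: the independent oracle for the online
# recursion (ridge + ROWSUM solved by dense linear algebra).
batch_rls <- function(r_seq, f, u_bal, X_bal, lambda, mu, ind_E, ind_I) {
  L <- ncol(r_seq)
  A <- crossprod(r_seq) + lambda * diag(L)
  for (ind in list(ind_E, ind_I)) {
    if (length(ind)) {
      e <- numeric(L); e[ind] <- 1
      A <- A + mu * tcrossprod(e)
    }
  }
  drop(solve(A, crossprod(r_seq, f - u_bal - X_bal)))
}

test_that("init_P equals the dense inverse and is positive definite", {
  P <- init_P(0.05, 8, 1:2, 3:4, 6)
  A <- 0.05 * diag(6)
  for (ind in list(1:2, 3:4)) {
    e <- numeric(6); e[ind] <- 1
    A <- A + 8 * tcrossprod(e)
  }
  expect_equal(P, solve(A), tolerance = 1e-12)
  expect_equal(P, t(P))
  expect_gt(min(eigen(P, symmetric = TRUE)$values), 0)
  expect_equal(init_P(0.5, 0, 1:2, 3:4, 5), diag(5) / 0.5)
})

test_that("online RLS reproduces the batch regularized minimizer", {
  for (case in 1:6) {
    set.seed(100 + case)
    L <- sample(4:10, 1)
    n <- sample(20:50, 1)
    nE <- sample(1:(L - 2), 1)
    ind_E <- seq_len(nE)
    ind_I <- nE + seq_len(sample(1:(L - nE - 1), 1))
    r_seq <- matrix(rnorm(n * L, 1, 0.5), n, L)
    f <- rnorm(n)
    ub <- rnorm(n, 0, 0.3)
    Xb <- runif(1)
    lambda <- runif(1, 0.01, 1)
    mu <- runif(1, 0, 10)
    st <- list(w = numeric(L), P = init_P(lambda, mu, ind_E, ind_I, L))
    for (t in seq_len(n)) st <- rls_step(st, r_seq[t, ], f[t], ub[t], Xb)
    wb <- batch_rls(r_seq, f, ub, Xb, lambda, mu, ind_E, ind_I)
    expect_equal(st$w, wb, tolerance = 1e-8)
  }
})

test_that("a zero-error step leaves the weights unchanged but updates P", {
  set.seed(3)
  L <- 5
  st <- list(w = rnorm(L), P = init_P(0.1, 2, 1:2, 3:4, L))
  r <- rnorm(L, 1)
  f <- sum(st$w * r) + 0.7 + 0.3   # e = 0 given u_bal = 0.7, X_bal = 0.3
  P_old <- st$P
  st2 <- rls_step(st, r, f, 0.7, 0.3)
  expect_equal(st2$w, st$w)
  expect_false(identical(st2$P, P_old))
  expect_equal(st2$e, 0)
})

test_that("interleaved neuron states evolve independently", {
  set.seed(4)
  L <- 4
  RA <- matrix(rnorm(20 * L), 20, L)
  RB <- matrix(rnorm(20 * L), 20, L)
  mk <- function() list(w = numeric(L), P = init_P(0.05, 8, 1:2, 3:4, L))
  a <- mk(); b <- mk(); a_ref <- mk()
  for (t in 1:20) {
    a <- rls_step(a, RA[t, ], sin(t / 3), 0, 0)
    b <- rls_step(b, RB[t, ], cos(t / 3), 0, 0)
  }
  for (t in 1:20) a_ref <- rls_step(a_ref, RA[t, ], sin(t / 3), 0, 0)
  expect_equal(a$w, a_ref$w)
  expect_equal(a$P, a_ref$P)
})

test_that("cost_eval is zero at a perfect fit and minimal at the batch optimum", {
  set.seed(5)
  L <- 6
  n <- 30
  ind_E <- 1:2; ind_I <- 3:4
  r_seq <- matrix(rnorm(n * L), n, L)
  ub <- rnorm(n); Xb <- 0.2
  f <- ub + Xb
  expect_equal(cost_eval(numeric(L), r_seq, f, ub, Xb, 1, 1, ind_E, ind_I), 0)

  f2 <- rnorm(n)
  wb <- batch_rls(r_seq, f2, ub, Xb, 0.3, 2, ind_E, ind_I)
  c0 <- cost_eval(wb, r_seq, f2, ub, Xb, 0.3, 2, ind_E, ind_I)
  for (k in 1:100) {
    wr <- wb + rnorm(L, 0, 0.3)
    expect_gte(cost_eval(wr, r_seq, f2, ub, Xb, 0.3, 2, ind_E, ind_I), c0)
  }
})

test_that("the large-mu limit pins the aggregate row sums", {
  set.seed(6)
  L <- 6; n <- 40
  ind_E <- 1:3; ind_I <- 4:6
  r_seq <- matrix(rnorm(n * L, 1), n, L)
  f <- rnorm(n, 2)
  w_hi <- batch_rls(r_seq, f, 0, 0, 0.05, 1e8, ind_E, ind_I)
  expect_lt(abs(sum(w_hi[ind_E])), 1e-4)
  expect_lt(abs(sum(w_hi[ind_I])), 1e-4)
})
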