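#' Training configuration
#'
#' @param lambda ridge (L2) penalty; also sets the effective learning rate
#' @param mu ROWSUM penalty keeping the aggregate excitatory and inhibitory
#'   plastic weights of each trained neuron near their initial values
#' @param n_iter number of training iterations
#' @param T_target target duration (ms)
#' @param learn_every update cadence (ms); must be a multiple of `dt`
#' @param err_avg_ms exponential averaging window (ms) of the error
#'   signal: the static input and presynaptic traces entering the update
#'   can be low-pass filtered over this window. The default (one time
#'   step) is the instantaneous error; filtering trades fast noise against
#'   lag-induced bias
#' @param clamp_pretarget also run updates during burn-in and stimulus with
#'   the neuron's baseline input as the target, keeping the plant
#'   controlled between target windows
#' @param reset_P restart the inverse-correlation matrix at each iteration
#'   (keeps the effective learning rate high across iterations); with
#'   `FALSE` the matrix carries over and the updates anneal
#' @param seed integer seed
#' @return an object of class `ss_train_config`
#' @export
training_config <- function(lambda = 0.05, mu = 8.0, n_iter = 200,
                            T_target = 2000, learn_every = 10,
                            err_avg_ms = 0.1, clamp_pretarget = TRUE,
                            reset_P = FALSE, seed = 1) {
  stopifnot(lambda > 0, mu >= 0, n_iter >= 0, learn_every > 0,
            err_avg_ms > 0)
  structure(list(lambda = lambda, mu = mu, n_iter = n_iter,
                 T_target = T_target, learn_every = learn_every,
                 err_avg_ms = err_avg_ms, clamp_pretarget = clamp_pretarget,
                 reset_P = reset_P, seed = seed),
            class = "ss_train_config")
}

#' Initial inverse-correlation matrix
#'
#' Closed-form `P0 = (lambda I + mu sum_a 1_a 1_a')^{-1}` computed with the
#' Woodbury identity (the indicator vectors of the two populations are
#' orthogonal, so the correction is a pair of rank-1 terms), never by dense
#' inversion.
#'
#' @param lambda ridge penalty (> 0)
#' @param mu ROWSUM penalty (>= 0)
#' @param ind_E,ind_I indices (within the weight vector) of the recurrent
#'   excitatory / inhibitory entries; feedforward entries belong to neither
#' @param L_tot total weight-vector length
#' @return `L_tot x L_tot` symmetric positive-definite matrix
#' @export
init_P <- function(lambda, mu, ind_E, ind_I, L_tot) {
  stopifnot(lambda > 0, mu >= 0, !anyDuplicated(c(ind_E, ind_I)))
  P <- diag(L_tot) / lambda
  for (ind in list(ind_E, ind_I)) {
    La <- length(ind)
    if (mu > 0 && La > 0) {
      e <- numeric(L_tot); e[ind] <- 1
      P <- P - (mu / (lambda * (lambda + mu * La))) * tcrossprod(e)
    }
  }
  P
}

#' One recursive-least-squares step for a trained neuron
#'
#' Error `e = f - u_bal - X_bal - w . r`; weight update
#' `w <- w + e P_new r` with the rank-1 Sherman--Morrison update of the
#' inverse-correlation matrix; `P` is re-symmetrized after the update.
#'
#' @param state list with elements `w` (weight vector) and `P`
#' @param r filtered presynaptic activity vector
#' @param f target value (total-input units)
#' @param u_bal instantaneous static synaptic input of the neuron
#' @param X_bal constant external input of the neuron
#' @return the updated state, with the realized error in `$e`
#' @export
rls_step <- function(state, r, f, u_bal, X_bal) {
  stopifnot(length(r) == length(state$w), all(is.finite(r)))
  e <- f - u_bal - X_bal - sum(state$w * r)
  Pr <- drop(state$P %*% r)
  den <- 1 + sum(r * Pr)
  if (den <= 0 || !is.finite(den))
    stop("inverse-correlation matrix lost positive definiteness")
  state$P <- state$P - tcrossprod(Pr) / den
  state$P <- (state$P + t(state$P)) / 2
  state$w <- state$w + (e / den) * Pr
  state$e <- e
  state
}

#' Evaluate the per-neuron training cost
#'
#' Squared tracking error accumulated over the discrete grid plus the ridge
#' and ROWSUM regularization terms:
#' `0.5 sum_t (f_t - u_t)^2 + 0.5 [lambda ||w||^2 + mu sum_a (w . 1_a)^2]`
#' with `u_t = u_bal,t + X_bal + w . r_t`.
#'
#' @param w weight vector
#' @param r_seq matrix of filtered presynaptic vectors (time rows x weights)
#' @param f target values per row
#' @param u_bal static input per row
#' @param X_bal constant external input
#' @param lambda,mu regularization penalties
#' @param ind_E,ind_I recurrent-entry indices per population
#' @return scalar cost
#' @export
cost_eval <- function(w, r_seq, f, u_bal, X_bal, lambda, mu, ind_E, ind_I) {
  stopifnot(ncol(r_seq) == length(w), length(f) == nrow(r_seq))
  err <- f - u_bal - X_bal - drop(r_seq %*% w)
  reg <- lambda * sum(w^2) +
    mu * (sum(w[ind_E])^2 + sum(w[ind_I])^2)
  0.5 * sum(err^2) + 0.5 * reg
}
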