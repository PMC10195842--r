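#' Solve the balanced equations
#'
#' The large-K population rates of the strongly coupled network satisfy the
#' linear system
#' `Jbar_EE r_E - Jbar_EI r_I + Xbar_E = 0`,
#' `Jbar_IE r_E - Jbar_II r_I + Xbar_I = 0`,
#' involving only the unscaled static weight magnitudes and external
#' drives. Rates come out in trace units (spikes per effective charge time
#' `rate_unit_ms = charge * tau_m`); the Hz conversion is also returned.
#' Negative solutions are flagged as non-physical ("no balanced solution").
#'
#' @param Jbar 2x2 matrix of unscaled weight magnitudes (all positive;
#'   inhibitory sign applied internally)
#' @param Xbar length-2 vector of scaled external drives `(Xbar_E, Xbar_I)`
#' @param rate_unit_ms effective per-spike charge time constant converting
#'   trace-unit rates to Hz (`charge * tau_m`, 5 ms at the defaults)
#' @return list with `rates` (trace units), `rates_hz`, `residual`, and
#'   `physical`
#' @export
solve_balance <- function(Jbar, Xbar, rate_unit_ms = 5) {
  stopifnot(all(dim(Jbar) == 2), length(Xbar) == 2)
  A <- matrix(c(Jbar[1, 1], Jbar[2, 1], -Jbar[1, 2], -Jbar[2, 2]), 2, 2)
  if (abs(det(A)) < 1e-14) stop("balanced system is singular")
  r <- solve(A, -as.numeric(Xbar))
  res <- A %*% r + as.numeric(Xbar)
  list(rates = c(E = r[1], I = r[2]),
       rates_hz = 1000 * c(E = r[1], I = r[2]) / rate_unit_ms,
       residual = max(abs(res)),
       physical = all(r >= 0))
}

#' Quenched disorder of the aggregate trained input
#'
#' Across-neuron variance of the time-mean input that an untrained neuron
#' receives from the trained population through frozen random connectivity:
#' `q = Jbar^2 * mean_j(<rate_j>^2)` with time-mean rates in trace units.
#'
#' @param mean_rates_hz time-mean rates of the trained neurons (Hz)
#' @param Jbar unscaled weight magnitude of the trained-to-untrained block
#' @param rate_unit_ms effective charge time constant (Hz-to-trace factor)
#' @return scalar `q`
#' @export
quenched_disorder <- function(mean_rates_hz, Jbar, rate_unit_ms = 5) {
  stopifnot(all(is.finite(mean_rates_hz)))
  Jbar^2 * mean((mean_rates_hz * rate_unit_ms / 1000)^2)
}

#' Predicted loading distribution of inputs to untrained neurons
#'
#' Singular value decomposition of the centered trained activity
#' `delta phi = U sqrt(lambda) V` (with `lambda_n = s_n^2 / M` so the left
#' singular vectors have unit-variance entries); by the central limit
#' theorem the loading of an untrained neuron's trained-population input on
#' mode `n` is Gaussian with mean zero and variance `Jbar^2 lambda_n`. When
#' measured loadings are supplied the report includes their z-scored
#' variance ratios and normality tests.
#'
#' @param trained_psth time x trained-neurons rate matrix (Hz)
#' @param Jbar unscaled weight magnitude of the trained-to-untrained block
#' @param measured_loadings optional matrix (untrained neurons x modes) of
#'   loadings of the measured aggregate input on the trained right singular
#'   vectors (input units)
#' @param k number of modes reported
#' @param rate_unit_ms effective charge time constant (Hz-to-trace factor)
#' @return list with `modes` data.frame (`lambda`, `pred_var`, and when
#'   measured: `meas_var`, `ratio`, normality p-value) and the trained
#'   right singular vectors `V` (time x modes)
#' @export
predict_loading_distribution <- function(trained_psth, Jbar,
                                         measured_loadings = NULL, k = 6,
                                         rate_unit_ms = 5) {
  R <- sweep(unclass(trained_psth), 2, colMeans(trained_psth)) *
    rate_unit_ms / 1000
  M <- ncol(R)
  sv <- svd(R)
  k <- min(k, length(sv$d))
  lambda <- sv$d[seq_len(k)]^2 / M
  pred <- Jbar^2 * lambda
  out <- data.frame(mode = seq_len(k), lambda = lambda, pred_var = pred)
  if (!is.null(measured_loadings)) {
    stopifnot(ncol(measured_loadings) >= k)
    mv <- apply(measured_loadings[, seq_len(k), drop = FALSE], 2, var)
    out$meas_var <- mv
    out$ratio <- mv / pred
    out$normal_p <- apply(measured_loadings[, seq_len(k), drop = FALSE], 2,
                          function(x) {
                            if (length(x) >= 50 && sd(x) > 0)
                              gaussian_loading_test(x)$p_value
                            else NA_real_
                          })
  }
  list(modes = out, V = sv$u[, seq_len(k), drop = FALSE])
}

#' Measure loadings of untrained-neuron inputs on trained modes
#'
#' Projects the temporal modulation of each untrained neuron's aggregate
#' trained-population input onto the trained right singular vectors.
#'
#' @param delta_u time x untrained-neurons matrix of input modulations
#' @param V time x modes matrix of trained temporal modes (unit norm)
#' @return untrained neurons x modes loading matrix
#' @export
input_mode_loadings <- function(delta_u, V) {
  stopifnot(nrow(delta_u) == nrow(V))
  t(crossprod(V, unclass(delta_u)))
}

#' Predicted spread of choice selectivity
#'
#' With ramp-dominated trained activity, the difference between the
#' lick-right and lick-left inputs to an untrained neuron is
#' `SI_i(t) ~ A dz_i + B da_i t`: `A^2` is the variance of the quenched
#' (baseline) difference and `B^2` the variance of the mode-1 modulation
#' difference, `B^2 = Jbar^2 (lambda_1^R + lambda_1^L - 2 rho
#' sqrt(lambda_1^R lambda_1^L))` with `rho` the correlation between the
#' mode-1 neuron loadings of the two trial types.
#'
#' @param psth_R,psth_L time x trained-neurons rate matrices (Hz)
#' @param Jbar unscaled weight magnitude of the trained-to-untrained block
#' @param rate_unit_ms effective charge time constant (Hz-to-trace factor)
#' @return list with `A`, `B`, and the per-type mode-1 spectra
#' @export
selectivity_spread_prediction <- function(psth_R, psth_L, Jbar,
                                          rate_unit_ms = 5) {
  uf <- rate_unit_ms / 1000
  dR <- (colMeans(psth_R) - colMeans(psth_L)) * uf
  A2 <- Jbar^2 * mean(dR^2)
  cR <- sweep(unclass(psth_R), 2, colMeans(psth_R)) * uf
  cL <- sweep(unclass(psth_L), 2, colMeans(psth_L)) * uf
  M <- ncol(cR)
  svR <- svd(cR); svL <- svd(cL)
  l1R <- svR$d[1]^2 / M
  l1L <- svL$d[1]^2 / M
  rho <- abs(cor(svR$v[, 1], svL$v[, 1]))
  B2 <- Jbar^2 * (l1R + l1L - 2 * rho * sqrt(l1R * l1L))
  list(A = sqrt(A2), B = sqrt(B2), lambda1 = c(R = l1R, L = l1L), rho = rho)
}

#' Weak-coupling control network
#'
#' Same adjacency as the matched strong network but with the static weights
#' rescaled from `Jbar/sqrt(K)` to `Jbar/K` (synapses average presynaptic
#' activity), per-neuron constant Gaussian inputs copied from the mean
#' inputs of the untrained strong network, uniform weak external drives
#' `X_E = 1.5 X_weak`, `X_I = 0.8 X_weak`, and injected external white
#' noise standing in for the fluctuating balanced input. The default noise
#' amplitude is calibrated in closed form so the membrane-potential
#' variance matches that produced by the strong network's measured input
#' fluctuation size at the static synaptic time constant.
#'
#' @param strong an `ss_network` with `sqrtK` scaling
#' @param X_weak uniform external-input scale
#' @param factors per-population multipliers of `X_weak` (E, I)
#' @param noise_amp white-noise amplitude (input units * sqrt(ms));
#'   `NULL` for the calibrated default
#' @param sigma_ref measured input fluctuation size of the strong network
#'   (from [estimate_sigma()]); required when `noise_amp` is `NULL`
#' @param X_gauss per-neuron constant inputs (mean total inputs of the
#'   untrained strong network)
#' @return an `ss_network` with weak weights, modified drives and
#'   `noise_amp` set
#' @export
weak_coupling_network <- function(strong, X_weak = 0.35,
                                  factors = c(E = 1.5, I = 0.8),
                                  noise_amp = NULL, sigma_ref = NULL,
                                  X_gauss = NULL) {
  weak <- strong
  # rescale each presynaptic column by 1/sqrt(K) of its block
  J <- strong$static$J
  K <- strong$syn$K
  colfac <- ifelse(strong$layout$is_exc, 1 / sqrt(K["E", "E"]),
                   1 / sqrt(K["E", "I"]))
  weak$static$J <- J %*% Matrix::Diagonal(x = colfac)
  weak$static$scaling <- "K"
  if (is.null(X_gauss)) X_gauss <- numeric(strong$layout$N)
  weak$X_bal <- ifelse(strong$layout$is_exc, factors[["E"]], factors[["I"]]) *
    X_weak + X_gauss
  if (is.null(noise_amp)) {
    if (is.null(sigma_ref))
      stop("supply sigma_ref (strong-network input SD) or noise_amp")
    noise_amp <- sigma_ref * sqrt(2 * strong$syn$tau_bal)
  }
  weak$noise_amp <- noise_amp
  weak
}
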