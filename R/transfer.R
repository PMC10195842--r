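#' Ricciardi transfer function of the leaky integrate-and-fire neuron
#'
#' Mean firing rate of an LIF neuron driven by white noise with mean input
#' `m` and fluctuation size `sigma`:
#' `phi(m, sigma) = 1 / (tau_m sqrt(pi) I)` with
#' `I = int_{(v_reset-m)/sigma}^{(v_thr-m)/sigma} e^{w^2} erfc(-w) dw`.
#' The integrand is evaluated through the scaled complementary error
#' function (`erfcx`) so it never overflows for the rates of interest, and
#' the integral uses adaptive quadrature. Strictly increasing in `m`;
#' returns 0 in the deep-subthreshold limit.
#'
#' @param m mean input (vectorized)
#' @param sigma input fluctuation SD (> 0)
#' @param neuron a [neuron_params()]
#' @return firing rate in Hz
#' @export
ricciardi_rate <- function(m, sigma, neuron = neuron_params()) {
  stopifnot(sigma > 0)
  vapply(m, function(mm) {
    a <- (neuron$v_reset - mm) / sigma
    b <- (neuron$v_thr - mm) / sigma
    if (b > 10) return(0)  # deep subthreshold: rate below ~1e-40 Hz
    val <- integrate(ricciardi_integrand, a, b, rel.tol = 1e-11,
                     abs.tol = 0)$value
    1000 / (neuron$tau_m * sqrt(pi) * val)
  }, numeric(1))
}

# e^{w^2} erfc(-w), stable via erfcx: for w <= 0 it equals erfcx(-w); for
# w > 0, erfc(-w) = 2 - erfc(w) gives 2 e^{w^2} - erfcx(w). The erfcx
# implementation is replaced by its asymptotic series beyond |w| = 25
# (where the library version loses validity).
ricciardi_integrand <- function(w) {
  out <- numeric(length(w))
  neg <- w <= 0
  out[neg] <- erfcx_safe(-w[neg])
  if (any(!neg))
    out[!neg] <- 2 * exp(pmin(w[!neg]^2, 700)) - erfcx_safe(w[!neg])
  out
}

erfcx_safe <- function(x) {
  out <- numeric(length(x))
  big <- x > 25
  if (any(!big)) out[!big] <- pracma::erfcx(x[!big])
  if (any(big)) {
    xb <- x[big]
    out[big] <- (1 - 0.5 / xb^2 + 0.75 / xb^4) / (xb * sqrt(pi))
  }
  out
}

#' Invert the transfer function
#'
#' Finds the mean input `m` with `phi(m, sigma) = rate` by bracketed root
#' finding, exploiting strict monotonicity.
#'
#' @param rate target rate(s) in Hz (must be strictly positive and below
#'   the rate achievable at the upper bracket)
#' @param sigma input fluctuation SD
#' @param neuron a [neuron_params()]
#' @param bracket search interval for `m`
#' @return mean input(s) `m`
#' @export
invert_transfer <- function(rate, sigma, neuron = neuron_params(),
                            bracket = c(-10, 20)) {
  hi <- ricciardi_rate(bracket[2], sigma, neuron)
  lo <- ricciardi_rate(bracket[1], sigma, neuron)
  vapply(rate, function(r) {
    if (!is.finite(r) || r <= 0 || r <= lo || r >= hi)
      stop("rate ", r, " Hz outside the achievable bracket (",
           signif(lo, 3), ", ", signif(hi, 3), ")")
    uniroot(function(m) ricciardi_rate(m, sigma, neuron) - r,
            interval = bracket, tol = 1e-12)$root
  }, numeric(1))
}

# Fast monotone inverse interpolator for batch PSTH conversion: dense grid
# of accurate transfer evaluations, then a monotone (Hyman-filtered) spline
# of m against log-rate.
transfer_inverse_fun <- function(sigma, neuron = neuron_params(),
                                 rate_range = c(0.02, 500), n_grid = 400) {
  m_lo <- invert_transfer(rate_range[1], sigma, neuron)
  m_hi <- invert_transfer(rate_range[2], sigma, neuron)
  mg <- seq(m_lo, m_hi, length.out = n_grid)
  rg <- ricciardi_rate(mg, sigma, neuron)
  keep <- rg > 0 & c(TRUE, diff(rg) > 0)
  sp <- splinefun(log(rg[keep]), mg[keep], method = "hyman")
  function(rate) sp(log(rate))
}

#' Estimate the synaptic fluctuation size from an untrained simulation
#'
#' Per neuron, the standard deviation over time of the fast (static)
#' synaptic input `u_bal` after burn-in; the population value is the mean
#' over neurons. This is the `sigma` entering the transfer function when
#' PSTHs are converted to input targets.
#'
#' @param network an `ss_network`
#' @param duration_ms recording length after burn-in (>= 5000)
#' @param seed integer seed
#' @return list with `sigma_E`, `sigma_I`, the per-neuron values, and the
#'   per-neuron mean inputs from the same run
#' @export
estimate_sigma <- function(network, duration_ms = 5000, seed = 1) {
  if (duration_ms < 5000)
    stop("recording too short for a stable sigma estimate (need >= 5 s)")
  drives <- make_drives(network, n_types = 1, T_target = duration_ms,
                        stim_ms = 0, burn_ms = 500, L_X = 0, seed = seed)
  sim <- simulate_network(network, NULL, drives, n_trials = 1, seed = seed,
                          record_spikes = FALSE)
  sdv <- sim$mean_inputs[, "u_bal_sd"]
  is_exc <- network$layout$is_exc
  list(sigma_E = mean(sdv[is_exc]), sigma_I = mean(sdv[!is_exc]),
       sigma_neuron = sdv, mean_inputs = sim$mean_inputs)
}

#' Mean-field estimate of the input fluctuation size
#'
#' Self-consistency expression `sigma_a^2 = Jbar_aE^2 phi_E +
#' Jbar_aI^2 phi_I` with population rates in trace units
#' (`Hz * rate_unit_ms / 1000`).
#'
#' @param syn a [synapse_params()]
#' @param rate_E,rate_I population mean rates in Hz
#' @param rate_unit_ms effective charge time constant
#' @return named vector with `sigma_E` and `sigma_I`
#' @export
meanfield_sigma <- function(syn, rate_E, rate_I, rate_unit_ms = 5) {
  rE <- rate_E * rate_unit_ms / 1000
  rI <- rate_I * rate_unit_ms / 1000
  c(sigma_E = sqrt(syn$Jbar["E", "E"]^2 * rE + syn$Jbar["E", "I"]^2 * rI),
    sigma_I = sqrt(syn$Jbar["I", "E"]^2 * rE + syn$Jbar["I", "I"]^2 * rI))
}

#' Self-consistent effective noise for the transfer function
#'
#' The raw standard deviation of the filtered static input underestimates
#' the diffusion-level noise that the Ricciardi formula expects (colored
#' noise, reset statistics). This calibration finds the sigma at which the
#' inverse transfer of the neurons' measured rates reproduces their
#' measured mean inputs on average, making PSTH-derived targets sit at the
#' network's true operating point.
#'
#' @param rates_hz measured per-neuron rates (Hz)
#' @param baselines measured per-neuron mean total inputs
#' @param neuron a [neuron_params()]
#' @param bracket search interval for sigma
#' @param rate_range rates kept for the fit (active, non-saturated cells)
#' @return calibrated sigma
#' @export
effective_sigma <- function(rates_hz, baselines, neuron = neuron_params(),
                            bracket = c(0.08, 2), rate_range = c(0.5, 60)) {
  keep <- rates_hz >= rate_range[1] & rates_hz <= rate_range[2]
  if (sum(keep) < 5)
    stop("too few active neurons for the sigma calibration")
  r <- rates_hz[keep]
  b <- baselines[keep]
  resid <- function(sg) mean(invert_transfer(r, sg, neuron) - b)
  lo <- resid(bracket[1])
  hi <- resid(bracket[2])
  if (lo * hi > 0) return(if (abs(lo) < abs(hi)) bracket[1] else bracket[2])
  uniroot(resid, bracket, tol = 1e-4)$root
}
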