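#' Ornstein--Uhlenbeck stimulus traces
#'
#' Mean-reverting OU process `X(t+dt) = X - X dt/tau + sigma sqrt(dt) xi`
#' sampled independently per neuron, used as the brief external stimulus
#' that triggers the learned response. The trace is nonzero only inside its
#' window; each trial type has its own frozen stimulus set that is reused
#' across trials of that type.
#'
#' @param n number of neurons (rows)
#' @param window_ms stimulus window length (ms)
#' @param dt time step (ms)
#' @param tau OU time constant (ms)
#' @param sigma OU noise amplitude
#' @param seed optional integer seed
#' @return `n x (window_ms/dt)` matrix
#' @export
ou_stimulus <- function(n, window_ms = 200, dt = 0.1, tau = 20, sigma = 0.2,
                        seed = NULL) {
  stopifnot(window_ms >= 0, dt > 0, tau > 0, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  steps <- round(window_ms / dt)
  if (steps == 0) return(matrix(0, n, 0))
  X <- matrix(0, n, steps)
  x <- numeric(n)
  a <- dt / tau
  b <- sigma * sqrt(dt)
  for (t in seq_len(steps)) {
    x <- x - a * x + b * rnorm(n)
    X[, t] <- x
  }
  X
}

#' Rate patterns of the external Poisson units
#'
#' Pre-determined time-varying rates: an OU process around a 5 Hz mean,
#' floored at zero, sampled at 1 ms resolution and frozen across trials.
#' Rates are returned in spikes per ms (internal units).
#'
#' @param L_X number of external units
#' @param dur_ms trial duration (ms)
#' @param mean_hz mean rate (Hz)
#' @param tau OU time constant (ms)
#' @param sd_hz stationary rate standard deviation (Hz)
#' @param seed optional seed
#' @return `L_X x dur_ms` matrix of rates (spikes/ms)
#' @export
external_rate_traces <- function(L_X, dur_ms, mean_hz = 5, tau = 50,
                                 sd_hz = 2, seed = NULL) {
  if (L_X == 0) return(matrix(0, 0, 0))
  if (!is.null(seed)) set.seed(seed)
  sigma <- sd_hz * sqrt(2 / tau)
  x <- matrix(0, L_X, dur_ms)
  cur <- rnorm(L_X, 0, sd_hz)
  for (t in seq_len(dur_ms)) {
    cur <- cur - cur / tau + sigma * rnorm(L_X)
    x[, t] <- pmax(mean_hz + cur, 0)
  }
  x / 1000
}

#' Inhomogeneous Poisson spike trains with synaptic filtering
#'
#' Bernoulli-per-step approximation of Poisson spiking at the given
#' time-varying rates, filtered with the plastic synaptic time constant
#' under the plastic-trace jump convention (each spike adds 1 to the
#' trace, which then decays with `tau_plas`), so the time-average of a
#' filtered train equals its rate in spikes per ms multiplied by
#' `tau_plas`.
#'
#' @param rate_traces `n x dur_ms` matrix of rates (spikes/ms)
#' @param dur_ms duration (ms)
#' @param dt time step (ms)
#' @param tau_plas filter time constant (ms)
#' @param seed optional seed
#' @return list with `spikes` (data.frame `unit`, `time_ms`) and `filtered`
#'   (`n x dur_ms/dt` matrix of filtered traces)
#' @export
poisson_external <- function(rate_traces, dur_ms, dt = 0.1, tau_plas = 150,
                             seed = NULL) {
  stopifnot(all(rate_traces >= 0))
  if (max(rate_traces) * dt > 1)
    stop("rate * dt exceeds 1: time step too coarse for Bernoulli sampling")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(rate_traces)
  steps <- round(dur_ms / dt)
  filt <- matrix(0, n, steps)
  cur <- numeric(n)
  dec <- 1 - dt / tau_plas
  un <- integer(0); tm <- numeric(0)
  for (t in seq_len(steps)) {
    ms <- min(ceiling(t * dt), ncol(rate_traces))
    p <- rate_traces[, ms] * dt
    sp <- which(runif(n) < p)
    cur <- cur * dec
    if (length(sp)) {
      cur[sp] <- cur[sp] + 1
      un <- c(un, sp); tm <- c(tm, rep((t - 1) * dt, length(sp)))
    }
    filt[, t] <- cur
  }
  list(spikes = data.frame(unit = un, time_ms = tm), filtered = filt)
}

#' Assemble the external drives of a trial
#'
#' Combines the frozen OU stimulus sets (one per trial type) and the frozen
#' rate patterns of the external Poisson units.
#'
#' @param network an `ss_network`
#' @param n_types number of trial types (1 or 2; lick-right, lick-left)
#' @param T_target target window (ms)
#' @param stim_ms stimulus window (ms)
#' @param burn_ms burn-in before the stimulus (ms)
#' @param L_X number of external units (match the plastic connectivity)
#' @param seed integer seed
#' @param stim_tau,stim_sigma OU stimulus parameters
#' @param ign_amp,ign_tau decaying ignition input applied at the start of
#'   the burn-in (amplitude in input units, time constant in ms). Finite
#'   networks whose external drive alone is subthreshold have a stable
#'   silent state; the brief kick moves them onto the active balanced
#'   state, and it has decayed to nothing well before the burn-in ends.
#' @return object of class `ss_drives`
#' @export
make_drives <- function(network, n_types = 1, T_target = 2000, stim_ms = 200,
                        burn_ms = 500, L_X = 0, seed = 1,
                        stim_tau = 20, stim_sigma = 0.2,
                        ign_amp = 1, ign_tau = 30) {
  dt <- network$neuron$dt
  N <- network$layout$N
  X_stim <- lapply(seq_len(n_types), function(ty)
    ou_stimulus(N, stim_ms, dt, stim_tau, stim_sigma,
                seed = seed + 1000L * ty))
  dur <- burn_ms + stim_ms + T_target
  ext_rate <- external_rate_traces(L_X, dur, seed = seed + 777L)
  structure(list(X_stim = X_stim, ext_rate = ext_rate, burn_ms = burn_ms,
                 stim_ms = stim_ms, T_target = T_target, n_types = n_types,
                 L_X = L_X, seed = seed, ign_amp = ign_amp,
                 ign_tau = ign_tau),
            class = "ss_drives")
}
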