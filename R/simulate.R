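# Assemble the 0-based plain-vector representation consumed by the C++ core.
cpp_net <- function(network, plastic) {
  if (is.null(plastic)) plastic <- empty_plastic(network$layout$N)
  J <- network$static$J
  list(N = network$layout$N,
       is_exc = network$layout$is_exc,
       dt = network$neuron$dt, tau_m = network$neuron$tau_m,
       v_thr = network$neuron$v_thr, v_reset = network$neuron$v_reset,
       tau_bal = network$syn$tau_bal, tau_plas = network$syn$tau_plas,
       noise_amp = network$noise_amp,
       charge = if (is.null(network$charge)) 0.45 else network$charge,
       Jp = J@p, Ji = J@i, Jx = J@x,
       X_bal = network$X_bal,
       trained = plastic$trained - 1L,
       w_off = as.integer(plastic$w_off),
       Lrec = as.integer(plastic$Lrec),
       w = plastic$w,
       pre_id = plastic$pre_id - 1L,
       kind = as.integer(plastic$kind),
       post_of = plastic$post_of - 1L,
       rp = as.integer(plastic$rev$rp), rflat = as.integer(plastic$rev$rflat),
       xp = as.integer(plastic$rev$xp), xflat = as.integer(plastic$rev$xflat),
       LX = as.integer(plastic$LX))
}

trace_channels <- c("u_balE", "u_balI", "u_plas", "X_plas", "X_stim",
                    "u_from_trainedE", "u_from_trainedI")

#' Simulate leaky integrate-and-fire trials
#'
#' Forward-Euler integration of the network at `dt`, with static, plastic
#' and external inputs. Each trial consists of a burn-in, an optional
#' stimulus window and the target window; membrane potentials start uniform
#' on `[v_reset, v_thr)` and trial `k` uses the sub-seed `seed + k`, so
#' trials are independent and reproducible. Spike times are reported in ms
#' from trial start; the target window starts at
#' `burn_ms + stim_ms`.
#'
#' @param network an `ss_network`
#' @param plastic an `ss_plastic` (or `NULL` for the untrained network)
#' @param drives an `ss_drives`
#' @param n_trials number of trials
#' @param trial_types integer vector (values in `1:n_types`) assigning a
#'   stimulus set to each trial; defaults to alternating types
#' @param seed integer base seed
#' @param record_neurons neuron ids whose input traces are recorded
#' @param trace_trials trial indices for which traces are kept
#' @param record_groups also record the static input arriving from trained
#'   presynaptic neurons, split by population
#' @param rec_every_ms trace sampling interval (ms)
#' @param record_spikes keep the spike raster
#' @return an object of class `ss_sim`: `spikes` (data.frame `trial`,
#'   `neuron`, `time_ms` ordered by trial, time, neuron), `mean_inputs`
#'   (N x 6 matrix: mean u_balE, u_balI, u_plas, X_plas, u_bal and the
#'   within-trial SD of u_bal, averaged over trials), `traces` (list of
#'   arrays neuron x time x channel), and the window layout
#' @export
simulate_network <- function(network, plastic = NULL, drives, n_trials = 1,
                             trial_types = NULL, seed = 1,
                             record_neurons = NULL, trace_trials = integer(),
                             record_groups = FALSE, rec_every_ms = 1,
                             record_spikes = TRUE) {
  dt <- network$neuron$dt
  net <- cpp_net(network, plastic)
  n_burn <- round(drives$burn_ms / dt)
  n_stim <- round(drives$stim_ms / dt)
  n_targ <- round(drives$T_target / dt)
  if (is.null(trial_types))
    trial_types <- rep_len(seq_len(drives$n_types), n_trials)
  stopifnot(length(trial_types) == n_trials,
            all(trial_types %in% seq_len(drives$n_types)))
  rec_neur <- if (is.null(record_neurons)) integer(0) else
    as.integer(record_neurons)
  sp <- vector("list", n_trials)
  traces <- list()
  msum <- matrix(0, network$layout$N, 6)
  for (k in seq_len(n_trials)) {
    set.seed(seed + k)
    want_tr <- k %in% trace_trials && length(rec_neur) > 0
    run <- list(n_burn = n_burn, n_stim = n_stim, n_targ = n_targ,
                ign_amp = drives$ign_amp, ign_tau = drives$ign_tau,
                Xstim = drives$X_stim[[trial_types[k]]],
                ext_rate = drives$ext_rate,
                rec_traces = want_tr,
                rec_neurons = rec_neur - 1L,
                rec_every = as.integer(round(rec_every_ms / dt)),
                rec_groups = record_groups,
                rec_spikes = record_spikes)
    out <- sim_trial_cpp(net, run)
    if (record_spikes && length(out$neuron))
      sp[[k]] <- data.frame(trial = k, neuron = out$neuron + 1L,
                            time_ms = out$time_ms)
    msum <- msum + out$mean_inputs
    if (want_tr) {
      tr <- out$traces
      dimnames(tr) <- list(neuron = rec_neur, NULL, channel = trace_channels)
      traces[[as.character(k)]] <- tr
    }
  }
  sp <- Filter(Negate(is.null), sp)
  spikes <- if (record_spikes && length(sp)) do.call(rbind, sp) else
    data.frame(trial = integer(0), neuron = integer(0), time_ms = numeric(0))
  spikes <- spikes[order(spikes$trial, spikes$time_ms, spikes$neuron), ,
                   drop = FALSE]
  rownames(spikes) <- NULL
  mi <- msum / n_trials
  colnames(mi) <- c("u_balE", "u_balI", "u_plas", "X_plas", "u_bal_mean",
                    "u_bal_sd")
  structure(list(spikes = spikes, mean_inputs = mi, traces = traces,
                 n_trials = n_trials, trial_types = trial_types,
                 N = network$layout$N,
                 burn_ms = drives$burn_ms, stim_ms = drives$stim_ms,
                 T_target = drives$T_target,
                 t_target0 = drives$burn_ms + drives$stim_ms,
                 rec_every_ms = rec_every_ms, seed = seed),
            class = "ss_sim")
}

#' Spikes restricted to the target window
#'
#' @param sim an `ss_sim`
#' @return data.frame with `time_ms` re-referenced to the target-window start
#' @export
target_window_spikes <- function(sim) {
  s <- sim$spikes[sim$spikes$time_ms >= sim$t_target0 &
                    sim$spikes$time_ms < sim$t_target0 + sim$T_target, ,
                  drop = FALSE]
  s$time_ms <- s$time_ms - sim$t_target0
  attr(s, "n_trials") <- sim$n_trials
  attr(s, "n_neurons") <- sim$N
  attr(s, "duration") <- sim$T_target
  attr(s, "trial_types") <- sim$trial_types
  s
}
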