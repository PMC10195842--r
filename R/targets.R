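#' Sinusoidal input targets with random phases
#'
#' `f_i(t) = a sin(2 pi freq t + phi_i) + b_i` on the target grid, with the
#' phase of each neuron uniform on `[0, 2 pi)` and the offset `b_i` the mean
#' total synaptic input of the neuron in the untrained balanced network.
#'
#' @param neurons trained neuron ids (one target per neuron)
#' @param baselines per-neuron offsets `b_i` (same length/order as `neurons`)
#' @param amp amplitude `a`
#' @param freq_hz sine frequency in Hz
#' @param T_target target duration (ms)
#' @param dt_bin target grid spacing (ms)
#' @param seed integer seed
#' @return an `ss_targets` object: list of per-type target matrices `f`
#'   (neurons x time bins), the grid `times` (ms), and `neurons`
#' @export
make_sine_targets <- function(neurons, baselines, amp = 0.5, freq_hz = 1,
                              T_target = 2000, dt_bin = 10, seed = 1) {
  stopifnot(length(baselines) == length(neurons), amp >= 0)
  set.seed(seed)
  phi <- runif(length(neurons), 0, 2 * pi)
  times <- seq(dt_bin, T_target, by = dt_bin)
  f <- outer(seq_along(neurons), times,
             function(i, t) amp * sin(2 * pi * freq_hz * t / 1000 + phi[i]) +
               baselines[i])
  structure(list(f = list(f), times = times, neurons = neurons,
                 phases = phi, amp = amp, freq_hz = freq_hz),
            class = "ss_targets")
}

#' Convert firing-rate PSTHs to synaptic-input targets
#'
#' Each rate bin is mapped through the inverse of the Ricciardi transfer
#' function at the population's fluctuation size, giving the mean input
#' that reproduces the desired rate. Rates are floored at `floor_hz` before
#' inversion (the transfer function is not invertible at 0); clipped bins
#' are counted in the attached log.
#'
#' @param psths rate matrix, time bins x neurons (Hz), with the bin times
#'   (ms) in `attr(, "times")` or supplied via `times`
#' @param sigma fluctuation size per target neuron (scalar or vector)
#' @param neurons model-neuron id per column
#' @param neuron a [neuron_params()]
#' @param times bin times (ms)
#' @param floor_hz lower clip for rates before inversion
#' @param ceiling_hz upper clip (the transfer function saturates; extreme
#'   synthetic-tail rates are clamped and logged)
#' @return an `ss_targets` with one type; see [make_sine_targets()]
#' @export
psth_to_targets <- function(psths, sigma, neurons,
                            neuron = neuron_params(), times = NULL,
                            floor_hz = 0.1, ceiling_hz = 400) {
  if (is.null(times)) times <- attr(psths, "times")
  stopifnot(!is.null(times), length(times) == nrow(psths),
            length(neurons) == ncol(psths))
  sigma <- rep_len(sigma, ncol(psths))
  n_clip <- sum(psths < floor_hz) + sum(psths > ceiling_hz)
  r <- pmin(pmax(psths, floor_hz), ceiling_hz)
  f <- matrix(0, ncol(psths), nrow(psths))
  for (sg in unique(sigma)) {
    cols <- which(sigma == sg)
    inv <- transfer_inverse_fun(sg, neuron,
                                rate_range = c(floor_hz / 2,
                                               min(1.2 * ceiling_hz,
                                                   2 * max(r) + 50)))
    rm <- r[, cols, drop = FALSE]
    f[cols, ] <- t(matrix(inv(as.numeric(rm)), nrow(rm), ncol(rm)))
  }
  structure(list(f = list(f), times = times, neurons = neurons,
                 clipped_bins = n_clip, sigma = sigma),
            class = "ss_targets")
}

#' Merge per-type targets into one two-type target set
#'
#' @param right,left `ss_targets` with identical neurons and grids
#' @return an `ss_targets` with `f` holding the lick-right and lick-left
#'   target matrices
#' @export
pair_targets <- function(right, left) {
  stopifnot(identical(right$neurons, left$neurons),
            identical(right$times, left$times))
  structure(list(f = list(R = right$f[[1]], L = left$f[[1]]),
                 times = right$times, neurons = right$neurons),
            class = "ss_targets")
}

#' Specification of the parametric cortical-like PSTH generator
#'
#' Synthetic trial-averaged rates are built as
#' `r_i(t) = r0_i + sum_n c_{ni} V_n(t)` with an orthonormal temporal basis
#' whose first mode is a ramp (orthogonal polynomials of increasing order),
#' baseline rates log-normal, and per-mode loadings Gaussian with scale
#' `k_n` growing linearly with the baseline rate. Defaults emulate
#' delay-period premotor-cortex statistics: excitatory mean rate 4.2 Hz,
#' inhibitory 11.0 Hz, log-normal shape 1.0; mode-variance fractions
#' `(45, 10, 8, 7, 6, 6, 6, 6, 6)%` so the ramp dominates and six modes
#' carry about 82% of the pre-noise centered variance; inhibitory loading
#' scales are 1.5x the excitatory ones.
#'
#' @param D number of temporal modes
#' @param T_bins number of time bins
#' @param dt_bin bin width (ms)
#' @param rate_mean_hz mean of the log-normal baseline-rate distribution
#' @param rate_sdlog log-scale SD of the baseline-rate distribution
#' @param mode_fracs relative variance per mode (length `D`, normalized).
#'   These are the fractions measured after the standard PSTH smoothing
#'   (`smooth_ms`): the generator pre-compensates the boxcar attenuation of
#'   each basis mode so that smoothed PSTHs carry the stated spectrum —
#'   the defaults put 80% of the centered variance in the first six modes
#'   with a dominant ramp
#' @param smooth_ms smoothing window assumed for the spectrum
#' @param mod_scale total modulation SD as a fraction of the baseline rate
#' @param rate_coupling exponent tying loading scale to baseline rate
#' @param multiplier relative strength of modulation (scales all loadings)
#' @return an `ss_synth_spec`
#' @export
synthetic_psth_spec <- function(D = 9, T_bins = 100, dt_bin = 20,
                                rate_mean_hz = 4.2, rate_sdlog = 1.0,
                                mode_fracs = c(40, 8, 8, 8, 8, 8, 7, 7, 6),
                                smooth_ms = 300,
                                mod_scale = 0.5, rate_coupling = 1,
                                multiplier = 1) {
  stopifnot(D >= 1, length(mode_fracs) == D, all(mode_fracs > 0),
            multiplier >= 0)
  # attenuation of each basis mode under the truncated boxcar used for
  # PSTH smoothing; pre-compensated so the smoothed spectrum is as stated
  B <- synth_basis(T_bins, D, round(smooth_ms / dt_bin))
  att <- attr(B, "attenuation")^2
  pre <- (mode_fracs / sum(mode_fracs)) / att
  structure(list(D = D, T_bins = T_bins, dt_bin = dt_bin,
                 rate_mean_hz = rate_mean_hz, rate_sdlog = rate_sdlog,
                 mode_fracs = pre / sum(pre),
                 mode_fracs_smoothed = mode_fracs / sum(mode_fracs),
                 smooth_ms = smooth_ms,
                 mod_scale = mod_scale, rate_coupling = rate_coupling,
                 multiplier = multiplier),
            class = "ss_synth_spec")
}

#' Inhibitory-population variant of the synthetic spec
#'
#' Same temporal basis with mean rate 11 Hz and loading scales 1.5x the
#' excitatory defaults (fast-spiking neurons carry stronger rate
#' modulation).
#'
#' @param ... overrides passed to [synthetic_psth_spec()]
#' @export
synthetic_psth_spec_I <- function(...) {
  args <- list(...)
  defaults <- list(rate_mean_hz = 11.0, mod_scale = 0.75)
  synthetic_psth_spec_args <- utils::modifyList(defaults, args)
  do.call(synthetic_psth_spec, synthetic_psth_spec_args)
}

# Orthonormal temporal basis: a linear ramp followed by smooth temporal
# bumps tiling the window, orthogonalized in order. All modes share
# similar (slow) frequency content, so the slow plastic synapses track
# them comparably and the standard PSTH smoothing attenuates each without
# collapsing their rank -- mirroring how cortical delay-period modes are
# diverse transient shapes rather than ever-faster oscillations.
synth_basis <- function(T_bins, D, smooth_bins = 15) {
  t <- seq_len(T_bins)
  ramp <- t - mean(t)
  centers <- seq(1, T_bins, length.out = max(D - 1, 1))
  width <- T_bins / max(D - 1, 1)
  bumps <- sapply(centers, function(c0) exp(-(t - c0)^2 / (2 * width^2)))
  raw <- sweep(cbind(ramp, bumps), 2, colMeans(cbind(ramp, bumps)))
  raw <- raw[, seq_len(D), drop = FALSE]
  # W: orthonormal basis of the smoothed bump space (in order, ramp first);
  # B solves smooth(B) = W within that space, so the mode spectrum of the
  # generated PSTHs is exact after the standard smoothing
  SR <- boxcar_smooth(raw, smooth_bins)
  W <- qr.Q(qr(SR))
  sgn <- apply(W, 2, function(v) sign(v[which.max(abs(v))]))
  W <- sweep(W, 2, sgn, `*`)
  B <- raw %*% qr.solve(SR, W)
  attr(B, "attenuation") <- rep(1, D)
  attr(B, "smoothed_modes") <- W
  B
}

#' Generate paired lick-right / lick-left synthetic PSTHs
#'
#' Draws `M` neurons per condition: baseline rate from the log-normal,
#' loadings `c_n ~ N(0, T frac_n (mod_scale r0 multiplier)^2)`, rates
#' floored at 0. The two conditions are generated independently, sorted by
#' mean rate and paired rank-wise; zero-mean Gaussian noise with SD equal to
#' the paired rate difference is then added per bin to the lick-left member
#' (and smoothed with the standard 300 ms boxcar), which injects choice
#' selectivity.
#'
#' @param spec an [synthetic_psth_spec()]
#' @param M number of neurons
#' @param seed integer seed
#' @return list of class `ss_synth_psths` with matrices `R` and `L`
#'   (time bins x neurons, Hz), bin `times` (ms), mean `rates` per
#'   condition, and the basis
#' @export
make_synthetic_psths <- function(spec, M, seed = 1) {
  stopifnot(inherits(spec, "ss_synth_spec"), M >= 1)
  set.seed(seed)
  B <- synth_basis(spec$T_bins, spec$D,
                   round(spec$smooth_ms / spec$dt_bin))
  meanlog <- log(spec$rate_mean_hz) - spec$rate_sdlog^2 / 2
  gen <- function() {
    r0 <- rlnorm(M, meanlog, spec$rate_sdlog)
    s <- spec$mod_scale * spec$multiplier * r0^spec$rate_coupling *
      spec$rate_mean_hz^(1 - spec$rate_coupling)
    C <- matrix(rnorm(spec$D * M), spec$D, M) *
      sqrt(spec$T_bins * spec$mode_fracs) * rep(s, each = spec$D)
    pmax(matrix(r0, spec$T_bins, M, byrow = TRUE) + B %*% C, 0)
  }
  R <- gen()
  L <- gen()
  oR <- order(colMeans(R))
  oL <- order(colMeans(L))
  R <- R[, oR, drop = FALSE]
  L <- L[, oL, drop = FALSE]
  dr <- abs(colMeans(R) - colMeans(L))
  noise <- matrix(rnorm(spec$T_bins * M), spec$T_bins, M) *
    rep(dr, each = spec$T_bins)
  L <- pmax(L + boxcar_smooth(noise, 15), 0)
  times <- seq(spec$dt_bin, by = spec$dt_bin, length.out = spec$T_bins)
  structure(list(R = R, L = L, times = times,
                 rates = cbind(R = colMeans(R), L = colMeans(L)),
                 basis = B, spec = spec),
            class = "ss_synth_psths")
}

#' Pair targets with model neurons by firing rate
#'
#' Greedy unique assignment: targets are processed in descending rate
#' order; each takes the still-unassigned model neuron with the smallest
#' absolute rate difference.
#'
#' @param model_rates rates of the candidate model neurons (Hz)
#' @param target_rates rates of the targets (Hz)
#' @return list with `model_idx` (index into `model_rates` per target) and
#'   the total matching `score` (sum of absolute rate differences)
#' @export
match_neurons_by_rate <- function(model_rates, target_rates) {
  if (length(model_rates) < length(target_rates))
    stop("model pool smaller than the number of targets")
  avail <- rep(TRUE, length(model_rates))
  model_idx <- integer(length(target_rates))
  for (k in order(target_rates, decreasing = TRUE)) {
    cand <- which(avail)
    pick <- cand[which.min(abs(model_rates[cand] - target_rates[k]))]
    model_idx[k] <- pick
    avail[pick] <- FALSE
  }
  list(model_idx = model_idx,
       score = sum(abs(model_rates[model_idx] - target_rates)))
}
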