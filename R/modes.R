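# Per-trial population rates at 1 ms resolution with a 200 ms boxcar, for
# the coding-mode analyses.
#' Single-trial filtered rate matrices
#'
#' Spike trains of one trial binned at `bin_ms` and filtered with a boxcar,
#' in Hz.
#'
#' @param spikes data.frame `trial`, `neuron`, `time_ms`
#' @param trial trial id
#' @param n_neurons number of neurons
#' @param window `c(t0, t1)` ms
#' @param bin_ms bin width (default 1 ms)
#' @param boxcar_ms boxcar filter width (default 200 ms)
#' @return time x neurons matrix
#' @export
trial_rate_matrix <- function(spikes, trial, n_neurons,
                              window = c(0, attr(spikes, "duration")),
                              bin_ms = 1, boxcar_ms = 200) {
  s <- spikes[spikes$trial == trial & spikes$time_ms >= window[1] &
                spikes$time_ms < window[2], , drop = FALSE]
  T <- floor((window[2] - window[1]) / bin_ms)
  counts <- matrix(0, T, n_neurons)
  if (nrow(s) > 0) {
    bin <- floor((s$time_ms - window[1]) / bin_ms) + 1L
    tab <- tabulate(bin + T * (s$neuron - 1L), nbins = T * n_neurons)
    counts <- matrix(tab, T, n_neurons)
  }
  boxcar_smooth(counts / (bin_ms / 1000), round(boxcar_ms / bin_ms))
}

#' Choice mode of a recorded population
#'
#' Unit-free population direction
#' `C = (⟨r_R⟩ - ⟨r_L⟩) / (sqrt(N) ||⟨r_R⟩ - ⟨r_L⟩||)` with the averages
#' taken over trials and over a window at the end of the delay epoch, so
#' that `||C|| = 1/sqrt(N)` and projections are independent of the number
#' of recorded neurons. Neurons missing in a trial are given weight zero;
#' trials with fewer than `min_neurons` recorded neurons are excluded.
#'
#' @param rates_R,rates_L lists of time x neurons per-trial rate matrices
#'   (from [trial_rate_matrix()]); `NA` columns mark unrecorded neurons
#' @param times bin times (ms) matching the matrix rows
#' @param window averaging window `c(t0, t1)` in ms (typically the last
#'   second of the delay)
#' @param min_neurons minimum simultaneously recorded neurons per trial
#' @return list with the mode vector `C`, the window used and the number
#'   of trials kept per condition
#' @export
choice_mode <- function(rates_R, rates_L, times, window,
                        min_neurons = 10) {
  keep_ok <- function(m) sum(!is.na(m[1, ])) >= min_neurons
  rates_R <- Filter(keep_ok, rates_R)
  rates_L <- Filter(keep_ok, rates_L)
  stopifnot(length(rates_R) >= 1, length(rates_L) >= 1)
  in_win <- times >= window[1] & times <= window[2]
  avg <- function(lst) {
    m <- sapply(lst, function(x) colMeans(x[in_win, , drop = FALSE]))
    rowMeans(m, na.rm = TRUE)
  }
  d <- avg(rates_R) - avg(rates_L)
  d[is.na(d)] <- 0
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("identical lick-right and lick-left averages")
  N <- length(d)
  list(C = d / (sqrt(N) * nrm), window = window,
       n_trials = c(R = length(rates_R), L = length(rates_L)))
}

#' Project population activity on the choice and homogeneous modes
#'
#' `P_C(t) = C . r(t)` and `P_H(t) = mean_i r_i(t)`.
#'
#' @param rates time x neurons rate matrix of one trial
#' @param C choice-mode vector from [choice_mode()]
#' @return data.frame with `P_C` and `P_H` per time bin
#' @export
project_modes <- function(rates, C) {
  stopifnot(ncol(rates) == length(C))
  r <- unclass(rates)
  r[is.na(r)] <- 0
  data.frame(P_C = drop(r %*% C), P_H = rowMeans(rates, na.rm = TRUE))
}

#' Recovery time of a mode after a perturbation
#'
#' Per-time-bin two-sample t-tests between perturbed and unperturbed
#' single-trial projections. A session is analyzed only if at least
#' `min_sig_frac` of the bins inside the perturbation window are
#' significant. The recovery time is the last significant bin inside the
#' search window at which the smoothed mean difference also changes slowly
#' (absolute derivative below `deriv_thresh`); the decay rate comes from an
#' exponential fit to the absolute mean difference.
#'
#' @param proj_pert,proj_unpert time x trials matrices of projections
#' @param times bin times (ms; the delay axis, go cue at 0)
#' @param pert_window perturbation window `c(t0, t1)` ms
#' @param search_window recovery search window `c(t0, t1)` ms
#' @param alpha per-bin significance level
#' @param min_sig_frac session-inclusion fraction
#' @param deriv_thresh slow-change criterion on `|d(Delta)/dt|`, in
#'   projection units per ms; default 0.1 of the peak |Delta| per 100 ms
#' @param smooth_ms smoothing applied to the difference curve before the
#'   derivative test
#' @return an `ss_recovery`: per-bin `p_values`, `significant` mask,
#'   `included`, `recovery_time` (`NA` when undefined), fitted `decay_rate`
#'   (1/ms) and the `delta` curve
#' @export
recovery_time <- function(proj_pert, proj_unpert, times, pert_window,
                          search_window = c(-1200, 0), alpha = 0.05,
                          min_sig_frac = 0.1, deriv_thresh = NULL,
                          smooth_ms = 100) {
  stopifnot(nrow(proj_pert) == length(times),
            nrow(proj_unpert) == length(times),
            ncol(proj_pert) >= 5, ncol(proj_unpert) >= 5)
  pv <- vapply(seq_along(times), function(t) {
    a <- proj_pert[t, ]
    b <- proj_unpert[t, ]
    if (sd(a) == 0 && sd(b) == 0) return(if (mean(a) == mean(b)) 1 else 0)
    t.test(a, b)$p.value
  }, numeric(1))
  sig <- pv < alpha
  in_pert <- times >= pert_window[1] & times <= pert_window[2]
  included <- mean(sig[in_pert]) >= min_sig_frac
  dt_bin <- diff(times[1:2])
  delta <- rowMeans(proj_pert) - rowMeans(proj_unpert)
  ds <- boxcar_smooth(matrix(delta), max(1, round(smooth_ms / dt_bin)))[, 1]
  deriv <- c(0, diff(ds)) / dt_bin
  if (is.null(deriv_thresh))
    deriv_thresh <- 0.1 * max(abs(ds)) / 100
  rec <- NA_real_
  if (included) {
    in_search <- times >= search_window[1] & times <= search_window[2]
    # the significant run attached to the perturbation window: scanning
    # forward from the window end, the run continues while bins stay
    # significant (single-bin gaps tolerated); isolated later false
    # positives do not extend the recovery estimate
    start <- which(in_search)[1]
    run_end <- NA_integer_
    gap <- 0L
    for (i in seq(start, length(times))) {
      if (!in_search[i]) break
      if (sig[i]) {
        run_end <- i
        gap <- 0L
      } else {
        gap <- gap + 1L
        if (gap >= 2L) break
      }
    }
    if (!is.na(run_end)) {
      cand <- which(sig & in_search & abs(deriv) <= deriv_thresh)
      cand <- cand[cand <= run_end]
      if (length(cand)) rec <- times[max(cand)] else rec <- times[run_end]
    }
  }
  # exponential decay fit of |delta| after the perturbation window
  decay <- NA_real_
  post <- which(times > pert_window[2] & abs(ds) > 1e-12)
  if (length(post) > 5) {
    df <- data.frame(t = times[post], y = log(abs(ds[post])))
    fit <- lm(y ~ t, df)
    decay <- -unname(coef(fit)[2])
  }
  structure(list(p_values = pv, significant = sig, included = included,
                 recovery_time = rec, decay_rate = decay, delta = ds,
                 times = times),
            class = "ss_recovery")
}
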