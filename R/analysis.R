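# Truncated boxcar smoothing along rows (time) of a time x neurons matrix;
# the window shrinks at the edges so no bins are lost.
boxcar_smooth <- function(x, width_bins) {
  if (width_bins <= 1) return(x)
  h <- floor((width_bins - 1) / 2)
  T <- nrow(x)
  cs <- rbind(0, apply(x, 2, cumsum))
  lo <- pmax(seq_len(T) - h, 1)
  hi <- pmin(seq_len(T) + h, T)
  (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

#' Trial-averaged PSTHs from a spike raster
#'
#' Spikes are placed in fixed-width bins over the analysis window, averaged
#' across trials and smoothed with a truncated moving average. Defaults:
#' 20 ms bins, 300 ms smoothing window.
#'
#' @param spikes data.frame with `trial`, `neuron`, `time_ms` (e.g. from
#'   [target_window_spikes()]); time 0 is the window start
#' @param n_neurons number of neurons (PSTH columns)
#' @param n_trials number of trials averaged (defaults to
#'   `attr(spikes, "n_trials")`)
#' @param window `c(t0, t1)` analysis window in ms
#' @param bin_ms bin width (ms)
#' @param smooth_ms moving-average window (ms); `smooth_ms = bin_ms` is the
#'   identity
#' @param neurons optional subset of neuron ids to keep as columns
#' @return matrix of class `ss_psth`, time bins x neurons, in Hz, with bin
#'   centers in `attr(, "times")`
#' @export
compute_psth <- function(spikes, n_neurons, n_trials = NULL,
                         window = c(0, attr(spikes, "duration")),
                         bin_ms = 20, smooth_ms = 300, neurons = NULL) {
  if (is.null(n_trials)) n_trials <- attr(spikes, "n_trials")
  stopifnot(!is.null(n_trials), n_trials >= 1)
  T <- floor((window[2] - window[1]) / bin_ms)
  keep <- spikes$time_ms >= window[1] & spikes$time_ms < window[1] + T * bin_ms
  s <- spikes[keep, , drop = FALSE]
  bin <- floor((s$time_ms - window[1]) / bin_ms)
  counts <- matrix(0, T, n_neurons)
  if (nrow(s) > 0) {
    idx <- bin + 1L + T * (s$neuron - 1L)
    tab <- tabulate(idx, nbins = T * n_neurons)
    counts <- matrix(tab, T, n_neurons)
  }
  rates <- counts / (n_trials * bin_ms / 1000)
  rates <- boxcar_smooth(rates, round(smooth_ms / bin_ms))
  if (!is.null(neurons)) rates <- rates[, neurons, drop = FALSE]
  structure(rates,
            times = window[1] + (seq_len(T) - 0.5) * bin_ms,
            bin_ms = bin_ms, smooth_ms = smooth_ms, n_trials = n_trials,
            class = c("ss_psth", "matrix"))
}

#' Principal component analysis of population rate dynamics
#'
#' The mean rate of every neuron is subtracted from its PSTH; the principal
#' components are the left singular vectors of the centered time x neurons
#' matrix, and the variance explained by component `k` is
#' `lambda_k^2 / sum_i lambda_i^2` with `lambda` the singular values. Each
#' component's sign is fixed so its largest-magnitude time bin is positive.
#'
#' @param psth time x neurons rate matrix (an `ss_psth` or plain matrix)
#' @return an `ss_pca`: `components` (time x modes, orthonormal),
#'   `sing_values`, `var_frac`, per-neuron `loadings`, and the removed
#'   `mean_rates`
#' @export
pca_psth <- function(psth) {
  R <- unclass(psth)
  stopifnot(ncol(R) >= 2)
  mu <- colMeans(R)
  R <- sweep(R, 2, mu)
  sv <- svd(R)
  sgn <- apply(sv$u, 2, function(u) sign(u[which.max(abs(u))]))
  sgn[sgn == 0] <- 1
  u <- sweep(sv$u, 2, sgn, `*`)
  v <- sweep(sv$v, 2, sgn, `*`)
  structure(list(components = u, sing_values = sv$d,
                 var_frac = sv$d^2 / sum(sv$d^2),
                 loadings = v %*% diag(sv$d, length(sv$d)),
                 mean_rates = mu),
            class = "ss_pca")
}

#' Transferred cortical-like activity
#'
#' Fraction of centered PSTH variance captured by the first `k` principal
#' components. With `reference_pcs` the variance is measured along the
#' given orthonormal components (e.g. those of the trained subnetwork)
#' instead of the population's own leading components.
#'
#' @param psth time x neurons rate matrix
#' @param k number of components
#' @param reference_pcs optional time x modes orthonormal matrix
#' @return variance fraction in `[0, 1]`
#' @export
transferred_activity <- function(psth, k = 6, reference_pcs = NULL) {
  R <- sweep(unclass(psth), 2, colMeans(psth))
  tot <- sum(R^2)
  if (is.null(reference_pcs)) {
    p <- pca_psth(psth)
    if (k > sum(p$sing_values > 1e-12 * p$sing_values[1]))
      stop("k exceeds the rank of the centered PSTH matrix")
    sum(p$var_frac[seq_len(k)])
  } else {
    stopifnot(nrow(reference_pcs) == nrow(R), k <= ncol(reference_pcs))
    proj <- crossprod(reference_pcs[, seq_len(k), drop = FALSE], R)
    sum(proj^2) / tot
  }
}

#' Fidelity of transferred principal components
#'
#' Absolute correlation between corresponding principal components of the
#' trained and the transferred (untrained-subnetwork) activity; components
#' are defined up to sign, so the absolute value is reported.
#'
#' @param pca_trained,pca_untrained `ss_pca` objects on the same time grid
#' @param k number of modes
#' @return numeric vector of per-mode fidelities
#' @export
pc_fidelity <- function(pca_trained, pca_untrained, k = 6) {
  stopifnot(nrow(pca_trained$components) == nrow(pca_untrained$components))
  vapply(seq_len(k), function(n)
    abs(cor(pca_trained$components[, n], pca_untrained$components[, n])),
    numeric(1))
}

#' Shared variance between two populations
#'
#' Correlation matrix `C[i, j] = cor(f_i, g_j)` between the PSTHs of the
#' two populations, its singular value decomposition `C = U S V'`, the
#' shared components `alpha_k = F u_k`, `beta_k = G v_k`, and the shared
#' variance fractions `||alpha_k||^2 / sum ||alpha||^2` (and the `beta`
#' analog). Zero-variance neurons get zero correlation rows/columns and are
#' reported.
#'
#' @param F,G time x neurons rate matrices on the same time grid
#' @return an `ss_shared`: `C`, `u`, `v`, `d`, `alpha`, `beta`,
#'   `frac_alpha`, `frac_beta`, `zero_variance`
#' @export
shared_variance <- function(F, G) {
  stopifnot(nrow(F) == nrow(G))
  Fc <- sweep(unclass(F), 2, colMeans(F))
  Gc <- sweep(unclass(G), 2, colMeans(G))
  zf <- apply(Fc, 2, sd) == 0
  zg <- apply(Gc, 2, sd) == 0
  C <- matrix(0, ncol(F), ncol(G))
  C[!zf, !zg] <- cor(Fc[, !zf, drop = FALSE], Gc[, !zg, drop = FALSE])
  sv <- svd(C)
  alpha <- Fc %*% sv$u
  beta <- Gc %*% sv$v
  na <- colSums(alpha^2)
  nb <- colSums(beta^2)
  structure(list(C = C, u = sv$u, v = sv$v, d = sv$d,
                 alpha = alpha, beta = beta,
                 frac_alpha = na / sum(na), frac_beta = nb / sum(nb),
                 zero_variance = list(F = which(zf), G = which(zg))),
            class = "ss_shared")
}

#' Choice selectivity of paired lick-right / lick-left PSTHs
#'
#' `s_i(t) = (r_R - r_L) / mean rate`, with the mean rate taken over time
#' and both conditions; the scalar index is the time-average of `s_i(t)`.
#' Positive values indicate lick-right preference. Neurons with zero mean
#' rate are undefined and reported as `NA`.
#'
#' @param psth_R,psth_L time x neurons rate matrices for paired neurons
#' @return list with `timeseries` (time x neurons), `index` (per neuron)
#'   and `excluded` (zero-rate neurons)
#' @export
choice_selectivity <- function(psth_R, psth_L) {
  stopifnot(dim(psth_R) == dim(psth_L))
  mr <- (colMeans(psth_R) + colMeans(psth_L)) / 2
  s <- sweep(unclass(psth_R) - unclass(psth_L), 2, mr, `/`)
  s[, mr == 0] <- NA_real_
  list(timeseries = s, index = colMeans(s),
       excluded = which(mr == 0))
}
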