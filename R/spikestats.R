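#' Spiking variability and rate statistics
#'
#' Fano factor of per-trial spike counts (variance/mean across trials,
#' averaged over neurons whose mean count in the window reaches
#' `min_count`), per-neuron interspike-interval coefficient of variation,
#' the firing-rate distribution with its skewness, and a normality test of
#' the log rates against a fitted normal (log-normal tendency).
#'
#' @param spikes data.frame `trial`, `neuron`, `time_ms`
#' @param n_neurons,n_trials population and trial counts (default from
#'   attributes)
#' @param window counting window `c(t0, t1)` ms (default the full window)
#' @param min_count minimum mean spike count for a neuron to enter the
#'   Fano average
#' @param min_isis minimum number of ISIs for the CV of a neuron
#' @return list with `fano`, `fano_per_neuron`, `cv`, `cv_per_neuron`,
#'   `rates_hz`, `log_rate_test` (Lilliefors), `rate_skewness`
#' @export
spike_stats <- function(spikes, n_neurons = attr(spikes, "n_neurons"),
                        n_trials = attr(spikes, "n_trials"),
                        window = c(0, attr(spikes, "duration")),
                        min_count = 1, min_isis = 5) {
  stopifnot(!is.null(n_neurons), !is.null(n_trials))
  s <- spikes[spikes$time_ms >= window[1] & spikes$time_ms < window[2], ,
              drop = FALSE]
  win_s <- (window[2] - window[1]) / 1000

  counts <- matrix(0, n_trials, n_neurons)
  if (nrow(s)) {
    tab <- tabulate(s$trial + n_trials * (s$neuron - 1L),
                    nbins = n_trials * n_neurons)
    counts <- matrix(tab, n_trials, n_neurons)
  }
  mu <- colMeans(counts)
  va <- apply(counts, 2, var)
  eligible <- mu >= min_count
  fano_per_neuron <- ifelse(mu > 0, va / mu, NA_real_)
  fano <- mean(fano_per_neuron[eligible], na.rm = TRUE)

  cv_per_neuron <- rep(NA_real_, n_neurons)
  if (nrow(s)) {
    s <- s[order(s$neuron, s$trial, s$time_ms), ]
    isis <- split(s$time_ms, list(s$trial, s$neuron), drop = TRUE)
    key <- strsplit(names(isis), "\\.")
    nrn <- as.integer(vapply(key, `[`, "", 2))
    d <- lapply(isis, diff)
    by_n <- split(unlist(d, use.names = FALSE), rep(nrn, lengths(d)))
    for (nm in names(by_n)) {
      x <- by_n[[nm]]
      if (length(x) >= min_isis)
        cv_per_neuron[as.integer(nm)] <- sd(x) / mean(x)
    }
  }
  cv <- mean(cv_per_neuron, na.rm = TRUE)

  rates <- mu / win_s
  pos <- rates > 0
  lr <- log(rates[pos])
  log_rate_test <- if (sum(pos) >= 5) nortest::lillie.test(lr) else NULL
  m3 <- mean((rates - mean(rates))^3) / sd(rates)^3

  list(fano = fano, fano_per_neuron = fano_per_neuron,
       cv = cv, cv_per_neuron = cv_per_neuron,
       rates_hz = rates, log_rate_test = log_rate_test,
       rate_skewness = m3)
}

#' Decompose recorded synaptic inputs by presynaptic group
#'
#' From group-resolved input traces of untrained neurons: the aggregate
#' input from the trained excitatory and trained inhibitory populations,
#' the untrained remainders, their temporal modulations
#' `delta u = u - time mean`, and the PCA of the modulations across
#' recorded neurons (whose per-component loadings feed
#' [gaussian_loading_test()]).
#'
#' @param traces array neuron x time x channel from [simulate_network()]
#'   run with `record_groups = TRUE`
#' @param X_bal external drives of the recorded neurons (for the total)
#' @return list with the group matrices (time x neurons), `delta` versions,
#'   `pca` of the trained-group modulation, `pca_total` of the total-input
#'   modulation, and the additivity residual
#' @export
input_decomposition <- function(traces, X_bal = NULL) {
  ch <- dimnames(traces)[[3]]
  need <- c("u_balE", "u_balI", "u_from_trainedE", "u_from_trainedI")
  if (!all(need %in% ch))
    stop("traces were not recorded with record_groups = TRUE")
  g <- function(nm) t(traces[, , nm])  # time x neurons
  uE <- g("u_balE"); uI <- g("u_balI")
  trE <- g("u_from_trainedE"); trI <- g("u_from_trainedI")
  upl <- g("u_plas"); xpl <- g("X_plas"); xst <- g("X_stim")
  tot <- uE + uI + upl + xpl + xst
  if (!is.null(X_bal)) tot <- sweep(tot, 2, X_bal, `+`)
  cen <- function(m) sweep(m, 2, colMeans(m))
  dtr <- cen(trE)
  dtot <- cen(tot)
  list(from_trainedE = trE, from_trainedI = trI,
       from_untrainedE = uE - trE, from_untrainedI = uI - trI,
       total = tot,
       delta_trainedE = dtr, delta_total = dtot,
       pca = pca_psth(trE), pca_total = pca_psth(tot))
}

#' Normality test for per-component loadings
#'
#' Standardized loadings are tested with the Lilliefors-corrected
#' Kolmogorov--Smirnov test against a fitted normal; the fitted mean and SD
#' are reported. Constant loadings are degenerate and reported as such.
#'
#' @param loadings numeric vector (>= 50 values)
#' @return list with `statistic`, `p_value`, `mean`, `sd`, `degenerate`
#' @export
gaussian_loading_test <- function(loadings) {
  if (length(loadings) < 50)
    stop("need at least 50 loadings for a meaningful normality test")
  m <- mean(loadings)
  s <- sd(loadings)
  if (s == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, mean = m, sd = 0,
                degenerate = TRUE))
  lt <- nortest::lillie.test(loadings)
  list(statistic = unname(lt$statistic), p_value = lt$p.value,
       mean = m, sd = s, degenerate = FALSE)
}
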