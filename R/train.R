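#' Train the plastic synapses of the selected subset
#'
#' FORCE-style online loop: every iteration runs the network through
#' burn-in, stimulus and target window; during the target window each
#' trained neuron's recursive-least-squares state is updated every
#' `learn_every` ms from its instantaneous filtered presynaptic vector so
#' that its total synaptic input tracks the per-neuron target. With two
#' trial types the iterations alternate types while a single weight set
#' serves both. The inverse-correlation matrices carry over across
#' iterations. Plastic weights may flip sign during training (the static
#' network alone enforces Dale's law).
#'
#' @param network an `ss_network`
#' @param plastic an `ss_plastic` built with [build_plastic_connectivity()]
#' @param targets an `ss_targets` (see [make_sine_targets()],
#'   [psth_to_targets()]); must contain one row per trained neuron, in any
#'   order, with `$neurons` naming the model neuron of each row. Before the
#'   target window the clamp target is the row's value at time 0 (the
#'   baseline input), keeping the plastic inputs controlled across the
#'   burn-in and stimulus of every training iteration
#' @param drives an `ss_drives` with as many stimulus sets as target types
#' @param config an [training_config()]
#' @return list with the trained `plastic`, a `diagnostics` data.frame
#'   (per-iteration mean absolute error and mean target--input correlation)
#'   and the per-neuron aggregate plastic row sums after training
#' @export
train_subset <- function(network, plastic, targets, drives, config) {
  stopifnot(inherits(plastic, "ss_plastic"), inherits(config, "ss_train_config"))
  dt <- network$neuron$dt
  learn_steps <- round(config$learn_every / dt)
  n_targ <- round(config$T_target / dt)
  if (n_targ %% learn_steps != 0)
    stop("T_target must be a multiple of learn_every")
  n_upd <- n_targ / learn_steps
  if (config$n_iter == 0) {
    return(list(plastic = plastic,
                diagnostics = data.frame(iter = integer(0),
                                         mean_abs_e = numeric(0),
                                         mean_corr = numeric(0)),
                rowsums = NULL))
  }
  n_types <- length(targets$f)
  stopifnot(drives$n_types >= n_types)

  # align target rows with the plastic slot order and resample each row at
  # the update instants
  ord <- match(plastic$trained, targets$neurons)
  if (anyNA(ord))
    stop("targets missing for some trained neurons")
  t_upd <- config$learn_every * seq_len(n_upd)
  f_upd <- lapply(targets$f, function(fm) {
    fm <- fm[ord, , drop = FALSE]
    t(apply(fm, 1, function(row)
      approx(targets$times, row, xout = t_upd, rule = 2)$y))
  })

  net <- cpp_net(network, plastic)
  cfg <- list(n_iter = as.integer(config$n_iter),
              learn_every = as.integer(learn_steps),
              lambda = config$lambda, mu = config$mu,
              err_avg_ms = config$err_avg_ms,
              reset_P = isTRUE(config$reset_P),
              clamp_pretarget = isTRUE(config$clamp_pretarget),
              Xstim = drives$X_stim[seq_len(n_types)],
              f_upd = f_upd,
              f_baseline = unname(f_upd[[1]][, 1]),
              ext_rate = drives$ext_rate,
              ign_amp = drives$ign_amp, ign_tau = drives$ign_tau,
              n_burn = round(drives$burn_ms / dt),
              n_stim = round(drives$stim_ms / dt),
              n_targ = as.integer(n_targ))
  set.seed(config$seed)
  out <- train_cpp(net, cfg)
  if (isTRUE(out$diverged))
    warning("training diverged (mean |e| grew 10x over 5 iterations); ",
            "weights returned at the point of divergence")
  plastic$w <- as.numeric(out$w)
  diag <- data.frame(iter = seq_len(config$n_iter),
                     mean_abs_e = as.numeric(out$mean_abs_e),
                     mean_corr = as.numeric(out$mean_corr))
  rs <- out$rowsums
  colnames(rs) <- c("E", "I")
  list(plastic = plastic, diagnostics = diag, rowsums = rs)
}

#' Aggregate plastic row sums per population
#'
#' @param plastic an `ss_plastic`
#' @return matrix (trained neurons x 2) of summed E and I recurrent plastic
#'   weights
#' @export
plastic_rowsums <- function(plastic) {
  nslot <- length(plastic$trained)
  rs <- matrix(0, nslot, 2, dimnames = list(NULL, c("E", "I")))
  for (s in seq_len(nslot)) {
    idx <- (plastic$w_off[s] + 1):plastic$w_off[s + 1]
    rs[s, 1] <- sum(plastic$w[idx][plastic$kind[idx] == 0])
    rs[s, 2] <- sum(plastic$w[idx][plastic$kind[idx] == 1])
  }
  rs
}
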