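#' Neuron parameters
#'
#' Integration and leaky integrate-and-fire parameters. Defaults are the
#' standard simulation values: Euler step `dt = 0.1` ms, membrane time
#' constant `tau_m = 10` ms, dimensionless spike threshold `v_thr = 1` and
#' post-spike reset `v_reset = 0`.
#'
#' @param dt simulation time step (ms)
#' @param tau_m membrane time constant (ms)
#' @param v_thr spike threshold (dimensionless input units)
#' @param v_reset post-spike reset value
#' @return an object of class `ss_neuron`
#' @export
neuron_params <- function(dt = 0.1, tau_m = 10, v_thr = 1, v_reset = 0) {
  stopifnot(dt > 0, tau_m > 0, v_reset < v_thr)
  structure(list(dt = dt, tau_m = tau_m, v_thr = v_thr, v_reset = v_reset),
            class = "ss_neuron")
}

#' Population layout
#'
#' Half-excitatory, half-inhibitory by default, stored E-block first.
#'
#' @param N total number of neurons
#' @param frac_exc fraction of excitatory neurons
#' @return an object of class `ss_layout` with fields `N`, `N_E`, `N_I` and
#'   the logical vector `is_exc`
#' @export
population_layout <- function(N, frac_exc = 0.5) {
  stopifnot(N >= 2, frac_exc > 0, frac_exc < 1)
  N_E <- round(N * frac_exc)
  N_I <- N - N_E
  structure(list(N = N, N_E = N_E, N_I = N_I,
                 is_exc = c(rep(TRUE, N_E), rep(FALSE, N_I))),
            class = "ss_layout")
}

#' Synapse parameters
#'
#' Static (fast, AMPA/GABA-like) and plastic (slow, NMDA-like) synaptic time
#' constants, the 2x2 table of unscaled static weight magnitudes
#' `Jbar[post, pre]` and the table of mean static in-degrees `K[post, pre]`.
#' Signs are applied at weight construction: excitatory presynaptic columns
#' are positive, inhibitory columns negative (Dale's law for static synapses).
#'
#' @param tau_bal static synaptic time constant (ms)
#' @param tau_plas plastic synaptic time constant (ms)
#' @param Jbar 2x2 matrix of unscaled weight magnitudes, dimnames E/I
#' @param K 2x2 matrix of mean static in-degrees
#' @return an object of class `ss_synapse`
#' @export
synapse_params <- function(tau_bal = 3, tau_plas = 150, Jbar, K) {
  stopifnot(tau_plas > tau_bal, tau_bal > 0,
            is.matrix(Jbar), all(dim(Jbar) == 2),
            is.matrix(K), all(dim(K) == 2), all(K > 0), all(Jbar > 0))
  dimnames(Jbar) <- dimnames(K) <- list(c("E", "I"), c("E", "I"))
  structure(list(tau_bal = tau_bal, tau_plas = tau_plas, Jbar = Jbar, K = K),
            class = "ss_synapse")
}

#' Default strong-coupling network parameters
#'
#' Assembles the default parameter set of the balanced network: connection
#' probability `p`, unscaled weights J_E = 2.0 (excitatory) and J_I = 2.0
#' (inhibitory magnitude), relative strengths gamma_E = 0.15 (E-to-E vs
#' E-to-I), gamma_I = 0.75 (I-to-E vs I-to-I) and gamma_X = 1.5 (external
#' drive to E vs I), and the external input X = 0.08 sqrt(K_I).
#'
#' @param N total number of neurons
#' @param p static connection probability (`K_ab = p N_b`)
#' @param J_E,J_I unscaled synaptic weight magnitudes
#' @param gamma_E,gamma_I,gamma_X relative-strength factors
#' @param X_scale external-input scale (X_I = X_scale * sqrt(K_I))
#' @param charge per-spike charge normalization of the static synapses, in
#'   units of `tau_m * J`: a presynaptic spike deposits membrane charge
#'   `charge * tau_m * J` through the fast synaptic kernel. The printed
#'   network equations fix the kernel but not this normalization; the
#'   default 0.45 places the network in the fluctuation-driven irregular
#'   regime while keeping reduced-size networks trainable (see the methods
#'   vignette)
#' @param frac_exc fraction of excitatory neurons
#' @param neuron a [neuron_params()] object
#' @param tau_bal,tau_plas synaptic time constants (ms)
#' @return a list of class `ss_params` with `layout`, `neuron`, `syn`,
#'   per-population external drives `X_E`, `X_I` and the scalars used
#' @export
network_params <- function(N, p = 0.2, J_E = 2.0, J_I = 2.0,
                           gamma_E = 0.15, gamma_I = 0.75, gamma_X = 1.5,
                           X_scale = 0.08, charge = 0.45, frac_exc = 0.5,
                           neuron = neuron_params(),
                           tau_bal = 3, tau_plas = 150) {
  layout <- population_layout(N, frac_exc)
  K <- matrix(c(p * layout$N_E, p * layout$N_E,
                p * layout$N_I, p * layout$N_I), 2, 2)
  Jbar <- matrix(c(gamma_E * J_E, J_E, gamma_I * J_I, J_I), 2, 2)
  syn <- synapse_params(tau_bal, tau_plas, Jbar, K)
  X_I <- X_scale * sqrt(syn$K["I", "I"])
  X_E <- gamma_X * X_I
  structure(list(layout = layout, neuron = neuron, syn = syn, p = p,
                 J_E = J_E, J_I = J_I, gamma_E = gamma_E, gamma_I = gamma_I,
                 gamma_X = gamma_X, X_scale = X_scale, charge = charge,
                 X_E = X_E, X_I = X_I),
            class = "ss_params")
}

#' Read / write a network configuration file
#'
#' Plain YAML mirroring the canonical parameter names (`tau_m`, `tau_bal`,
#' `tau_plas`, `J_E`, `J_I`, `gamma_E`, `gamma_I`, `gamma_X`, `X`, `p`, `N`,
#' `lambda`, `mu`, `N_iter`, `T_target`, `learn_every`).
#'
#' @param path file path
#' @param config named list of parameters
#' @return `read_network_config` returns the named list
#' @export
read_network_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_network_config
#' @export
write_network_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
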