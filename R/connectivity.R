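#' Build the static balanced connectivity
#'
#' Connects neuron `j` of population `beta` to neuron `i` of population
#' `alpha` (`i != j`) independently with probability `K[alpha,beta] / N_beta`
#' and weight `Jbar[alpha,beta] / sqrt(K[alpha,beta])`, positive for
#' excitatory and negative for inhibitory presynaptic neurons. With
#' `scaling = "K"` the weight magnitude is `Jbar / K` instead, giving the
#' weak-coupling (averaging) control network.
#'
#' @param layout a [population_layout()]
#' @param syn a [synapse_params()]
#' @param seed integer seed
#' @param scaling `"sqrtK"` (strong, balanced) or `"K"` (weak control)
#' @return a list of class `ss_static` with the sparse weight matrix `J`
#'   (postsynaptic rows x presynaptic columns, `dgCMatrix`) and the build
#'   parameters
#' @export
build_static_connectivity <- function(layout, syn, seed = 1,
                                      scaling = c("sqrtK", "K")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(layout, "ss_layout"), inherits(syn, "ss_synapse"))
  N <- layout$N
  Nb <- c(E = layout$N_E, I = layout$N_I)
  for (b in c("E", "I"))
    if (any(syn$K[, b] > Nb[[b]]))
      stop("in-degree K[, ", b, "] exceeds N_", b)
  set.seed(seed)
  pre_blk <- list(E = seq_len(Nb["E"]), I = Nb["E"] + seq_len(Nb["I"]))
  post_blk <- pre_blk
  ii <- vector("list", 4L); jj <- vector("list", 4L); xx <- vector("list", 4L)
  blk <- 0L
  for (b in c("E", "I")) {
    for (a in c("E", "I")) {
      blk <- blk + 1L
      p_ab <- syn$K[a, b] / Nb[[b]]
      den <- if (scaling == "sqrtK") sqrt(syn$K[a, b]) else syn$K[a, b]
      wgt <- (if (b == "E") 1 else -1) * syn$Jbar[a, b] / den
      same <- identical(a, b)
      n_post <- Nb[[a]]
      ptr <- vector("list", Nb[[b]])
      for (jloc in seq_len(Nb[[b]])) {
        pool <- if (same) n_post - 1L else n_post
        cnt <- rbinom(1L, pool, p_ab)
        if (cnt == 0L) { ptr[[jloc]] <- integer(0); next }
        idx <- sample.int(pool, cnt)
        if (same) idx <- idx + (idx >= jloc)  # skip the diagonal
        ptr[[jloc]] <- idx
      }
      lens <- lengths(ptr)
      ii[[blk]] <- post_blk[[a]][1L] - 1L + unlist(ptr, use.names = FALSE)
      jj[[blk]] <- rep(pre_blk[[b]], lens)
      xx[[blk]] <- rep(wgt, sum(lens))
    }
  }
  J <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(N, N))
  structure(list(J = J, layout = layout, syn = syn, scaling = scaling,
                 seed = seed),
            class = "ss_static")
}

#' Assemble a balanced network
#'
#' Convenience constructor tying together [network_params()] and
#' [build_static_connectivity()] with the constant external drives
#' `X_bal` (`gamma_X * X` to excitatory and `X` to inhibitory neurons, both
#' proportional to `sqrt(K)`).
#'
#' @param params an `ss_params` object from [network_params()]
#' @param seed integer seed for the connectivity draw
#' @param scaling weight scaling, see [build_static_connectivity()]
#' @return an object of class `ss_network`
#' @export
balanced_network <- function(params, seed = 1, scaling = "sqrtK") {
  static <- build_static_connectivity(params$layout, params$syn, seed, scaling)
  X_bal <- ifelse(params$layout$is_exc, params$X_E, params$X_I)
  structure(list(layout = params$layout, neuron = params$neuron,
                 syn = params$syn, params = params, static = static,
                 X_bal = X_bal, noise_amp = 0, charge = params$charge),
            class = "ss_network")
}

#' Initial plastic-weight magnitudes for the standard training setups
#'
#' Multipliers of the unscaled static weights: `sine` uses W_E = 2 J_E,
#' W_I = 1 J_I; `neural_psth` uses 0.66 J_E / 0.33 J_I; `synthetic_psth`
#' uses 1 J_E / 0.5 J_I. Feedforward synapses from the external units are
#' initialized at the excitatory magnitude.
#'
#' @param setup one of `"sine"`, `"neural_psth"`, `"synthetic_psth"`
#' @return list with elements `E` and `I` (multipliers of J_E, J_I)
#' @export
plastic_init_scales <- function(setup = c("sine", "neural_psth",
                                          "synthetic_psth")) {
  setup <- match.arg(setup)
  switch(setup,
         sine = list(E = 2.0, I = 1.0),
         neural_psth = list(E = 0.66, I = 0.33),
         synthetic_psth = list(E = 1.0, I = 0.5))
}

#' Build the sparse trainable (plastic) connectivity
#'
#' Each trained neuron receives `L_rec / 2` excitatory and `L_rec / 2`
#' inhibitory recurrent plastic synapses plus all `L_X` feedforward synapses
#' from the external Poisson units. Presynaptic pools follow the
#' trained-subnetwork rule: when the excitatory subnetwork is trained, the
#' excitatory partners are drawn from the other trained excitatory neurons
#' and the inhibitory partners from the whole inhibitory population (and
#' symmetrically when the inhibitory subnetwork is trained). The plastic
#' support is disjoint from the static synapses and from the diagonal, and
#' stays fixed for the lifetime of a training run; only values change.
#'
#' @param network an `ss_network`
#' @param trained_set integer vector of trained neuron ids (1-based)
#' @param L_rec total number of recurrent plastic synapses per trained
#'   neuron (even; half from each population). Default `c_plastic * sqrt(K)`
#'   rounded to an even number.
#' @param L_X number of external (feedforward) plastic units
#' @param c_plastic order-one sparsity prefactor used when `L_rec` is `NULL`
#' @param init_scales list with `E` and `I` multipliers of the unscaled
#'   J_E / J_I magnitudes, see [plastic_init_scales()]
#' @param seed integer seed
#' @return an object of class `ss_plastic` holding the flat weight layout
#'   (`trained`, `w_off`, `Lrec`, `pre_id`, `kind`, `post_of`, `w`, `LX`)
#'   and the reverse adjacency maps used by the simulator
#' @export
build_plastic_connectivity <- function(network, trained_set,
                                       L_rec = NULL, L_X = 0,
                                       c_plastic = 2.83,
                                       init_scales = plastic_init_scales("sine"),
                                       seed = 1) {
  stopifnot(inherits(network, "ss_network"), length(trained_set) >= 1)
  layout <- network$layout
  trained_set <- sort(unique(as.integer(trained_set)))
  if (any(trained_set < 1 | trained_set > layout$N))
    stop("trained_set out of range")
  K_tot <- sum(network$syn$K[1, ])
  if (is.null(L_rec)) L_rec <- 2L * round(c_plastic * sqrt(K_tot) / 2)
  if (L_rec %% 2 != 0) stop("L_rec must be even (half per population)")
  Lh <- L_rec / 2L
  set.seed(seed)

  is_exc <- layout$is_exc
  trE <- trained_set[is_exc[trained_set]]
  trI <- trained_set[!is_exc[trained_set]]
  allE <- which(is_exc)
  allI <- which(!is_exc)
  poolE_base <- if (length(trE)) trE else allE
  poolI_base <- if (length(trI)) trI else allI

  Jt <- methods::as(network$static$J, "TsparseMatrix")
  # static partners per postsynaptic neuron (for disjointness)
  static_pre <- split(Jt@j + 1L, factor(Jt@i + 1L, levels = seq_len(layout$N)))

  J_E_val <- network$params$J_E / sqrt(network$syn$K["E", "E"])
  J_I_val <- network$params$J_I / sqrt(network$syn$K["I", "I"])
  # a plastic spike delivers charge tau_plas * W; the tau_m/tau_plas factor
  # gives the initial synapse the same per-spike membrane charge as a
  # static synapse of magnitude scale * J, keeping the initial plastic
  # input near spike threshold
  chg <- network$neuron$tau_m / network$syn$tau_plas
  wE <- init_scales$E * J_E_val * chg
  wI <- -init_scales$I * J_I_val * chg

  nslot <- length(trained_set)
  per_len <- L_rec + L_X
  pre_id <- integer(nslot * per_len)
  kind <- integer(nslot * per_len)
  post_of <- integer(nslot * per_len)
  w <- numeric(nslot * per_len)
  for (s in seq_len(nslot)) {
    i <- trained_set[s]
    excl <- c(static_pre[[i]], i)
    pe <- setdiff(poolE_base, excl)
    pi_ <- setdiff(poolI_base, excl)
    if (length(pe) < Lh || length(pi_) < Lh)
      stop("infeasible plastic in-degree for neuron ", i,
           " after excluding static partners")
    se <- if (length(pe) == Lh) pe else sample(pe, Lh)
    si <- if (length(pi_) == Lh) pi_ else sample(pi_, Lh)
    o <- (s - 1L) * per_len
    idx <- o + seq_len(per_len)
    pre_id[idx] <- c(se, si, seq_len(L_X))
    kind[idx] <- rep(c(0L, 1L, 2L), c(Lh, Lh, L_X))
    post_of[idx] <- i
    w[idx] <- c(rep(wE, Lh), rep(wI, Lh), rep(wE, L_X))
  }
  w_off <- c(0L, cumsum(rep(per_len, nslot)))
  obj <- structure(list(trained = trained_set, w_off = w_off,
                        Lrec = rep(L_rec, nslot), pre_id = pre_id,
                        kind = kind, post_of = post_of, w = w, LX = L_X,
                        L_rec = L_rec, init_scales = init_scales,
                        seed = seed),
                   class = "ss_plastic")
  obj$rev <- plastic_reverse_maps(obj, layout$N)
  obj
}

# CSC-style reverse maps: presynaptic neuron -> flat weight entries (recurrent)
# and external unit -> flat weight entries (feedforward)
plastic_reverse_maps <- function(plastic, N) {
  rec <- which(plastic$kind != 2L)
  ffw <- which(plastic$kind == 2L)
  ord_r <- rec[order(plastic$pre_id[rec])]
  rp <- c(0L, cumsum(tabulate(plastic$pre_id[rec], nbins = N)))
  ord_x <- ffw[order(plastic$pre_id[ffw])]
  xp <- c(0L, cumsum(tabulate(plastic$pre_id[ffw],
                              nbins = max(plastic$LX, 1L))))
  list(rp = rp, rflat = ord_r - 1L, xp = xp, xflat = ord_x - 1L)
}

# Empty plastic object (untrained network)
empty_plastic <- function(N) {
  structure(list(trained = integer(0), w_off = 0L, Lrec = integer(0),
                 pre_id = integer(0), kind = integer(0), post_of = integer(0),
                 w = numeric(0), LX = 0L, L_rec = 0L,
                 rev = list(rp = rep(0L, N + 1L), rflat = integer(0),
                            xp = 0L, xflat = integer(0))),
            class = "ss_plastic")
}

#' Verify that plastic and static supports are disjoint
#'
#' @param network an `ss_network`
#' @param plastic an `ss_plastic`
#' @return `TRUE` invisibly; stops if any pair carries both synapse types
#' @export
assert_disjoint_support <- function(network, plastic) {
  if (length(plastic$w) == 0) return(invisible(TRUE))
  rec <- plastic$kind != 2L
  key_p <- paste(plastic$post_of[rec], plastic$pre_id[rec])
  Jt <- methods::as(network$static$J, "TsparseMatrix")
  key_s <- paste(Jt@i + 1L, Jt@j + 1L)
  if (any(key_p %in% key_s))
    stop("plastic support overlaps static synapses")
  if (any(plastic$post_of[rec] == plastic$pre_id[rec]))
    stop("plastic self-connection found")
  invisible(TRUE)
}
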