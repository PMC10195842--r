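// Core leaky integrate-and-fire engine for balanced E/I networks with
// static (fast) and plastic (slow) conductance-free synapses, plus the
// online recursive-least-squares trainer that adjusts the plastic weights
// of a selected subset of neurons so their total synaptic input follows
// per-neuron target time series.
//
// Conventions (documented in the package vignette):
//  * forward Euler at dt; at most one spike per neuron per step
//  * static synapses: on a presynaptic spike the synaptic variable jumps
//    by (tau_m / tau_bal) * J and decays with tau_bal, so each spike
//    delivers membrane charge tau_m * J (a PSP of amplitude ~ J, the
//    classical balanced-network normalization; rates entering the balance
//    algebra are in spikes per membrane time constant)
//  * plastic synapses: the filtered presynaptic trace jumps by 1 and
//    decays with tau_plas (time-average = rate * tau_plas, an O(1)
//    regressor for the RLS), and the plastic input jumps by the weight,
//    so a plastic spike delivers charge tau_plas * W
//  * all indices arriving from R are 0-based (converted in the R wrappers)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// reference BLAS symmetric kernels (double precision) used by the RLS
// update; declared directly to stay clear of header linkage clashes
extern "C" {
void dsymv_(const char* uplo, const int* n, const double* alpha,
            const double* a, const int* lda, const double* x,
            const int* incx, const double* beta, double* y,
            const int* incy, size_t uplo_len);
void dsyr_(const char* uplo, const int* n, const double* alpha,
           const double* x, const int* incx, double* a, const int* lda,
           size_t uplo_len);
}

namespace {

struct NetC {
  int N;
  std::vector<char> isE;   // excitatory?
  std::vector<char> istr;  // trained?
  double dt, tau_m, v_thr, v_reset, tau_bal, tau_plas, noise_amp, charge;
  // static weights, CSC over presynaptic columns (post x pre)
  IntegerVector Jp, Ji;
  NumericVector Jx;
  NumericVector X_bal;
  // plastic weights, flat layout: per trained slot s the entries
  // w[w_off[s] .. w_off[s+1]-1] are [recurrent (Lrec), feedforward (LX)]
  IntegerVector trained;   // slot -> neuron id
  IntegerVector w_off;     // nslot + 1
  IntegerVector Lrec;      // per slot
  arma::vec w;             // mutable weight values
  IntegerVector pre_id;    // per entry: presyn neuron (rec) or external unit (ffwd)
  IntegerVector kind;      // per entry: 0 = E-rec, 1 = I-rec, 2 = ffwd
  IntegerVector post_of;   // per entry: postsynaptic neuron id
  // reverse maps: presyn neuron -> flat entries; external unit -> flat entries
  IntegerVector rp, rflat;
  IntegerVector xp, xflat;
  int LX;
};

NetC parse_net(const List& L) {
  NetC n;
  n.N = as<int>(L["N"]);
  LogicalVector ise = L["is_exc"];
  n.isE.assign(n.N, 0);
  for (int i = 0; i < n.N; ++i) n.isE[i] = ise[i] ? 1 : 0;
  n.dt = as<double>(L["dt"]);
  n.tau_m = as<double>(L["tau_m"]);
  n.v_thr = as<double>(L["v_thr"]);
  n.v_reset = as<double>(L["v_reset"]);
  n.tau_bal = as<double>(L["tau_bal"]);
  n.tau_plas = as<double>(L["tau_plas"]);
  n.noise_amp = as<double>(L["noise_amp"]);
  n.charge = as<double>(L["charge"]);
  n.Jp = L["Jp"]; n.Ji = L["Ji"]; n.Jx = L["Jx"];
  n.X_bal = L["X_bal"];
  n.trained = L["trained"];
  n.w_off = L["w_off"];
  n.Lrec = L["Lrec"];
  n.w = as<arma::vec>(L["w"]);
  n.pre_id = L["pre_id"];
  n.kind = L["kind"];
  n.post_of = L["post_of"];
  n.rp = L["rp"]; n.rflat = L["rflat"];
  n.xp = L["xp"]; n.xflat = L["xflat"];
  n.LX = as<int>(L["LX"]);
  n.istr.assign(n.N, 0);
  for (int s = 0; s < n.trained.size(); ++s) n.istr[n.trained[s]] = 1;
  return n;
}

struct RunC {
  int n_burn, n_stim, n_targ;
  double ign_amp, ign_tau;  // decaying burn-in kick out of the silent state
  arma::mat Xstim;     // N x n_stim (may be 0 x 0)
  arma::mat ext_rate;  // LX x n_ms, spikes per ms
  bool rec_traces;
  IntegerVector rec_neur;
  int rec_every;
  bool rec_groups;
  bool rec_spikes;
};

RunC parse_run(const List& L) {
  RunC r;
  r.n_burn = as<int>(L["n_burn"]);
  r.n_stim = as<int>(L["n_stim"]);
  r.n_targ = as<int>(L["n_targ"]);
  r.ign_amp = as<double>(L["ign_amp"]);
  r.ign_tau = as<double>(L["ign_tau"]);
  r.Xstim = as<arma::mat>(L["Xstim"]);
  r.ext_rate = as<arma::mat>(L["ext_rate"]);
  r.rec_traces = as<bool>(L["rec_traces"]);
  r.rec_neur = L["rec_neurons"];
  r.rec_every = as<int>(L["rec_every"]);
  r.rec_groups = as<bool>(L["rec_groups"]);
  r.rec_spikes = as<bool>(L["rec_spikes"]);
  return r;
}

struct Trainer {
  int learn_every, n_upd;
  bool clamp_pre;                // also update toward the baseline pre-target
  double tau_avg;                // EMA window (ms) of the error signal
  const arma::mat* f;            // nslot x n_upd targets at update instants
  const arma::vec* f0;           // nslot baseline inputs clamped pre-target
  std::vector<arma::mat>* P;     // per slot inverse-correlation matrix
  double abs_e_sum;
  long e_count;
  arma::mat u_rec;               // nslot x n_upd total input at update instants
};

// Network state (membrane potentials and synaptic traces); persists across
// training iterations, reset per trial in ordinary simulations.
struct SimState {
  arma::vec v, ubE, ubI, upl, xpl, rpl, rX, utrE, utrI;
  void init(const NetC& net, bool groups) {
    const int N = net.N;
    v.set_size(N);
    for (int i = 0; i < N; ++i)
      v[i] = net.v_reset + unif_rand() * (net.v_thr - net.v_reset);
    ubE.zeros(N); ubI.zeros(N); upl.zeros(N); xpl.zeros(N); rpl.zeros(N);
    rX.zeros(std::max(net.LX, 1));
    if (groups) { utrE.zeros(N); utrI.zeros(N); }
  }
};

// One trial (burn-in + stimulus + target window). If tr != NULL the RLS
// update runs every tr->learn_every steps of the target window.
void run_trial(NetC& net, const RunC& rc, Trainer* tr, SimState& st,
               std::vector<int>& sp_n, std::vector<double>& sp_t,
               arma::cube* traces, arma::mat* msum, int* msteps) {
  const int N = net.N, LX = net.LX;
  const double dt = net.dt;
  const double db = 1.0 - dt / net.tau_bal;
  const double dp = 1.0 - dt / net.tau_plas;
  const double g = dt / net.tau_m;
  // static jump: per-spike membrane charge = charge * tau_m * J
  const double jb = net.charge * net.tau_m / net.tau_bal;
  const double sq = std::sqrt(dt);
  const int n_steps = rc.n_burn + rc.n_stim + rc.n_targ;
  const int n_ms = rc.ext_rate.n_cols;

  // smoothed copies of the quantities entering the RLS error; the fast
  // (tau_bal) noise of the balanced input is unlearnable by the slow
  // plastic traces and only injects variance into the weights
  arma::vec uba, rpla, rXa;
  double ea = 0.0;
  if (tr) {
    ea = dt / tr->tau_avg;
    uba = st.ubE + st.ubI;
    rpla = st.rpl;
    rXa = st.rX;
  }
  arma::vec& v = st.v;
  arma::vec& ubE = st.ubE;
  arma::vec& ubI = st.ubI;
  arma::vec& upl = st.upl;
  arma::vec& xpl = st.xpl;
  arma::vec& rpl = st.rpl;
  arma::vec& rX = st.rX;
  arma::vec& utrE = st.utrE;
  arma::vec& utrI = st.utrI;

  double ign = rc.ign_amp;
  const double ign_dec = rc.ign_tau > 0 ? std::exp(-dt / rc.ign_tau) : 0.0;
  std::vector<int> spiked;
  spiked.reserve(256);
  int rec_t = 0;
  const bool noisy = net.noise_amp > 0;

  for (int t = 0; t < n_steps; ++t) {
    if (t % 5000 == 0) Rcpp::checkUserInterrupt();
    const int t_stim = t - rc.n_burn;
    const int t_targ = t - rc.n_burn - rc.n_stim;
    const bool in_stim = (t_stim >= 0 && t_targ < 0 && rc.Xstim.n_cols > 0);

    // membrane integration and threshold crossing
    spiked.clear();
    for (int i = 0; i < N; ++i) {
      double u = ubE[i] + ubI[i] + upl[i] + xpl[i] + net.X_bal[i];
      if (t_stim < 0) u += ign;
      if (in_stim) u += rc.Xstim(i, t_stim);
      if (noisy) u += net.noise_amp * norm_rand() / sq;
      v[i] += g * (u - v[i]);
      if (v[i] >= net.v_thr) {
        v[i] = net.v_reset;
        spiked.push_back(i);
      }
    }

    if (t_stim < 0) ign *= ign_dec;

    // synaptic decay
    ubE *= db; ubI *= db;
    upl *= dp; xpl *= dp; rpl *= dp;
    if (LX > 0) rX *= dp;
    if (rc.rec_groups) { utrE *= db; utrI *= db; }

    // recurrent spike propagation
    for (size_t si = 0; si < spiked.size(); ++si) {
      const int j = spiked[si];
      const bool je = net.isE[j], jt = net.istr[j];
      for (int k = net.Jp[j]; k < net.Jp[j + 1]; ++k) {
        const int i = net.Ji[k];
        const double a = net.Jx[k] * jb;
        if (je) {
          ubE[i] += a;
          if (rc.rec_groups && jt) utrE[i] += a;
        } else {
          ubI[i] += a;
          if (rc.rec_groups && jt) utrI[i] += a;
        }
      }
      for (int k = net.rp[j]; k < net.rp[j + 1]; ++k) {
        const int fl = net.rflat[k];
        upl[net.post_of[fl]] += net.w[fl];
      }
      rpl[j] += 1.0;
      if (rc.rec_spikes) {
        if (sp_n.size() > (size_t)(0.25 * N * n_steps * dt))
          stop("network runaway: mean rate exceeded 250 Hz "
               "(first at step %d, %.1f ms)", t, t * dt);
        sp_n.push_back(j);
        sp_t.push_back(t * dt);
      }
    }

    // external Poisson units (Bernoulli per step at the given rate)
    if (LX > 0) {
      int ms = (int)(t * dt);
      if (ms >= n_ms) ms = n_ms - 1;
      for (int j = 0; j < LX; ++j) {
        const double pr = rc.ext_rate(j, ms) * dt;
        if (pr > 0 && unif_rand() < pr) {
          rX[j] += 1.0;
          for (int k = net.xp[j]; k < net.xp[j + 1]; ++k) {
            const int fl = net.xflat[k];
            xpl[net.post_of[fl]] += net.w[fl];
          }
        }
      }
    }

    if (tr) {
      uba += ea * (ubE + ubI - uba);
      rpla += ea * (rpl - rpla);
      if (LX > 0) rXa += ea * (rX - rXa);
    }

    // RLS update of plastic weights; before the target window the clamp
    // holds the total synaptic input at the neuron's baseline, so the
    // plant stays controlled throughout training
    if (tr && ((t + 1) % tr->learn_every == 0) &&
        (tr->clamp_pre || t_targ >= 0)) {
      const bool in_targ = t_targ >= 0;
      const int uidx = in_targ ? (t_targ + 1) / tr->learn_every - 1 : -1;
      const int nslot = net.trained.size();
      for (int s = 0; s < nslot; ++s) {
        const int i = net.trained[s];
        const int o = net.w_off[s];
        const int len = net.w_off[s + 1] - o;
        const int Lr = net.Lrec[s];
        arma::vec r(len);
        for (int k = 0; k < Lr; ++k) r[k] = rpla[net.pre_id[o + k]];
        for (int k = Lr; k < len; ++k) r[k] = rXa[net.pre_id[o + k]];
        arma::vec wv(net.w.memptr() + o, len, false, true);
        const double ub = uba[i];
        const double upred = arma::dot(wv, r);
        const double ftar = (uidx >= 0 && uidx < tr->n_upd)
                                ? (*tr->f)(s, uidx)
                                : (*tr->f0)[s];
        const double e = ftar - ub - net.X_bal[i] - upred;
        arma::mat& Ps = (*tr->P)[s];
        // symmetric matrix-vector product and rank-1 downdate through the
        // lower triangle only (dsymv/dsyr): P stays exactly symmetric, no
        // re-symmetrization pass needed
        arma::vec Pr(len);
        const int n_ = len, one_ = 1;
        const double d_one = 1.0, d_zero = 0.0;
        dsymv_("L", &n_, &d_one, Ps.memptr(), &n_, r.memptr(), &one_,
               &d_zero, Pr.memptr(), &one_, 1);
        const double den = 1.0 + arma::dot(r, Pr);
        if (den <= 0 || !std::isfinite(den))
          stop("RLS update lost positive definiteness (neuron %d, step %d)",
               i + 1, t);
        const double mden = -1.0 / den;
        dsyr_("L", &n_, &mden, Pr.memptr(), &one_, Ps.memptr(), &n_, 1);
        wv += (e / den) * Pr;
        // plastic inputs now reflect the new weights
        if (Lr > 0) upl[i] = arma::dot(wv.head(Lr), r.head(Lr));
        if (len > Lr) xpl[i] = arma::dot(wv.tail(len - Lr), r.tail(len - Lr));
        if (uidx >= 0 && uidx < tr->n_upd) {
          tr->abs_e_sum += std::fabs(e);
          tr->e_count += 1;
          tr->u_rec(s, uidx) = ub + net.X_bal[i] + upred;
        }
      }
    }

    // trace recording (1 ms default) and running input means (post burn-in)
    if (rc.rec_traces && (t % rc.rec_every == 0)) {
      for (int q = 0; q < rc.rec_neur.size(); ++q) {
        const int i = rc.rec_neur[q];
        (*traces)(q, rec_t, 0) = ubE[i];
        (*traces)(q, rec_t, 1) = ubI[i];
        (*traces)(q, rec_t, 2) = upl[i];
        (*traces)(q, rec_t, 3) = xpl[i];
        (*traces)(q, rec_t, 4) = in_stim ? rc.Xstim(i, t_stim) : 0.0;
        if (rc.rec_groups) {
          (*traces)(q, rec_t, 5) = utrE[i];
          (*traces)(q, rec_t, 6) = utrI[i];
        }
      }
      ++rec_t;
    }
    if (msum && t >= rc.n_burn) {
      for (int i = 0; i < N; ++i) {
        const double ub = ubE[i] + ubI[i];
        (*msum)(i, 0) += ubE[i];
        (*msum)(i, 1) += ubI[i];
        (*msum)(i, 2) += upl[i];
        (*msum)(i, 3) += xpl[i];
        (*msum)(i, 4) += ub;
        (*msum)(i, 5) += ub * ub;
      }
      ++(*msteps);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List sim_trial_cpp(List net_, List run_) {
  NetC net = parse_net(net_);
  RunC rc = parse_run(run_);
  std::vector<int> sp_n;
  std::vector<double> sp_t;
  sp_n.reserve(1 << 16);
  sp_t.reserve(1 << 16);
  arma::cube traces;
  if (rc.rec_traces) {
    const int nT =
        (rc.n_burn + rc.n_stim + rc.n_targ + rc.rec_every - 1) / rc.rec_every;
    traces.zeros(rc.rec_neur.size(), nT, 7);
  }
  arma::mat msum(net.N, 6, arma::fill::zeros);
  int msteps = 0;
  SimState st;
  st.init(net, rc.rec_groups);
  run_trial(net, rc, nullptr, st, sp_n, sp_t,
            rc.rec_traces ? &traces : nullptr, &msum, &msteps);
  if (msteps > 0) msum /= (double)msteps;
  // convert second moment of u_bal into its standard deviation over time
  for (int i = 0; i < net.N; ++i) {
    double m = msum(i, 4), s2 = msum(i, 5) - m * m;
    msum(i, 5) = s2 > 0 ? std::sqrt(s2) : 0.0;
  }
  List out = List::create(
      _["neuron"] = wrap(sp_n), _["time_ms"] = wrap(sp_t),
      _["mean_inputs"] = wrap(msum));
  if (rc.rec_traces) out["traces"] = wrap(traces);
  return out;
}

// [[Rcpp::export]]
List train_cpp(List net_, List cfg_) {
  NetC net = parse_net(net_);
  const int n_iter = as<int>(cfg_["n_iter"]);
  const int learn_every = as<int>(cfg_["learn_every"]);
  const double tau_avg = as<double>(cfg_["err_avg_ms"]);
  const bool reset_P = as<bool>(cfg_["reset_P"]);
  const bool clamp_pre = as<bool>(cfg_["clamp_pretarget"]);
  const double lambda = as<double>(cfg_["lambda"]);
  const double mu = as<double>(cfg_["mu"]);
  List Xstim_types = cfg_["Xstim"];
  List f_types = cfg_["f_upd"];
  arma::vec f0 = as<arma::vec>(cfg_["f_baseline"]);
  const int n_types = f_types.size();
  RunC rc;
  rc.n_burn = as<int>(cfg_["n_burn"]);
  rc.n_stim = as<int>(cfg_["n_stim"]);
  rc.n_targ = as<int>(cfg_["n_targ"]);
  rc.ext_rate = as<arma::mat>(cfg_["ext_rate"]);
  rc.ign_amp = as<double>(cfg_["ign_amp"]);
  rc.ign_tau = as<double>(cfg_["ign_tau"]);
  rc.rec_traces = false;
  rc.rec_neur = IntegerVector(0);
  rc.rec_every = 10;
  rc.rec_groups = false;
  rc.rec_spikes = false;

  const int nslot = net.trained.size();
  const int n_upd = rc.n_targ / learn_every;

  // P0 = (lambda I + mu sum_a 1_a 1_a')^{-1} in closed form (Woodbury with
  // orthogonal indicator vectors): I/lambda - sum_a mu/(lambda (lambda + mu L_a)) 1_a 1_a'
  std::vector<arma::mat> P(nslot);
  for (int s = 0; s < nslot; ++s) {
    const int o = net.w_off[s];
    const int len = net.w_off[s + 1] - o;
    arma::vec eE(len, arma::fill::zeros), eI(len, arma::fill::zeros);
    for (int k = 0; k < len; ++k) {
      if (net.kind[o + k] == 0) eE[k] = 1.0;
      if (net.kind[o + k] == 1) eI[k] = 1.0;
    }
    const double LE = arma::accu(eE), LI = arma::accu(eI);
    arma::mat P0(len, len, arma::fill::eye);
    P0 /= lambda;
    if (mu > 0) {
      if (LE > 0) P0 -= (mu / (lambda * (lambda + mu * LE))) * (eE * eE.t());
      if (LI > 0) P0 -= (mu / (lambda * (lambda + mu * LI))) * (eI * eI.t());
    }
    P[s] = P0;
  }

  arma::vec mean_abs_e(n_iter, arma::fill::zeros);
  arma::vec mean_corr(n_iter, arma::fill::zeros);
  std::vector<int> sp_n;
  std::vector<double> sp_t;
  bool diverged = false;
  // the network state runs continuously through training: each iteration
  // appends burn-in, stimulus and target window without resetting membrane
  // potentials or synaptic traces, so the plant never free-runs from a
  // random state with partially converged weights
  SimState st;
  st.init(net, false);

  std::vector<arma::mat> P0;
  if (reset_P) P0 = P;
  for (int it = 0; it < n_iter; ++it) {
    if (reset_P && it > 0) P = P0;
    const int ty = it % n_types;
    rc.Xstim = as<arma::mat>(Xstim_types[ty]);
    arma::mat f = as<arma::mat>(f_types[ty]);
    Trainer tr;
    tr.learn_every = learn_every;
    tr.clamp_pre = clamp_pre;
    tr.tau_avg = tau_avg;
    tr.n_upd = n_upd;
    tr.f = &f;
    tr.f0 = &f0;
    tr.P = &P;
    tr.abs_e_sum = 0.0;
    tr.e_count = 0;
    tr.u_rec.zeros(nslot, n_upd);
    sp_n.clear();
    sp_t.clear();
    run_trial(net, rc, &tr, st, sp_n, sp_t, nullptr, nullptr, nullptr);
    mean_abs_e[it] = tr.e_count ? tr.abs_e_sum / tr.e_count : 0.0;
    double csum = 0.0;
    int cn = 0;
    for (int s = 0; s < nslot; ++s) {
      arma::rowvec a = tr.u_rec.row(s), b = f.row(s);
      const double sa = arma::stddev(a), sb = arma::stddev(b);
      if (sa > 0 && sb > 0) {
        csum += arma::as_scalar(arma::cor(a, b));
        ++cn;
      }
    }
    mean_corr[it] = cn ? csum / cn : NA_REAL;
    if (it >= 5 && mean_abs_e[it] > 10.0 * mean_abs_e[it - 5] &&
        mean_abs_e[it - 5] > 0) {
      diverged = true;
      break;
    }
  }

  // aggregate plastic row sums per population (ROWSUM diagnostics)
  arma::mat rowsums(nslot, 2, arma::fill::zeros);
  for (int s = 0; s < nslot; ++s) {
    const int o = net.w_off[s];
    for (int k = o; k < net.w_off[s + 1]; ++k) {
      if (net.kind[k] == 0) rowsums(s, 0) += net.w[k];
      if (net.kind[k] == 1) rowsums(s, 1) += net.w[k];
    }
  }

  return List::create(_["w"] = wrap(net.w), _["mean_abs_e"] = wrap(mean_abs_e),
                      _["mean_corr"] = wrap(mean_corr),
                      _["rowsums"] = wrap(rowsums),
                      _["diverged"] = diverged);
}
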