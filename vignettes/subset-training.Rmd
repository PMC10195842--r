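---
title: "Subset training in balanced spiking networks: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subset training in balanced spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spikespread)
```

## The model

`spikespread` simulates recurrent networks of `N` leaky integrate-and-fire
neurons, half excitatory (E) and half inhibitory (I), coupled by two
superimposed synaptic systems:

* **static synapses** — sparse random connectivity with probability
  `p = K/N` and strong weights `J̄/√K` (positive from E, negative from I).
  With this scaling the summed excitatory and inhibitory inputs each grow
  as `√K`, far beyond the spike threshold, and cancel dynamically: the
  *balanced regime*. The population rates in this regime follow the linear
  balanced equations (`solve_balance()`), which involve only the unscaled
  weights and external drives.
* **plastic synapses** — a much sparser trainable set (about `c·√K`
  synapses per trained neuron, `c` of order one) with slow kinetics
  (`tau_plas = 150` ms vs `tau_bal = 3` ms), disjoint from the static
  support. Only neurons in the selected subset receive them.

The membrane follows `tau_m dv/dt = -v + u + X`, forward-Euler integrated
at `dt = 0.1` ms with threshold 1 and reset 0 and at most one spike per
step (no refractory period). Subset training adjusts the plastic weights
with a per-neuron recursive-least-squares rule so that the *total synaptic
input* of each trained neuron follows a target time series after a brief
stimulus, while the static network — and therefore the balanced-state
statistics — is untouched. Because the plastic input is of the order of
the threshold, it never enters the balanced equations: population mean
rates are essentially unchanged by training, yet single neurons can be
driven to arbitrary smooth patterns. Trained activity then spreads to the
untrained neurons through the static synapses alone; the mean-field module
quantifies this spread.

## Units and the per-spike charge convention

The network equations fix the synaptic kernels but not the per-spike
normalization of the synaptic variable, and the printed parameter tables
are not mutually consistent under any single literal reading: rates of a
few Hz, a log-normal rate distribution, irregular spiking (Fano ≈ 1.4) and
the printed external drive `X = 0.08√K` cannot all be produced by the same
jump convention. `spikespread` therefore makes the convention explicit:

* a static synapse of magnitude `J` delivers per-spike membrane charge
  `charge · tau_m · J` (kernel `exp(-t/tau_bal)`); with `charge = 1` the
  post-synaptic potential amplitude is `J`, the classical normalization of
  balanced-network theory, and the balanced-equation rates are in spikes
  per `tau_m`;
* a plastic synapse of weight `w` delivers charge `tau_plas · w`; its
  filtered presynaptic trace jumps by 1 per spike (time-average
  `rate · tau_plas`), which keeps the RLS regressors of order one at the
  printed regularization `lambda = 0.05`;
* the package default is `charge = 0.45`. At desk scales (N of a few
  thousand) `charge = 1` reproduces the untrained spiking statistics best
  but renders closed-loop RLS training unstable, while small values train
  easily but make spiking too regular. `charge = 0.45` keeps the untrained
  network fluctuation-driven (ISI CV ≈ 0.8–0.9, right-skewed rates around
  5–10 Hz with I above E) while training remains convergent. The
  conversion between internal trace units and Hz uses
  `rate_unit_ms = charge · tau_m` (4.5 ms at the defaults) and appears as an
  explicit argument of the mean-field functions.

Finite desk-scale networks whose external drive alone is below threshold
have a stable silent state alongside the active balanced state; every
trial therefore starts with a brief decaying ignition input during the
burn-in (amplitude 1, time constant 30 ms), gone long before anything is
recorded.

## Training loop

Each trained neuron keeps a private inverse-correlation matrix `P`
(initialized in closed form from the ridge and ROWSUM penalties through
the Woodbury identity) and a weight vector over its plastic synapses. The
online update is the standard rank-1 RLS recursion on the instantaneous
error `e = f - u_bal - X_bal - w·r`; `P` is re-symmetrized after each
update and carries over across iterations. Four loop-level choices, made
after extensive experimentation at reduced network sizes, matter for
convergence and are therefore defaults:

* **continuous state** — training iterations run back-to-back without
  resetting membrane potentials or synaptic traces, so the plant never
  free-runs from a random state under partially converged weights;
* **baseline clamping before the target window** — during burn-in and
  stimulus the update target is the neuron's baseline input (its target
  value at time zero). Without it, the free phases between target windows
  amplify weight noise into network runaway;
* **update cadence** — 2 ms when the whole network is trained (the
  closed loop of a strongly coupled network drifts on the static synaptic
  timescale, 3 ms, so sparser updates lose control of the plant); 5 ms
  suffices for subnetwork-sized trained sets and is much cheaper.
* **initial weights** — Table magnitudes are kept for the excitatory
  entries, while the inhibitory magnitude is rescaled so the expected
  aggregate plastic drive vanishes at the measured untrained rates
  (`rate_balanced_scales()`). At the cortical E/I rate asymmetry the
  printed 2:1 magnitude ratio already has this property; at desk scales
  with more symmetric rates the printed ratio leaves a net-excitatory
  aggregate that the ROWSUM penalty then freezes in place, destabilizing
  the trained network.

The error signal may optionally be low-pass filtered (`err_avg_ms`), but
the default is the instantaneous error: the filter's lag biases the
regression more than the fast noise it removes.

The ROWSUM penalty (`mu = 8`) suppresses drift of each neuron's aggregate
E and I plastic weights relative to unregularized training; the absolute
"fixed aggregate" behaviour of the original large-scale setting is unit-
dependent and is not reproduced quantitatively at desk scale.

## Target generation

* `make_sine_targets()` — random-phase sinusoids `a·sin(2π f t + φ) + b`,
  with `a = 0.5` and the offsets `b` equal to the neurons' untrained mean
  inputs.
* `psth_to_targets()` — firing-rate PSTHs converted to input targets by
  inverting the Ricciardi transfer function of the LIF neuron at the
  population's measured input fluctuation `sigma` (`estimate_sigma()`).
  The integrand is evaluated through the scaled complementary error
  function, with an asymptotic tail beyond its library validity range, and
  inversion uses bracketed root finding (batch conversion uses a monotone
  spline over a dense accurate grid plus the analytic transfer at test
  points). Rates are floored at 0.1 Hz before inversion.
* `make_synthetic_psths()` — a fully parametric stand-in for cortical
  delay-period activity, since no recorded data ship with the package.
  Rates are `r0 + Σ c_n V_n(t)` on a temporal basis built from a linear
  ramp plus smooth bumps tiling the window, orthogonalized in order (all
  modes share similar slow frequency content, as cortical delay-period
  modes are diverse transient shapes rather than ever-faster
  oscillations); baselines are log-normal (mean 4.2 Hz for the
  E-like spec, 11 Hz for the I-like spec, shape 1.0); loadings are
  Gaussian with scale proportional to the baseline rate, so faster neurons
  are more strongly modulated, and the I-like spec carries 1.5× stronger
  modulation. The mode-variance fractions are specified *after* the
  standard smoothing — the basis is constructed so that the smoothed
  profiles are exactly orthonormal and the defaults
  (40, 8, 8, 8, 8, 8, 7, 7, 6)% put 80% of the smoothed centered variance
  in the first six modes with a dominant ramp. (The source statements
  "the ramp carries over 70%", "six components carry 80%" and "nine modes
  carry ≥ 95%" cannot simultaneously hold for any descending spectrum;
  these defaults favour the six-component figure, which is the one the
  trained-network analyses use.) Extreme log-normal-tail rates are
  clipped at 400 Hz before transfer inversion. Lick-right and lick-left sets are drawn
  independently, rank-paired by mean rate, and per-bin Gaussian noise with
  SD equal to the paired rate difference — smoothed by the standard 300 ms
  boxcar — is added to the lick-left member, which injects choice
  selectivity. What the generator deliberately does *not* emulate:
  temporal autocorrelation structure beyond the smooth basis, non-Gaussian
  loading tails, and any session or cell-type covariates of real
  recordings; tests that pass on it therefore certify the machinery, not
  the biology.

## Analyses

PSTHs use 20 ms bins; the 300 ms truncated moving average applies when
converting data-style rate tables to targets (200 ms for display-style
smoothing), while the population-PCA pipeline operates on raw binned
trial averages — its variance fractions therefore mix the structured
activity with the finite-trial noise floor, exactly as the procedure
defines them, and grow with the number of trials. PCA subtracts each
neuron's mean rate and reports variance fractions `λ_k²/Σλ²` of the
singular values,
with each component's sign fixed so its largest-magnitude bin is positive.
Shared variance follows the SVD of the cross-population correlation
matrix. The choice mode normalizes the lick-R minus lick-L difference by
`√N` times its norm (so `‖C‖ = 1/√N`), computed from 1 ms rates filtered
with a 200 ms boxcar and averaged over the last second of the delay;
trials with fewer than 10 recorded neurons are excluded. Recovery times
use per-bin two-sided t-tests without multiple-comparison correction
(matching the source procedure), a session-inclusion rule of ≥ 10%
significant bins inside the perturbation window (default [-1600, -1200] ms
on the delay axis; the printed window "[-1.6, 1.2] s" is inconsistent with
a delay ending at 0 and was read as a typo), and define recovery as the
last significant bin of the contiguous significant run attached to the
perturbation window (single-bin gaps tolerated) at which the smoothed
difference curve changes by less than 10% of its peak per 100 ms — the
printed "derivative smaller than 10 ms" criterion has mismatched units and
this reading is ours. The Fano factor counts spikes over the full target
window by default.

## Mean-field predictions

With the trained activity's centered SVD `δφ = U√λV` (normalized so the
left singular vectors have unit-variance entries, `λ_n = s_n²/M`), the
aggregate static input from `K` random trained partners to an untrained
neuron has per-mode loadings that are Gaussian with mean zero and variance
`J̄²λ_n` — strong coupling (`1/√K` weights) is exactly what keeps this
variance finite as `K` grows, and the weak-coupling (`1/K`) control makes
it vanish. `predict_loading_distribution()` computes the prediction and
compares measured loadings (from group-resolved input recordings) with it;
`selectivity_spread_prediction()` propagates the same argument to the
lick-R/lick-L difference. The weak control keeps the strong network's
adjacency, rescales weights to `J̄/K`, imports each neuron's mean input
from the untrained strong network as a constant, applies the uniform weak
drives (0.35 with factors 1.5/0.8), and injects white noise whose
amplitude is set in closed form so the membrane variance matches the
strong network's measured input fluctuation at `tau_bal`.

## Problem sizes

All shipped analyses run at desk scale: networks of 800–2000 neurons with
per-population in-degrees of 80–400, tens of training iterations at the
2 ms cadence, and tens of trials per condition. These sizes were chosen as
the smallest at which the active balanced state is robust and the spread
analyses are informative; the data structures (sparse static matrices,
flat plastic layout, per-neuron dense `P`) scale to the full-size
networks of the original setting, at correspondingly larger cost. Reduced
size has real physical consequences documented above: stronger finite-K
rate drift across `K`, weaker network chaos (lower Fano factors), and a
narrower margin between trainability and the fluctuation-driven regime —
these, not the algorithms, bound what desk-scale runs can reproduce.

## Known limitations

* The acceptance-grade spiking statistics sit at the edge of their target
  bands at desk scale (trained-network Fano factors land above, and
  untrained ISI CV at, the large-network values).
* Population rates drift with `K` at desk scale, so the `√K` input-growth
  exponent is only approximate for the inhibitory input.
* No conductance synapses, delays, refractoriness or Dale-constrained
  plastic training; plastic weights may change sign.
* NWB/DANDI ingestion is out of scope; `read_psth()` accepts user tables
  in the documented delimited format instead.
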