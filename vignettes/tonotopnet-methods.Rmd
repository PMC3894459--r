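---
title: "Model and methods behind tonotopnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind tonotopnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonotopnet)
```

## The model

`tonotopnet` simulates a tonotopic network of spiking neurons that learns
dynamic spectro-temporal sound features -- FM sweeps, formant transitions --
through delayed lateral connections with bistable spike-driven plasticity.
The architecture follows the neuromorphic auditory models in which sweep
selectivity arises from the interplay of propagation delays and
spike-timing-dependent plasticity (STDP), rather than from a classifier
trained on static spectra.

The frequency axis is divided into `n_channels` tonotopic channels
(32 by default).  Each channel houses three leaky integrate-and-fire (LIF)
neurons:

* **A** -- the input neuron, driven by injected current (synthetic stimuli)
  or by a precomputed spike raster; it stands for the output of an
  artificial cochlea at that place on the frequency axis.
* **B1** -- a relay neuron excited by its channel's A neuron.
* **B2** -- the output neuron, excited by its channel's A neuron and by
  *delayed lateral* projections from the B1 neurons of up to `fan_out`
  (default 14) channels on either side -- never from its own channel.
  These lateral synapses are plastic and are the locus of all learning.

A lateral event from channel $x$ to channel $y$ is delivered after

$$d = d_0 + |x - y|\,\nu$$

where $\nu$ (ms/channel) is the propagation time per channel of separation
and $d_0$ a fixed offset.  Delays are realized exactly by an event queue
(a ring of per-step buckets inside the compiled core), so the delay law
holds to the integration step, unlike analog hardware where such delays
inherit fabrication variability.  Same-channel inhibitory B1 -> B2
projections keep output firing in a sensitive range; because their
anatomical origin is not constrained by the source material we expose the
topology as `inhibition_mode` (`"same"`, `"all"`, `"off"`) and default to
the minimal same-channel reading.

A B2 neuron therefore fires preferentially when delayed lateral excitation
*coincides* with its own channel's feed-forward drive.  A stimulus whose
spectro-temporal correlations match the delay law drives those
coincidences; plasticity converts them into connectivity.

### Neuron model

All populations share one LIF parameter set (`neuron_params()`), integrated
by forward Euler at `dt = 0.1` ms:

$$\tau_m \frac{dv}{dt} = (v_{rest} - v) + R_{in} I$$

with threshold crossing -> spike, reset, and an absolute refractory period.
Potentials are on a normalized scale ($v_{rest} = 0$, $v_{thresh} = 1$);
with $\tau_m = 10$ ms, $R_{in} = 13$ and refractory 1 ms, a unit 5.5 ms
current pulse elicits a 3-spike burst in A -- the burst-coding regime the
lateral coincidence mechanism needs.  The reference neuron constants of the
neuromorphic chips were never published, so these are free parameters of
the software model, chosen once for that qualitative regime.  Synaptic
events are delivered as instantaneous potential jumps (`w_a_b1 = 1.2`
suprathreshold, `w_a_b2 = 0.7` so that B2 needs two near-coincident inputs,
inhibition 0.25, full-efficacy lateral jump `w_plastic_max = 0.3`).

Ties among simultaneous events are resolved in the fixed order
(time, population A < B1 < B2, channel); a postsynaptic spike simultaneous
with a presynaptic arrival is *not* counted as preceding it.

### Plasticity

Lateral efficacies $w \in [0,1]$ follow a bistable spike-driven rule in the
style of binary-synapse STDP models: in the absence of presynaptic events
$w$ drifts toward 0 or 1 depending on which side of the bistability
threshold $w_\theta = 0.5$ it lies (ties drift down, matching the "low"
reset state), and both endpoints are absorbing.  Each B2 neuron carries a
calcium-like trace (jump 1 per spike, $\tau_{ca} = 4$ ms decay) that gates
the jumps triggered by presynaptic arrivals:

* trace $\ge$ 0.5 -- the target fired just before the arrival: potentiate
  by `a_pot` (0.2);
* 0.05 $\le$ trace < 0.5 -- the target fired earlier, i.e. activity in the
  target channel *preceded* the delayed source activity: depress by
  `b_dep` (0.2);
* trace < 0.05 -- quiescent target: no change.

The depression branch penalizes reversed temporal order, the property the
analytical connectivity prediction mirrors with its $-\epsilon$ term.
Drift rates are `5e-4`/ms, slow against single presentations but fast
enough that a quiescent settling period (default 2500 ms, applied in
closed form after exposure) leaves every efficacy at an endpoint.  Inside
the compiled core the drift is evaluated lazily per synapse: between its
events an efficacy cannot cross $w_\theta$, so the piecewise-linear update
is exact.  The chip constants of the original rule are unpublished; all
values here are exposed in `plasticity_params()` and were fixed once
against the canonical two-pulse experiment (below).

### The canonical two-pulse experiment

Two 5.5 ms pulses, channel 5 then channel 9, lag 9 ms.  With
$d_0 + 4\nu = 9$ ms ($\nu = 2$) the delayed activity from channel 5
arrives at B2 of channel 9 exactly as that neuron fires from its own
feed-forward burst; 30 repetitions with learning on followed by quiescent
drift leave the synapse (5, 9) -- and only it -- at $w = 1$.  A mismatched
$\nu$ leaves all efficacies at 0.  This experiment pins the sign
conventions of delays, calcium gating and drift, and the same geometry is
reproduced analytically by `predict_connectivity()`.

## Stimuli

**FM sweeps** (`fm_sweep_current`): a unit current pulse of 5.5 ms in each
channel in turn, onset interval `onset_step_ms`; rate = 1/onset interval
channels/ms; `"down"` reverses the channel axis.

**Noise**: an Ornstein--Uhlenbeck current added to every channel over the
whole stimulus period.  The level $\sigma$ is the ratio of the OU
stationary standard deviation to the (unit) pulse amplitude; the study grid
is $\sigma \in \{0, 0.15, 0.35, 0.45\}$.  The forward-Euler recursion
$x_{n+1} = x_n(1 - \theta\,\Delta t) + \sigma_w \sqrt{\Delta t}\,\xi_n$
is calibrated to the *discrete-time* stationary variance
$\sigma_w^2 \Delta t / (1 - (1-\theta \Delta t)^2)$, so long-path sample
standard deviations recover $\sigma$ without Euler bias.  The
mean-reversion time constant (5 ms) is not stated in the source material;
it was chosen comparable to the pulse duration so the noise is neither
white nor quasi-DC, and is exposed in `noise_spec()`.

**Formant-track words** (`synth_formant_patterns`): the speech-derived
32 x 25 binary patterns (10 ms bins, 250 ms words) of the original
experiments are not deposited, so the package generates a synthetic
stand-in: 7 classes x 3 exemplars, each class defined by two smooth
"formant" channel trajectories with a distinct dynamic shape (rising,
falling, converging, diverging, steady close, steady wide, rise--fall).
Classes are localized in the (channel, separation) plane the way vowels
are localized in formant space, and all within-class separations stay
within the lateral reach of the network (fan-out x delay window) --
a class whose formant spacing exceeds that reach would be unlearnable by
construction.  Exemplars are channel-jittered copies (offset + tilt,
s.d. `jitter = 0.75` channels), emulating within-class variability of
repeated utterances.  What the generator does *not* emulate: consonant
segments and silent gaps inside words, amplitude variation (patterns are
binary), or correlations between jitter and class -- so passing tests show
robustness of the learning mechanism to channel jitter, additive noise and
time warping, not performance on real speech.

**Sentences** (`build_sentence`): gapless random concatenations with equal
class counts.  Presentation rate (60/100/150/200% of the normal 4 words/s)
is varied by nearest-neighbour column resampling to
$T' = \max(1, \lfloor T \cdot 100 / \text{rate} + 0.5\rfloor)$ bins --
round-half-up, preserving binarity; the warping mechanism used originally
is unspecified.

## Exposure/probe protocol

A trial (`trial_config`, `run_exposure`, `run_probe`) has two phases:

1. **Exposure**: plastic efficacies reset to the low state; the exposure
   stimulus is presented with learning on (reference designs: 30
   repetitions for FM sweeps, 20 word repetitions for formant classes),
   then efficacies settle to their endpoints.
2. **Probe**: learning off; probe stimuli presented in seeded random
   order (100 reps/stimulus FM, 50 formant in the reference designs) and
   the total B2 spike count recorded per presentation.

Design choices the source material leaves open, fixed here: probe noise is
applied to probe stimuli only (exposure is the clean formative pattern);
in gapless sentences membrane state persists across words and spikes are
attributed to the word whose bins span the spike time, with no latency
correction; FM probes are presented from resting state.  All randomness
(word order, exemplar draws, noise paths) flows from explicit seeds; the
simulation core itself is deterministic, so identical configurations
reproduce rasters and response tables bit-identically.

## Acuity metrics

From a labeled response table the package estimates, over the observed
integer spike-count support with a uniform class prior (optional Laplace
pseudo-count, default 0 -- the original estimator is unstated), the
conditionals $p(r|\Theta)$ and posterior $p(\Theta|r)$, and computes

$$i_{sp}(r) = -\sum_\Theta p(\Theta)\log_2 p(\Theta)
             + \sum_\Theta p(\Theta|r)\log_2 p(\Theta|r), \qquad
  i_{SSI}(\Theta) = \sum_r p(r|\Theta)\, i_{sp}(r)$$

with the $0\log 0 = 0$ convention.  For $K$ equiprobable classes both are
bounded by $\log_2 K$ (3.32 bits for 10 classes, 2.80 for 7), attained
exactly when responses are class-diagnostic; the test suite verifies both
bounds and agreement with a hand-written oracle to $10^{-12}$.

Treating the exposure class as a detection target (higher count = more
target-like) yields an ROC curve over all integer thresholds and its
trapezoid AUC.  The textbook definitions TPR = TP/(TP+FN),
FPR = FP/(FP+TN) are used; the trapezoid AUC over tie blocks equals the
Mann--Whitney statistic $U/(n_1 n_2)$ with half credit for ties, which the
tests verify exactly.

## Analytical connectivity prediction

For an arbitrary activity matrix $A_{x,t}$ the expected post-exposure
connectivity is the lag-specific correlation

$$C(x,y) = \sum_t \left[A_{x,t}A_{y,t+\Delta t+\epsilon}
                       - A_{x,t}A_{y,t+\Delta t-\epsilon}\right],
  \qquad \Delta t = |x-y|\,\nu$$

(the $d_0$ offset of the simulated network can be included; it defaults to
0, the bare operator).  Lags are rounded to the nearest column -- results
therefore depend on the column width -- and out-of-range indices contribute
zero.  Negative values are kept signed internally (the depression branch)
and clipped at zero for rendering, since efficacies cannot go below 0.
$\epsilon$ defaults to one column.  The vectorized implementation
accumulates lagged cross-products per channel distance and is tested for
exact equality against a naive triple loop.

Sweeping $\nu$ (`sweep_nu`) probes correlations at increasing time scales.
On a train of descending chirps, a small $\nu$ matched to the within-chirp
slope concentrates mass below the diagonal of $C$ (down-sweep learning),
while $\nu$ matched to the inter-chirp interval produces the apparent
up-sweep between the low-frequency end of one chirp and the body of the
next (mass above the diagonal).  The deposited audio behind the original
seal-call illustration is unavailable, so a deterministic synthetic
chirp-train fixture reproduces the two regimes qualitatively.

## Cochlear front end

For real audio, `cochleagram()` applies a linear 4th-order gammatone
filterbank (Glasberg--Moore bandwidths, truncated impulse responses
normalized to unit gain at the center frequency) at `n` frequencies equally
spaced on the ERB-number scale between 50 and 8000 Hz, then half-wave
rectification, a 1 kHz low-pass (a stand-in for the phase-locking limit of
auditory-nerve firing; the original cutoff is unstated) and 1 ms frame
averaging.  `activity_to_pattern()` thresholds the result into the binary
pipeline.  A minimal PCM WAV reader is included.  The front end is
deliberately linear -- no adaptation or compression.

## Problem sizes and numerical checks

The test and acceptance experiments run scaled versions of the reference
designs, chosen so the whole suite completes in about a minute: the FM
direction-selectivity experiment uses an 8-channel network, 30 exposure
repetitions and 20 probes per direction; the formant robustness experiment
uses the full 32-channel network, 20 exposure repetitions and 16 probe
occurrences per class over 3 pattern seeds; OU calibration uses a 100 s
path.  Bistability is asserted to $10^{-6}$; the information and
connectivity oracles to $10^{-12}$ and exact equality respectively.

## Known limitations

* The hardware neuron/synapse constants being unpublished, absolute spike
  counts and AUC values are not comparable to the original tables; only
  the qualitative phenomena (direction selectivity, graceful degradation
  with noise and rate, prediction regimes) are reproduced.
* Discriminability depends on the exposure class: classes whose formant
  geometry barely engages the lateral delay structure learn fewer synapses
  and separate less -- mirroring the class-to-class spread in the original
  results.
* The connectivity operator samples exactly two lags per channel pair; for
  sparse activity it is sensitive to column-width rounding.
* No real-time guarantee, no hardware (AER) interface, no LPC analysis of
  recorded speech.
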