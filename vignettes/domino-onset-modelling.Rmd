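---
title: "Modelling domino-like seizure onset on bistable node networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling domino-like seizure onset on bistable node networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dominonet)
```

## The problem

Generalized seizures recorded on multichannel EEG do not start everywhere
at once.  Ordering electrodes by the time at which seizure activity is
first detected reveals *domino-like* recruitment: sometimes all channels
join within a fraction of a second (fast domino), sometimes the cascade
takes seconds (slow domino), and sometimes one or more large gaps split
the channels into distinct sub-cascades (multi domino).  The same
phenomenology appears at the micro scale in mouse medial entorhinal
cortex (mEC) slices, where seizure-like events sweep from the ventral to
the dorsal end of a 16-electrode probe over tens of seconds.

`dominonet` implements the full analysis chain for this phenomenon:
onset detection, pattern classification, data-driven estimation of
coupling and excitability, a mechanistic stochastic network model, and
quantitative model–data comparison.

## Onset detection

Each channel is band-pass filtered, z-normalised over the epoch and
rectified.  An envelope is interpolated (cubic spline) through local
maxima at least `np` samples apart, and the onset is the first time the
processed signal exceeds `mean(envelope) + s * sd(envelope)`.  Two
presets carry the published parameters:

| preset | band (Hz) | `np` (samples) | `s` |
|--------|-----------|----------------|-----|
| `eeg`  | 4–20      | 60             | 0.6 |
| `mec`  | 15–35     | 22000          | 1   |

Decisions the algorithm description leaves open, fixed here:

* **Filter realisation** — 4th-order Butterworth applied
  forward–backward (zero-phase), so filtering does not bias onset times.
* **Peak retention** — strict local maxima; conflicts under the minimum
  separation are resolved greedily by descending height.
* **Envelope edges** — the spline is clamped to the first/last retained
  peak value outside the knot span, avoiding extrapolation overshoot.
* **Onset granularity** — the sample-exact index of the first crossing,
  reported in seconds; channels without a crossing carry an `NA`
  sentinel, never an in-band numeric value.

A robustness scan (in the test suite) confirms that the classification
of a synthetic multi-domino epoch is unchanged for `s` between 0.4 and
0.8 at `np = 60`.

Two caveats the detector inherits from its definition.  First, the
threshold is *relative*: in a pure-noise channel the largest excursion
still exceeds `mean + 0.6 sd` of the envelope, so the detector reports
an (uninformative) onset — epochs must be screened for genuine events
upstream, exactly as in clinical practice.  Second, when an oscillation
occupies the majority of an epoch the envelope statistics are dominated
by the seizure itself and the threshold climbs to the oscillation
amplitude; detection then hangs on noise peaks.  Both behaviours shaped
the synthetic generator below.

## Pattern classification

From detected onsets `recruitment_pattern()` computes recruitment times
$t_n = \tau_n - \min_n \tau_n$, the total recruitment time $r =
\max_n t_n$ and the maximum lag $l$ (largest gap between consecutive
ordered recruitment times).  The seed rule (`initial_grouping()`) uses
the thresholds 0.5 s on $r$ and 0.4 s on $l$; the production classifier
(`classify_domino()`) uses the published linear discriminant boundaries

$$L_1 = 2.9644 - 1.5236\,r - 16.5419\,l, \qquad
  L_2 = 31.0766 + 2.301\,r - 97.5312\,l.$$

The decision rule checks $L_2$ first ($L_2 < 0$ is multi — multi is
defined by the lag feature, so it takes precedence), then $L_1 < 0$ is
slow, else fast.  The sign orientation is anchored by unambiguous
exemplars of each class (small $(r,l)$ fast; large $r$, small $l$ slow;
large $l$ multi); ties on a boundary fall to the fast side.
`fit_lda_boundaries()` refits both pairwise discriminants with equal
class priors (group sizes in a seed set are incidental); if a batch
lacks one class entirely the published default line for that pair is
retained.

## The network model

Each electrode is a bistable node

$$f(z;\nu) = (-\nu + i\omega)\,z + 2 z |z|^2 - z |z|^4, \qquad z \in
\mathbb{C},$$

a truncated Hopf (Bautin) normal form.  The origin (background) is
stable for $\nu > 0$; a stable limit cycle (seizure state) of radius
$r^2 = 1 + \sqrt{1-\nu}$ coexists with it for $0 < \nu < 1$, separated
by an unstable cycle at $r^2 = 1 - \sqrt{1-\nu}$.  The bistable range is
bounded by a subcritical Hopf bifurcation at $\nu = 0$ and a saddle-node
of limit cycles at $\nu = 1$ (`bifurcation_points()` locates both by
root finding).  $\nu$ is the *node excitability*: near 0 the smallest
noise kicks the node into the seizure state, near 1 the node is robust.
Escape does not depend on the oscillation phase, so $\omega = 0$
throughout.

Nodes are coupled diffusively through a weighted adjacency matrix $A$
with global scale $\beta$ and driven by additive noise:

$$dz_n = \Big[f(z_n;\nu_n) + \beta \sum_m A_{n,m}(z_m - z_n)\Big]dt +
\alpha\, dW_n .$$

Parameters and their defaults:

* $\alpha = 0.05$ — noise amplitude, fixed throughout.
* $\xi = 0.5$ — escape threshold on $|z_n|$; for the working $\nu$
  range it sits between the unstable and stable cycle radii.
* $h = 10^{-3}$ — step of the stochastic Heun integrator
  (predictor–corrector; the deterministic drift is evaluated twice, the
  same Wiener increment is added once per step).
* $K = 1000$ — ensemble size; every realization starts at $z_n = 0$.
* **Noise convention** — $W_n$ is complex with independent real and
  imaginary standard Wiener components (each increment
  $\mathcal N(0, h)$, multiplied by $\alpha$).  The alternative
  normalisation (total unit variance) halves the noise power; with the
  study's $\nu$ range that inflates mean escape times by factors of
  $e^6$–$e^9$, incompatible with finite ensembles — so the
  per-component convention is the only workable reading.  A
  real-component-only mode remains selectable for comparison.

Threshold crossings are resolved at step granularity ($h = 10^{-3}$
makes sub-step interpolation irrelevant next to noise-driven
variability).  A realization whose state exceeds $|z| = 10$ is aborted
and flagged (never observed at the study parameters).

### Chains, gradients, severed chains

For the mEC geometry the network is a bidirectional nearest-neighbour
chain (`chain_adjacency()`): node 1 ventral, node 16 dorsal.  Dorso-
ventral heterogeneity enters either as a linear excitability gradient
$\nu_n = \nu^0 + (n-1)\delta\nu$ or a linear coupling gradient
$A_{n,n+1} = A_{n+1,n} = A^0 + (n-1)\delta A$, and the anatomical
separation experiment zeroes the weights between nodes 8 and 9.

### Numerical and performance choices

The integrator is written in C++ (Rcpp).  Randomness comes from a
counter-based xoshiro256++ generator with ziggurat normal draws, seeded
per (seed, realization index), so ensembles are bit-reproducible and
realizations are independent streams regardless of execution order.
The generator's output is itself under test (moments, KS against the
normal), and the whole integrator is validated distributionally against
an independent Euler–Maruyama reference at a finer step.

Two stopping modes: `all_escape` integrates to the default horizon
`t_max = 5000` (censored realizations are excluded from mean
recruitment times but counted in diagnostics), while `first_escape`
halts at the first crossing of any node — sufficient for initiation
statistics ($P_V$) and orders of magnitude cheaper.  The acceptance
script runs its first-passage ensembles with a horizon of 2500 time
units: the first-crossing node is asymptotically independent of the
crossing time (escape hazards become stationary after a short
transient), so censoring does not bias $P_V$ while bounding the cost of
the slowest (homogeneous $\nu = 0.2$) ensembles, whose mean first
escape sits near 1500 time units.

## Estimating model inputs from data

**Coupling** (`association_index()`, `association_matrix()`): the
nonlinear association index $h^2$ is a correlation ratio — the fraction
of the target channel's variance explained by a piecewise-linear
regression on the source channel, estimated from per-bin means over
`n_bins = 10` equal-width amplitude bins (configurable; zero lag).  It
is directional, lives in $[0,1]$, and captures nonmonotone dependence
that linear correlation misses (a purely quadratic relation scores
$h^2 > 0.9$ with near-zero correlation).  The whole-epoch matrix serves
as the weighted adjacency of the EEG-style model.  `pearson_dissimilarity()`
(one minus the Pearson correlation of off-diagonal entries — the
diagonal is structurally zero) quantifies interval stability of these
matrices; on synthetic epochs the sub-interval containing the event is
closest to the whole-epoch matrix, mirroring the published protocol.

**Excitability** (`energy_profile()`, `excitability_profile()`): channel
energy is accumulated over 1-s windows with 50% overlap (half-open
$[t, t+1)$ so overlapping windows never double-count the shared
endpoint), on the raw signal by default (a band-passed variant is a
switch).  The profile is scaled affinely to $[0.1, 0.2]$ per epoch
across channels and mapped to $\nu_n = 0.3 - \hat E_n$: the
highest-energy channel becomes the most excitable node.

## Model–data comparison

Simulated recruitment times are averaged over realizations and scaled
by their maximum ($\max \hat T_n = 1$); data are scaled the same way.
The least-squares distance $d$ is the plain sum of squared differences
of the scaled curves — this reproduces the published magnitudes
($d \approx 2.5$ for a 16-node homogeneous mismatch, $d < 0.2$ for good
fits), so no square root is taken.  Two matching modes: EEG-style
comparisons sort the curves (electrodes unlabelled), mEC-style
comparisons are position-matched along the chain.

`grouped_distance()` implements the grouped protocol: 1000 realizations
split into 20 groups of 50, per-group node means ordered (within the
group, by default; a global-ordering switch exists), scaled and compared
to the sorted data; the median of the 20 distances is reported with a
seeded percentile-bootstrap 95% CI (10 000 resamples).
`compare_distance_sets()` is the two-sided Mann–Whitney U test on two
sets of distances.  `parameter_sweep()` maps $d$ and $P_V$ over a
$(\nu^0, \delta\nu)$ or $(A^0, \delta A)$ grid and extracts iso-contours
(default $d = 0.2$) by marching squares.

## Synthetic data: what it does and does not emulate

The generator exists so the pipeline can be exercised end to end with
known ground truth.  `make_onset_times()` produces onset geometries that
realise a prescribed domino class by construction (validated against the
0.5 s / 0.4 s thresholds before jitter).  `synthesize_recording()`
renders each channel as unit-variance band-limited Gaussian background
plus a mid-band sinusoid of relative amplitude `snr` starting at the
prescribed onset, with a 50-ms linear ramp so the ground-truth onset
stays sharp, and lasting `burst_duration` seconds (default 40% of the
epoch).  Finite bursts matter: a discharge sustained to the end of the
epoch drives the envelope threshold up to the oscillation amplitude
(see the detection caveats), which is an artifact of the
constant-amplitude surrogate — real discharges terminate.  The mEC
fixture (`make_mec_fixture()`) uses 100-s epochs at 2 kHz with the
20-s ventral-to-dorsal cascade starting 35 s in and 25-s bursts, tuned
so the published mEC preset detects every channel.

What the surrogates deliberately omit: 1/f spectra, artifacts,
amplitude drift, channel cross-talk, and any biophysics.  Passing
round-trip tests therefore demonstrates correctness of the algorithmic
chain, not clinical detection performance.  A second usage mode renders
recordings from simulator trajectories ($|z_n|$ as amplitude
modulation) for integration tests, but ground-truth-critical tests use
the sinusoid surrogate precisely so the generator is independent of the
simulator under test.

## Worked example

A small end-to-end run (sizes reduced to keep the vignette light):

```{r example}
set.seed(1)
# synthesize a slow-domino epoch and recover its class
ot <- make_onset_times("slow", n_channels = 19, jitter = 0.05, seed = 2)
rec <- synthesize_recording(ot$tau, fs = 256, duration = 15,
                            band = c(4, 20), snr = 8, seed = 3)
det <- detect_recording(rec, detection_preset("eeg"))
pat <- recruitment_pattern(det)
c(r = pat$r, l = pat$l, class = classify_domino(pat$r, pat$l))
```

```{r example-sim}
# a 16-node chain with the red-star excitability gradient
spec <- network_spec(chain_adjacency(16, 0.1),
                     excitability_gradient(16, 0.14, 0.002))
ens <- simulate_ensemble(spec, sim_config(K = 100, t_max = 1000,
                                          seed = 4,
                                          stop_mode = "first_escape"))
summarize_ensemble(ens, ventral = 1:8)$P_V
```

## Reproduced quantities and known limitations

The test suite reproduces, at desk scale: the bifurcation structure of
the node model (exact); the symmetry of homogeneous chains ($P_V = 0.5$
within binomial error); the ventral concentration of initiation under
excitability and coupling gradients at the published red-star
parameters; the slower-domino effect of steeper excitability gradients;
and the recruitment lag between nodes 8 and 9 of a severed chain.

Known limitations:

* The excitability-gradient red star reproduces $P_V \approx 0.74$
  (SE $\approx 0.014$ at $K = 1000$) against a published map value of
  $\approx 0.86$; the published criterion band (95% CI of the
  experimental estimate, roughly $[0.72, 0.93]$) contains the value,
  but the point estimates differ.  The coupling-gradient red star
  reproduces $\approx 0.87$.
* Clinical-data results (event counts, per-seizure fit errors
  $d = 0.29$–$0.64$, robustness percentages) require the private
  recordings and are out of scope; the corresponding machinery is
  exercised on synthetic data only.
* Connectivity is static (whole-epoch); no time-resolved coupling, no
  surrogate-based significance testing of $h^2$, no source-space
  analysis.
* Network topologies beyond dense and chain, phase-dependent coupling,
  and seizure-to-background return transitions are out of scope.
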