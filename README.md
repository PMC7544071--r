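# dominonet

Tools for characterising and mechanistically modelling **domino-like
seizure-onset patterns** in multichannel electrophysiology — for
epilepsy researchers working with scalp-EEG epochs of generalized
seizures and for slice electrophysiologists studying seizure-like
cascades in mouse medial entorhinal cortex (mEC).

Seizure onset is rarely simultaneous across channels.  Ordering
electrodes by the time seizure activity is first detected yields a
recruitment pattern summarised by two numbers: the total recruitment
time `r = max(t_n)` and the maximum lag `l` (largest gap between
consecutive ordered recruitment times).  These separate three onset
classes — *fast domino* (small `r`, small `l`), *slow domino* (large
`r`, small `l`) and *multi domino* (one or more lags ≥ 0.4 s splitting
the channels into sub-cascades).

The mechanistic core is a stochastic network of bistable nodes.  Each
node follows a truncated Hopf (Bautin) normal form

    dz_n = [ (-nu_n + i w) z_n + 2 z_n |z_n|^2 - z_n |z_n|^4
             + beta * sum_m A[n,m] (z_m - z_n) ] dt + alpha dW_n

which is bistable for excitability `0 < nu < 1` (stable background
equilibrium plus stable seizure limit cycle, bounded by a subcritical
Hopf bifurcation at `nu = 0` and a saddle-node of limit cycles at
`nu = 1`).  Noise drives escapes from background to seizure; diffusive
coupling propagates them.  Escape times over `K` realizations give mean
recruitment curves and the ventral-initiation proportion `P_V`, which
are compared quantitatively against data via a least-squares distance
`d` with a grouped bootstrap protocol and Mann–Whitney tests.

The package covers the full chain:

* **Detection** — band-pass, z-normalise, rectify; spline envelope over
  separated maxima; onset at the first crossing of
  `mean(env) + s * sd(env)`.  Published presets: EEG (4–20 Hz, np = 60,
  s = 0.6) and mEC (15–35 Hz, np = 22000, s = 1).
* **Classification** — published linear-discriminant boundaries in the
  `(r, l)` plane, the 0.5 s / 0.4 s seed thresholds, and refitting.
* **Model inputs from data** — directional nonlinear association index
  h² as functional coupling; windowed signal energy mapped to node
  excitability `nu = 0.3 - E_hat`.
* **Simulation** — fast Rcpp stochastic-Heun ensembles (h = 1e-3,
  alpha = 0.05, xi = 0.5), chain/gradient/severed-chain constructors,
  escape-time extraction and summaries.
* **Comparison** — scaled recruitment curves, grouped distance with
  bootstrap CI, parameter sweeps with d / P_V maps and contours.
* **Synthetic data** — surrogate EEG/mEC recordings with prescribed
  onset geometry and class, for validation without clinical data.

## Worked example

```r
library(dominonet)

# 1. synthesize a slow-domino epoch with known onsets, detect, classify
ot  <- make_onset_times("slow", n_channels = 19, jitter = 0.05, seed = 2)
rec <- synthesize_recording(ot$tau, fs = 256, duration = 15,
                            band = c(4, 20), snr = 8, seed = 3)
det <- detect_recording(rec, detection_preset("eeg"))
pat <- recruitment_pattern(det)
c(r = pat$r, l = pat$l)
#>         r         l
#> 1.4726562 0.1523438
classify_domino(pat$r, pat$l)
#> [1] "slow"
```

The epoch was generated with a 1.5-s recruitment spread; detection
recovers `r ≈ 1.47` s with no large lag, and the published discriminant
boundaries assign it to the slow-domino class, matching the ground
truth.

```r
# 2. the 16-node mEC chain with the red-star excitability gradient
spec <- network_spec(chain_adjacency(16, 0.1),
                     excitability_gradient(16, 0.14, 0.002))
ens  <- simulate_ensemble(spec, sim_config(K = 200, t_max = 1500, seed = 4,
                                           stop_mode = "first_escape"))
summarize_ensemble(ens, ventral = 1:8)$P_V
#> [1] 0.77
```

With a linear dorso-ventral excitability gradient (`nu` rising from
0.14 ventrally to 0.17 dorsally, uniform coupling 0.1), roughly three
quarters of the simulated seizure-like events initiate in the ventral
half of the chain — the symmetric homogeneous chain gives 0.5.

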