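---
title: "Methods: microstates, complexity, and reinforcement-learning classification of sleep EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microstates, complexity, and reinforcement-learning classification of sleep EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(somnirl)
```

This vignette documents the models implemented in `somnirl`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic generator does and does not emulate, and the numerical
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. Signal conditioning

Recordings are channels × samples matrices in microvolts
(`eeg_recording`). Conditioning follows the conventional order: broadband
zero-phase Butterworth band-pass (default 0.5–70 Hz, order 4 per pass, so
an 8th-order magnitude response after the forward–backward pass), a mains
notch (default 50 Hz, quality 30, i.e. a ~1.7 Hz stop band), and
re-referencing (linked mastoids when A1/A2 are present, common average
otherwise — simulated montages carry no mastoid channels). Epochs are
non-overlapping 2 s windows by default; trailing samples that do not fill
an epoch are dropped.

Numerical notes, all visible in `R/filters.R`:

* Band-pass filters are designed analytically as cascaded second-order
  sections (analog Butterworth prototype → band transform → bilinear
  mapping with prewarping). The expanded polynomial form of an 8th-order
  band-pass whose corners sit far below Nyquist (0.5 Hz at fs = 250) has
  poles clustered near `z = 1` and loses its stop band to rounding; biquads
  do not. The notch is a 4th-degree band-stop, which is well conditioned,
  and is taken from `signal::butter`.
* Zero-phase filtering pads each channel by odd reflection, continued by a
  constant level when the settling time of the slowest pole (decay to
  1e-6) exceeds the signal length, and every filter stage starts from the
  steady state for a constant input equal to the first padded sample.
  Without these two details the 0.5 Hz high-pass edge rings for seconds
  into the data. Residual edge transients are unavoidable for narrow low
  bands on short signals: stop-band attenuation should be assessed away
  from the edges (the tests measure RMS amplitude over the middle half of
  12 s signals).
* The channel mean (DC) is removed before band-pass filtering; DC lies in
  the stop band, so this changes nothing in exact arithmetic but avoids
  exciting the slow transient with the recording's offset.

Band conventions: delta 0.5–4, theta 4–7, alpha 8–12, beta 13–30, gamma
30–70 Hz. The gamma lower edge is a package convention (the literature
varies); its upper edge matches the broadband filter.

The sampling rate is configurable everywhere and defaults to 250 Hz.
Nothing in the method depends on the exact rate beyond Nyquist headroom
for the gamma band.

## 2. Welch spectra

`welch_psd()` averages modified periodograms: segments of length `M`
(default: the whole epoch, so one periodogram per 2 s epoch and the
averaging in `average_psd()` runs across epochs), a Hamming taper with
power normalization `U = mean(w²)`, no overlap by default, one-sided
density with the factor-2 correction off DC and Nyquist. The estimator
satisfies Parseval (the integrated density equals the variance of white
noise, checked by simulation) and scales quadratically with amplitude.
`band_power()` integrates the density trapezoidally, so contiguous bands
add exactly.

## 3. Microstate segmentation

Global field power is the spatial standard deviation across electrodes at
each sample. Candidate topographies are taken at GFP peaks (strict local
maxima, greedily thinned to a minimum separation, default 10 ms in the
pipeline), where topographic signal-to-noise is maximal.

The modified k-means is polarity-invariant: maps are average-referenced
and unit-normalized, assignment maximizes the *squared* spatial
correlation, and each prototype is updated as the dominant right singular
vector of its assigned maps (the direction maximizing explained squared
correlation, indifferent to sign). Conventions:

* Restarts: `n_init = 10` seeded restarts, best kept by GEV; `max_iter =
  500`; convergence when assignments stabilize or the relative GEV change
  falls below 1e-6.
* Ties in the assignment argmax go to the lowest prototype index
  (deterministic).
* Empty clusters are re-seeded from the worst-fitted map rather than
  crashing.
* Prototype sign is fixed by making the largest-magnitude entry positive,
  so refitting a globally negated recording returns bit-identical
  prototypes — the whole pipeline is invariant under a global sign flip,
  which the acceptance suite checks end to end.

Model selection fits every K in 4..10 and keeps the maximal GEV; the full
GEV-versus-K table is retained. GEV rises monotonically with K on rich
data, so the maximum often sits at the top of the range; callers who want
the canonical four classes pin `k = 4`, which is what the end-to-end
pipeline does (one recording's GFP peaks rarely justify ten stable
classes, and the generator produces four). Prototypes are fitted per
recording; pooling maps across recordings before fitting is possible by
concatenation but is not the default, since inter-subject topography
alignment is its own problem.

Backfitting assigns every sample (not just peaks) to the best prototype by
squared correlation, then absorbs segments shorter than `min_duration_ms`
(default 20 ms) into whichever neighbouring state correlates better with
the segment's samples, shortest segments first. Temporal parameters follow
the standard definitions: mean segment duration (ms), occurrence
(segments/s), coverage (sample fraction; sums to 1), mean GFP while
active, and the segment-level transition matrix (self-transitions
structurally zero; rows of states with no outgoing transition stay zero).
A state that never occurs yields zeros, with a message, rather than an
error — grids of epochs should not abort because one epoch missed a state.

## 4. Lempel–Ziv complexity

Per channel: the analytic signal (frequency-domain Hilbert transform; the
real part is the input exactly), its amplitude envelope, binarization at
the envelope median, and the Lempel–Ziv (1976) exhaustive-history parse,
implemented in C++ (Kaspar–Schuster scan) and cross-checked in the tests
against an independently written brute-force parser. The classic sequence
`0001101001000101` parses into 6 components. Counts are normalized as
`c · log2(n) / n`, which approaches 1 for maximally irregular sequences.

Two deterministic conventions: ties at the median map to 0, and values
within square-root machine precision (relative to the signal scale) of
the median count as ties — a pure tone's envelope is constant to 1e-15
and would otherwise binarize floating-point noise into a spuriously
complex string. Binarizing after the analytic amplitude is invariant to
positive rescaling of the input.

The pairing of complexity with microstate features follows the
"parameter + per-channel LZC" construction: `build_features()`
concatenates one temporal parameter (K values, state order) with the C
per-channel LZC values (channel order), e.g. `"mean_gfp+lzc"`. The
alternative reading — complexity of a parameter's own time course — is
not the default because per-epoch parameter sequences are far too short
to parse meaningfully. In the pipeline the LZC is computed on the
broadband conditioned epoch by default (`lzc_band = NULL`); the clinical
convention of extracting it from the delta band is one argument away
(`lzc_band = "delta"`). On synthetic data the complexity contrast lives
in the broadband mixture (see the generator section below), which is why the harness default
differs from the clinical one.

## 5. Statistics

`ks_normality()` is the one-sample Kolmogorov–Smirnov test against a
normal with the sample's own mean and SD (plug-in parameters, labeled as
such; p-values are approximate in the Lilliefors sense).
`mann_whitney_u()` uses midranks; for `n1 + n2 ≤ 20` the two-sided p is
computed by exact enumeration of all group assignments (ties included),
otherwise by the normal approximation with tie correction and a 0.5
continuity correction — the tests verify exact agreement with a
brute-force pairwise-counting oracle for all `n1 + n2 ≤ 10` and type-I
calibration within [0.03, 0.07] at α = 0.05 over 2000 null replicates.
Effect size is η² = z²/n, clipped to [0, 1]. `significance_mask()`
thresholds at α or α/m (Bonferroni).

## 6. The attention agent

One episode classifies one epoch. The observation is the epoch's GFP
amplitude sequence; the static feature vector (microstate parameters and
LZC, z-scored across the dataset) is appended to the encoded glimpse at
every step, so the agent sees global synchronization dynamics and local
summaries at once.

Per step `t`: a multi-scale glimpse at location `l_{t-1}` ∈ [−1, 1]
(windows of `base_length · scale_factor^{k-1}` samples, block-averaged to
`base_length`, zero-padded outside the sequence — fine resolution at the
centre, coarse peripherally); a two-layer 1-D conv encoder with mean
pooling (or a dense layer in the conv-free variant); a linear combiner
over (features, location, statics) with ReLU and dropout; a GRU update
(or a stateless tanh layer in `cnn_rl`); then three linear heads — a
tanh location mean, a softmax action distribution, and a scalar value
baseline. Hidden states stay in (−1, 1) by construction.

Training follows REINFORCE with a baseline. The reward is `r_t = 1` when
the step's action matches the label, the return-to-go is
`G_t = Σ_{t'≥t} γ^{t'-t} r_{t'}`, and one Adam ascent step per batch is
taken on

    (1/M) Σ_i Σ_t ∇ log π(l_t, a_t | s_1:t) · (G_t − b(s_t)),

where the location and action log-probabilities add (the combined action
is the pair), the advantage is treated as a constant, and the value head
is regressed to `G_t` by squared error with its gradient confined to the
head. All parameter groups — glimpse encoder, combiner, core, location
head, action head — are updated through the policy-gradient term; the
location head is part of the optimized set even though it is sometimes
omitted from parameter lists in the literature, because its distribution
is what the estimator differentiates.

Open choices and their resolutions:

* Location policy: isotropic Gaussian with fixed σ = 0.1 (normalized
  units), clipped to [−1, 1]; the canonical choice for continuous glimpse
  locations. The log-density gradient is evaluated at the clipped sample.
* Per-step reward rather than terminal-only, because the return is a
  discounted sum over steps; the final step's action is the episode's
  prediction.
* ε-greedy exploration applies to the class action only, never to
  locations (which have their own Gaussian exploration), decaying linearly
  from 1.0 to 0.1 over the first 1000 episodes.
* Defaults follow the reference protocol: Adam at 0.001, γ = 0.9, batch
  128, up to 500 epochs, dropout 0.2 on the glimpse feature layer. Network
  sizes are package assumptions, config-exposed: T = 6 glimpses, 3 scales
  of 16 samples (factor 2), conv channels 8 and 16 (kernels 5 and 3), GRU
  hidden size 128, glimpse feature width 64.
* Gradients are clipped to a global norm of 5 before the Adam step — a
  standard stabilizer for recurrent policy gradients; without it the
  policy can collapse mid-training, and although early stopping (patience
  20 on validation reward, best-validation policy returned) would still
  rescue the result, clipped runs are markedly steadier.
* Updates replay recorded trajectories (locations, actions, dropout
  masks) through the current parameters, so `reinforce_update()` is a
  pure, deterministic function of its inputs — checked bit-for-bit in the
  tests.
* Evaluation is deterministic: mean locations, argmax actions. Per-class
  one-vs-rest ACC/PPV/NPV with zero-denominator cases reported as `NA`.

Correctness of the estimator is established two ways: on an enumerable
two-location/two-class toy, the trajectory-averaged estimator equals the
finite-difference gradient of the expected return to ~1e-10 relative
error (`pg_gradient_check()`); and the full BPTT path through conv, GRU,
and heads matches finite differences of the replayed objective on random
parameter coordinates.

The experiment harnesses retrain per condition: `channel_subset_experiment()`
over montage subsets of sizes 19/13/12/10/7/2 (frontal/central emphasis at
intermediate sizes) and `window_length_experiment()` over epoch lengths
1–40 s. Cross-validation variants (repeats × folds) reduce to repeated
calls with different `seed`s.

## 7. The synthetic generator

`make_dataset()` emulates a 19-channel 10–20 study with four conditions.
Prototype topographies are zero-mean, unit-norm random maps with pairwise
|correlation| ≤ 0.5 (rejection sampling; an impossible cap raises an error
naming it). Microstate labels follow a semi-Markov chain: truncated-normal
dwell times (90 ± 20 ms, floored at 20 ms — the middle of the 60–120 ms
quasi-stability range) and uniform off-diagonal segment transitions. Each
state's source signal mixes unit-variance band-limited noise components
weighted by the condition's band gains, blended with broadband noise
according to `complexity_knob` (the fraction of unfiltered noise — a
monotone handle on Lempel–Ziv complexity), amplitude-modulated mildly per
segment, gated by the label sequence, multiplied by the active prototype,
and topped with white sensor noise.

Condition defaults encode the qualitative physiology the analysis expects:
alpha maximal in EO (gain 3.0) and highest there across conditions; delta
dominant in EC (1.8); delta and alpha elevated under REM-with-stimuli
(2.0 / 0.9) relative to EC and reduced once stimuli stop (0.6 / 0.45);
complexity ordered EC (0.05) < EO (0.10) < REM_nostim (0.15) < REM_stim
(0.22). The gain contrasts are deliberately strong: gating a narrowband
source on and off every ~90 ms convolves its spectrum with the gate's
(±~11 Hz main lobe), and with mild contrasts the leakage into wide high
bands would overturn the nominal band ordering. With these defaults each
condition's largest-gain band carries the largest integrated Welch band
power, which the test suite checks state by state.

What the generator does *not* emulate: volume-conducted biophysics (maps
are statistical, not dipolar), eye/muscle artifacts, 1/f background
spectra, sleep spindles and K-complexes, inter-subject variability, or
stage transitions within a recording. Passing tests therefore demonstrate
the correctness and internal consistency of the implementation and its
sensitivity to the encoded contrasts — not clinical performance on real
polysomnography.

## 8. Problem sizes in tests and acceptance runs

The suite is sized for a single CPU: the microstate-recovery property uses
one 10 s recording; complexity-monotonicity uses five knob levels × 20
matched seeds of 4 s recordings; the separable burst task trains 150
sequences per class at default hyperparameters; the order-memory
architecture contrast runs five seeds at reduced sizes (hidden 48, 40
epochs, batch 64); the end-to-end study uses 5 recordings × 60 s per
condition (600 two-second epochs) with `k = 4`, 5 clustering restarts, 10
glimpses over 4 scales, and at most 150 training epochs with early
stopping. These are the package's chosen study sizes; all scale up by
argument.

## 9. Known limitations

* Microstate prototypes are fitted per recording; group-level two-stage
  clustering is out of scope.
* The EDF writer/reader covers continuous 16-bit EDF with one sampling
  rate; EDF+ annotations and mixed-rate signals are not supported.
* REINFORCE remains a high-variance estimator; different seeds can move
  held-out accuracy by several points on small synthetic studies, and the
  reported end-to-end accuracy should be read with that variance in mind.
* The agent trains on CPU-sized problems; there is no GPU path.
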