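# somnirl

Sleep-state analysis from multichannel scalp EEG: microstate segmentation,
Lempel–Ziv complexity, and an attention-glimpse CNN+GRU classifier trained
by policy-gradient reinforcement learning.

## The problem

Wakefulness, NREM sleep, and REM sleep (with or without concurrent auditory
stimulation) leave distinct signatures in the EEG: band power shifts between
delta, theta, and alpha rhythms; the sequence of quasi-stable scalp
topographies ("microstates", ~60–120 ms each) reorganizes; and the
irregularity of the signal, measured by Lempel–Ziv complexity, rises and
falls with cognitive engagement. `somnirl` implements the full analysis
chain that turns raw recordings into a four-state classification
(eyes-open wake **EO**, eyes-closed/NREM onset **EC**, REM with stimuli
**REM_stim**, REM without stimuli **REM_nostim**), plus a seeded synthetic
EEG generator so every stage can be validated against known ground truth —
useful because clinical sleep recordings are rarely shareable.

## The methods

- **Conditioning** — zero-phase Butterworth band-pass (0.5–70 Hz, cascaded
  second-order sections), mains notch, linked-mastoid or common-average
  re-referencing, non-overlapping 2 s epochs.
- **Spectra** — Welch's averaged modified periodogram
  `PSD(f) = (1/L) Σ_i |Σ_n x_i(n) w(n) e^{-j2πfn/M}|² / (M U fs)` with
  `U = mean(w²)`, and trapezoidal band power per channel.
- **Microstates** — global field power
  `GFP_t = sqrt(Σ_i (x_it − x̄_t)²/N)`; topographies at GFP peaks are
  clustered by polarity-invariant modified k-means (assignment by maximal
  squared spatial correlation, prototypes as dominant spatial
  eigenvectors), the class count K ∈ 4..10 chosen by maximal global
  explained variance (GEV, the GFP²-weighted mean squared correlation);
  backfitting labels every sample and yields per-state duration,
  occurrence, coverage, mean GFP, and the segment transition matrix.
- **Complexity** — per channel, the Hilbert analytic amplitude is
  binarized at its median and parsed by the Lempel–Ziv (1976)
  exhaustive-history rule; counts are normalized by `n / log2(n)`.
- **Statistics** — Kolmogorov–Smirnov normality screening, Mann–Whitney U
  (exact enumeration for small samples, tie-corrected normal approximation
  otherwise) with η² = z²/n effect sizes, and Bonferroni-aware
  significance masks.
- **Classifier** — a recurrent attention agent: a multi-scale glimpse
  sensor reads short windows of the epoch's GFP sequence at an agent-chosen
  location, a small 1-D CNN encodes them, a GRU integrates across glimpses
  (static microstate + LZC features are appended at each step), and
  location/action heads are trained by REINFORCE with a learned value
  baseline (reward 1 per correctly classified step, discounted return
  `R = Σ_t γ^{t-1} r_t`), ε-greedy exploration, Adam, dropout, and early
  stopping. Per-class accuracy, PPV, and NPV are reported one-vs-rest.

## Worked example

```r
library(somnirl)

topo <- make_topographies(4, montage_10_20(), corr_cap = 0.5, seed = 42)
spec <- default_state_specs()[["EC"]]
rec  <- simulate_recording(topo, spec, duration_s = 30, fs = 250, seed = 42)
rec
#> <eeg_recording> 19 channels x 7500 samples @ 250 Hz (30.0 s)
#>   state: EC

clean <- preprocess(rec)                       # 0.5-70 Hz, notch, avg ref
g     <- gfp(clean)
peaks <- gfp_peaks(g, min_separation_ms = 10)  # 1179 peaks
model <- fit_microstates(t(clean$data[, peaks]), k = 4, n_init = 10,
                         seed = 1, gfp_values = g$values[peaks])
model
#> <microstate_model> K = 4, GEV = 0.9792 (10 restarts, seed 1)

labels <- backfit(model, clean)
temporal_parameters(labels, g)
#> <microstate_features>
#>  state duration_ms occurrence_per_s  coverage mean_gfp
#>      1    78.71845         3.433333 0.2702667 1.582236
#>      2    73.30612         3.266667 0.2394667 1.638876
#>      3    75.40909         2.933333 0.2212000 1.599430
#>      4    80.72000         3.333333 0.2690667 1.761335
```

The fitted prototypes explain 97.9% of the GFP²-weighted topographic
variance, and the recovered mean durations (73–81 ms) match the
generator's 90 ± 20 ms dwell distribution after backfit smoothing. The
delta band dominates this eyes-closed recording, as designed:

```r
psd <- welch_psd(clean$data, 250, spectral_config(segment_length = 500))
round(sapply(default_bands(), function(b) mean(band_power(psd, b))), 2)
#> delta theta alpha  beta gamma
#>  1.55  0.89  0.62  0.50  0.16
```

Training the classifier end to end on a balanced synthetic study:

```r
res <- run_end_to_end(n_per_state = 5, duration_s = 60,
                      cfg = train_config(epochs = 150, n_glimpses = 10,
                                         glimpse = glimpse_config(4, 16, 2),
                                         seed = 2024),
                      seed = 2024)
res$report$accuracy      # held-out accuracy over 4 states (chance 0.25)
```

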