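# csibreathe

Contactless respiratory monitoring from Wi-Fi channel state information
(CSI). When a person breathes near a Wi-Fi link, the moving chest wall
modulates the delay of a reflected propagation path; the interference
between that moving reflection and the static multipath pattern leaves a
periodic signature in the complex per-subcarrier channel estimates a
MIMO-OFDM receiver already computes. `csibreathe` implements the full
pipeline around that effect for people building or evaluating CSI-based
vital-sign sensors:

* a **physics-based simulator** of breathing-modulated CSI tensors
  (`[n_rx, n_tx, n_subcarriers, n_frames]`) over a 5280 MHz, 56-subcarrier
  802.11n-style link, with a catalog of nine respiratory patterns
  (3–30 breaths/min, tidal volumes 171–705 mL), added path attenuation
  against a fixed noise floor, and an emulated receiver AGC;
* **spectral preprocessing**: per-stream FFT, band-limited log-power
  features, zero-mean/unit-variance standardization, optional Hampel
  despiking;
* a **bidirectional LSTM classifier** (sequence input → BiLSTM → fully
  connected → softmax; 50 hidden units/direction, Adam at learning rate
  0.01, batch 64) with a reproducible RcppArmadillo training core;
* **evaluation**: confusion matrices (rows = predicted, columns = true),
  per-class and macro precision/recall/specificity/F1, stratified k-fold
  cross-validation with dispersion and 95 % intervals;
* **characterization studies**: dataset recipes for the 9-pattern,
  normal-vs-abnormal, 28-rate and 3-band tasks, and sweeps over added
  attenuation, acquisition length and frame rate, plus a free-space
  link budget (`fspl_db()`, `attenuation_to_distance()`) mapping
  attenuation to equivalent transmitter–receiver distance.

The model in one line: each CSI entry is
`h(f,t) = Σ_ℓ ξ_ℓ exp(−j2πf τ_ℓ(t))` with one path's delay modulated by
the round-trip chest displacement `τ(t) = τ₀ + 2d(t)/c`; classification
treats the stream-to-label mapping as an unknown nonlinear function
learned end-to-end with cross-entropy.

## Worked example

Simulate one acquisition for three patterns, preprocess, and
cross-validate the classifier:

```r
library(csibreathe)

# distances the link budget assigns to added attenuation
round(fspl_db(attenuation_to_distance(c(0, 10, 20, 30)), 5.28e9))
#> [1] 54 64 74 84

# simulate one acquisition per pattern (8 subcarriers, 60 s at 10 Hz)
tensors <- lapply(c(2, 4, 6), function(id) {
  simulate_csi(breathing_pattern(id),
               channel_config(n_subcarriers = 8),
               noise_config(seed = 100 + id),
               label = sprintf("pattern-%d", id))
})
tensors[[1]]
#> csi_tensor: 3 rx x 2 tx x 8 subcarriers x 600 frames (label pattern-2)

# spectral preprocessing: band-limited log-power features per stream
ds <- build_dataset(tensors, feature_mode = "spectrum")
ds
#> csi_dataset: 144 sequences, 3 classes, mode 'spectrum'
#>   sequence shape: 62 steps x 1 channels

# 2-fold cross-validated BiLSTM
cv <- kfold_cross_validate(ds, k = 2, seed = 1,
                           cfg = net_config(max_epochs = 30, patience = 8))
cv
#> 2-fold CV: accuracy 1.0000 +/- 0.0000 (min 1.0000, max 1.0000)
#>   binomial 95% CI (0.9747, 1.0000); fold-mean 95% CI (1.0000, 1.0000)
cm_metrics(cv$pooled)
#> accuracy 1.0000 (n = 144)
#> macro: precision 1.0000  recall 1.0000  specificity 1.0000  f1 1.0000
```

Each of the 144 sequences is one CSI stream (one antenna pair ×
subcarrier) of the 60 s acquisition; at the clean operating point the
three patterns — 6, 18 and 15 breaths/min with distinct waveform shapes
— separate perfectly. Accuracy degrades with added attenuation and
shorter acquisitions; `run_sweep()` quantifies both:

```r
run_sweep(experiment_spec("pattern-9", "attenuation_db",
                          c(0, 10, 20, 30), seed = 1))
```

A command-line interface over the same functions is installed at
`exec/csibreathe` (subcommands `simulate`, `preprocess`, `train`,
`evaluate`, `sweep`, `fixtures`).

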