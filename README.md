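# eegclean

Automated artifact removal for multichannel EEG, built for researchers who
need scalp recordings cleaned of physiological contamination — cardiac
(ECG), muscular (EMG), ocular (EOG), eye-blink, and broadband noise —
without hand-inspecting every component. The package implements a complete,
self-contained chain:

1. **SOBI** (second-order blind identification): sources are estimated from
   the model `X(t) = A S(t)` by whitening and joint approximate
   diagonalization of time-lagged covariance matrices
   `R(q) = (1/(T−q)) Σ_t X̄(t) X̄ᵀ(t−q)`, `q = 1…100`.
2. **Angle-plot features**: each source is embedded in the plane with a time
   delay, and the signed turning angles
   `θ_i = atan2(u×w, u·w)` between consecutive trajectory chords are
   summarized by 12 features (moments, median, a Shannon functional
   `−Σ θ² ln θ²`, series length, and crossing counts of five Poincaré
   sections: both axes, both diagonals, and an r = 0.001 circle).
3. **Ensemble classification**: t-test feature screening (p < 0.05), then a
   majority vote of MLP (one hidden layer, 10 units), KNN (K = 20) and
   Gaussian naive Bayes — optionally plus a degree-3 polynomial SVM whose
   vote breaks four-member ties — labels each source neural or artifactual
   (or one of six classes), evaluated by stratified 10-fold
   cross-validation.
4. **SWT suppression**: flagged sources are decomposed by a 5-level
   stationary Haar transform; detail bands are soft-thresholded at the
   universal threshold `σ̂ √(2 ln n)`, `σ̂ = median(|d₁|)/0.6745`; the
   reconstructed artifact-only signal is subtracted and the channels are
   rebuilt through the mixing matrix.
5. **Metrics**: RRMSE in time and spectrum, mean absolute spectral error,
   average correlation, average mutual information, and the truncated-band
   trade-off `PSD_tr` = (4–30 Hz change) / (1–4 Hz change + >30 Hz change).

A fully specified simulator (19 channels, 256 Hz, four-sinusoid 4–30 Hz EEG
segments, five artifact models, random sparse channel projections, exact
linear-SNR mixing `X_C = X_P + λ X_ART`) provides ground truth for every
experiment; no external recordings are needed.

## Worked example

```r
library(eegclean)

## a 10-s contaminated scene with known ground truth
sc  <- build_scene(sim_config(duration = 10, snr = 0.5, seed = 77))
dec <- sobi(eeg_recording(sc$contaminated, sc$fs))
dec
#> <sobi> 19 sources x 2560 samples @ 256 Hz
#> lags: 1..100 (C = 100); joint diagonalization converged in 46 sweep(s)

table(label_sources(dec, sc))
#>         EEG         ECG         EMG         EOG       blink white_noise
#>          14           1           1           1           1           1

## train a detector on an independent corpus and clean the scene
corp <- simulate_component_corpus(n_scenes = 8, duration = 10,
                                  snr_range = c(0.1, 0.3), seed = 90)
mdl  <- train_ensemble(corp$features, corp$binary, seed = 91)
res  <- run_pipeline(sc, mdl)
res$metrics
#> <metrics_report>
#>   rrmse_time  1.0598
#>   rrmse_psd   0.7930
#>   rrmae_psd   0.0189
#>   acc_corr    0.7502
#>   ami_bits    1.0071
#>   psd_tr      0.0641
rrmse_time(sc$pure, sc$contaminated)   # before cleaning
#> [1] 2
```

Contamination at SNR 0.5 doubles the signal's RMS error budget (RRMSE 2
against the pure EEG); after detection and wavelet suppression the cleaned
channels sit at RRMSE 1.06 with average correlation 0.75 to the pure EEG,
and the trade-off score 0.064 shows the spectral change concentrated
almost entirely in the artifact bands (1–4 Hz and above 30 Hz) rather than
the 4–30 Hz brain band.

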