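# chctools

Analysis toolkit for two-photon calcium imaging of **chandelier cells
(ChCs)** and pyramidal cells in mouse primary visual cortex. ChCs are
axo-axonic interneurons that innervate pyramidal-cell axon initial
segments; characterizing what drives them requires a pipeline spanning
passive grating sessions, natural-image encoding models, virtual-tunnel
visuomotor behaviour and chemogenetic silencing. `chctools` implements
that pipeline as a tested R package for systems neuroscientists
analysing such recordings — or building and validating the same
statistics on synthetic data with known ground truth.

## What it computes

* **Preprocessing** — neuropil correction (`F − 0.7·Fneu`), ΔF/F with a
  moving 10th-percentile baseline over 5000-frame windows,
  event-triggered tensors, baseline correction, z-scoring.
* **Grating tuning** — response amplitudes (0.2–1.2 s window), running
  trial exclusion, circular-Gaussian fits

  `R(θ) = C + Rp·exp(−ang_ori(θ−θ_pref)² / 2σ²)`

  (single Gaussian for orientation; a double Gaussian with a second peak
  `Rn` at θ_pref+180° for direction), and tuning strength as
  `1−CircVar = |Σ R(θk)e^{2iθk}| / Σ|R(θk)|` (angle doubling for
  orientation).
* **Encoding model** — a factorized readout on a pluggable convolutional
  feature extractor: `ŷ_n = [Σ Ws(n) ∗ X_l] ∗ Wf(n)`, trained jointly
  with Adam under Laplacian-smoothness (Ws), L1 (Wf) and L2 penalties;
  oracle and cross-validated correlations; most-exciting-input (MEI)
  synthesis by gradient ascent on pixels; in-silico orientation/SF/
  contrast probes and Gaussian receptive-field size.
* **Population statistics** — lifetime sparseness, pairwise and
  behavioural correlations, shrinkage-LDA image decoding with repeated
  stratified splits and a subsample permutation test.
* **Virtual tunnel** — 2-cm position binning, Ward clustering with
  silhouette model selection, Bhattacharyya-distance cluster
  separability (`BD = −ln Σ√(P_i·Q_i)`) with a permutation null,
  location-corrected visuomotor mismatch responses, locomotion-onset
  detection, visual-flow onset responses.
* **Chemogenetic silencing** — locomotion-modulation curves and linear
  fits, the locomotion modulation index
  `LMI = (ΔF/F_run − ΔF/F_stat)/(ΔF/F_run + ΔF/F_stat)`, a per-neuron
  circular-shift permutation test for pre/post changes, and χ² group
  comparisons of modulated fractions.
* **Synthetic sessions** — seeded generators for passive, image, tunnel
  and chemogenetic sessions with known ground truth, used throughout the
  test suite for parameter recovery and calibration.

## Worked example

Simulate a passive grating session, preprocess it, and fit direction
tuning for one neuron:

```r
library(chctools)

gt      <- make_ground_truth(n_chc = 4, n_pyc = 20, seed = 1)
passive <- make_passive_session(gt, n_trials_per_direction = 10,
                                noise_sd = 0.1, seed = 2)

dff  <- session_dff(passive$session)            # neuropil + moving-percentile dFF
keep <- exclude_running_trials(passive$events, passive$session$speed,
                               passive$session$frame_rate)
gr   <- grating_response(dff, passive$events[keep, ],
                         passive$session$frame_rate)

curve <- tapply(gr$amplitude[, 1], gr$direction, mean)
fit_direction(as.numeric(curve), as.numeric(names(curve)))
#> <tuning_fit> C=0.0971 Rp=1.01 Rn=0.284 theta_pref=244 sigma=33.6
#>              sse=0.000541 dsi=0.356 fit_ok=TRUE
```

49 of 80 trials survive the running filter, and the fitted preferred
direction (244°) recovers the generating value (242.5°) to within 2°;
`Rp` is the peak amplitude in ΔF/F units, `Rn` the opposite-direction
peak, `sigma` the tuning width in degrees, and `dsi` the 1−CircVar
direction selectivity. The same session shows the arousal signature
that distinguishes the cell types:

```r
r_run <- behavior_correlation(dff, passive$session$speed)
mean(r_run[passive$session$cell_type == "ChC"])   #> 0.93
mean(r_run[passive$session$cell_type == "PyC"])   #> 0.25
```

The vignette (`vignettes/chctools-methods.Rmd`) documents every model,
parameter and numerical choice, including known limitations of the
permutation procedures.

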