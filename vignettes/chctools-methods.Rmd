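---
title: "Models and methods in chctools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in chctools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chctools)
```

`chctools` implements the computational pipeline for two-photon calcium
recordings of chandelier cells (ChCs) and pyramidal cells (PyCs) in mouse
primary visual cortex: trace preprocessing, grating tuning, an image
encoding model with most-exciting-input (MEI) synthesis, population
statistics, virtual-tunnel analyses and chemogenetic-silencing
statistics. This vignette explains the models, the tunable parameters,
the numerical choices, and what the synthetic-data generator does and
does not emulate.

## Preprocessing

Raw ROI fluorescence is neuropil-corrected as `F - 0.7 * Fneu` and
converted to dFF with a moving baseline: the 10th percentile over a
5000-frame window, centred on the current frame and truncated at the
session edges. The window alignment is a design choice (the convention
is not universal); a centred window avoids biasing stimulus onsets that
follow long quiet periods. Percentiles use linear (type-7)
interpolation. For long sessions the baseline is evaluated every
`window/100` frames and linearly interpolated, since a 5000-frame
percentile drifts on a far slower timescale; `step = 1` recovers the
exact per-frame sliding percentile and is what the unit tests verify
against a brute-force oracle.

Time is handled in frames internally; windows in seconds are converted
with round-half-up. Frame indices are 0-based in event tables, matching
the convention of acquisition software; the first frame at or after a
physical event carries that event.

## Grating tuning

Responses are baseline-corrected means over 0.2-1.2 s after stimulus
onset; trials with running speed above 1 cm/s anywhere from 1 s before
to 4 s after onset are excluded, and only contrasts above 0.7 enter
tuning. Mean responses at the 8 directions are fit with a single
circular Gaussian (orientation; angular differences wrapped to 0-90
degrees) or a double circular Gaussian with a second peak opposite the
preferred direction (direction; wrapped to 0-180 degrees). Fitting is
nonlinear least squares with a multi-start over the 8 stimulus
directions for the preferred angle, sigma bounded to [5, 90] degrees so
the width stays identifiable, followed by a Levenberg-Marquardt polish
that drives well-conditioned fits to machine precision.

Two caveats are worth stating. First, 8 directions provide only 4
distinct orientation samples, so the single Gaussian's 4 parameters are
exactly determined only while the curve is narrow; beyond roughly
sigma = 30 degrees alternative exact solutions appear and no fitting
method can promise recovery. Parameter-recovery guarantees in the test
suite therefore cover widths of 18-28 degrees, the typical V1 regime.
Second, tuning strength (1-CircVar) normalizes responses to their
maximum and, by design choice, rectifies negative means at zero: the
statistic is only interpretable on [0, 1], and negative lobes would
otherwise make the numerator ill-defined. Rectification is configurable
(`rectify = FALSE`).

## The factorized readout encoding model

Each neuron's predicted response to an image is

    yhat_n = [ sum_xy Ws(n) * X_l ] . Wf(n)

where `X_l` are batch-normalized activations of a convolutional feature
extractor, `Ws(n)` is a 2-D spatial map over feature-map positions and
`Wf(n)` a vector over channels. The loss is squared error plus a
Laplacian smoothness penalty on `Ws` (3x3 kernel, zero-padded),
an L1 penalty on `Wf` and an L2 penalty on both; all neurons are
optimized jointly with Adam (default 600 epochs, batch size 128,
learning rate decaying by 3 at epochs 200 and 400, best-validation
snapshot returned). The published description of the schedule is
ambiguous ("early stopping (every 200 epochs, decay factor = 3)"); both
the step-decay reading (default) and a schedule-free mode are
implemented.

The extractor is an injected dependency. The bundled default is a
deterministic Gabor bank: 8 orientations x 2 phases at one spatial
frequency, 11 px kernels, stride 2, followed by a ReLU. The
rectification matters for more than realism: with a purely linear bank,
responses depend on the image only through the single equivalent
pixel-domain filter, so the (Ws, Wf) factorization is unidentifiable
from any stimulus set and ground-truth weight recovery is impossible in
principle. The rectified bank removes that collapse; simulated recovery
of generating spatial maps then reaches median r near 0.98 at the noise
levels used in the tests. The factorization always retains a per-neuron
global sign symmetry (flip both `Ws` and `Wf`), so recovery is assessed
after sign alignment through `Wf`.

Hyperparameters are selected by exhaustive grid search; following the
original selection rule the default scores candidates on the training
set, with validation-based selection available (`select = "val"`), since
train-set selection is only safe when the grid varies regularization
strength alone.

MEIs are synthesized by Adam ascent on the pixels (learning rate 1e-2,
weight decay 1e-3, 50 steps), maximizing one neuron's response or the
summed response of a set (composite MEI). A squared-Laplacian penalty
(weight 1e-3) discourages high-frequency artefacts and a random integer
jitter of up to 2 px per step is the bundled stochastic transformation;
rotation and scaling transformations are not applied by default because
their published magnitudes are unspecified and nearest-neighbour
resampling would break the exactness of the gradient. Pixels are
clipped to [-1, 1]. With the jitter disabled, ascent is monotone, which
the tests assert.

In-silico probes present full-field sinusoidal gratings: orientation
(8 orientations, 5 SFs 0.02-0.08 cpd, 2 phases; OSI computed on
max-over-SF/phase responses), spatial frequency (12 SFs, preference =
argmax), and contrast (7 contrasts at each neuron's best
orientation/SF/phase; sensitivity = least-squares slope). Pixel size is
calibrated by `deg_per_pixel` (default 2 degrees/pixel, i.e. a 64-degree
32-px canvas, matching the synthetic geometry); receptive-field size is
the FWHM of a 2-D Gaussian fit to `Ws`, `2 sqrt(2 ln 2)` times the
geometric mean of the axis SDs, with fields above 40 degrees flagged
excluded and fits explaining under half the map variance flagged failed.

## Population statistics

Lifetime sparseness follows the standard two-moment form on [0, 1]; it
is applied as printed even to signed (baseline-corrected) responses,
with a warning when the summed response is negative. Decoding uses LDA
with repeated stratified 80/20 splits (50 runs). Because the paper
decodes 34-40 neurons from 320 training trials and subsamples can be
worse-conditioned, the pooled within-class covariance is shrunk toward
a scaled identity with an analytic (Ledoit-Wolf-style) intensity; plain
LDA is the limiting case when shrinkage tends to zero. The subsample
permutation test compares a small focal population against
size-matched random subsets of a reference population (default 1000
iterations); the p-value is one-tailed by default (focal below
reference), uses the (k+1)/(n+1) correction, and the tail is
configurable because the published description does not state it.

## Virtual tunnel

Trials slower than 15 s to reward and, for profile analyses, trials
containing mismatch events are excluded. Activity is averaged in 50
position bins of 2 cm, then over trials. The visual-response score is
the mean between 20 and 80 cm minus the mean over 0-20 cm. PyCs are
clustered by Ward linkage on z-scored profiles with k chosen by mean
silhouette over k = 2..6; silhouette cannot test k = 1, which is why
cluster separability is additionally tested with the Bhattacharyya
distance `BD = -ln sum_i sqrt(P_i Q_i)` between the two clusters'
score histograms on shared edges. The bin count uses the
Freedman-Diaconis rule on the pooled scores (the published bin count is
unstated; FD is scale-free and deterministic). Zero-count bins
contribute zero, disjoint supports give BD = Inf and compare as larger
than any finite value, and the permutation null shuffles neurons
between clusters with cluster sizes held fixed (1000 shuffles).

Mismatch responses are corrected for tunnel position: for each mismatch
event, control trials are resampled 100 times at the same 2-cm position
bin, the average control trace subtracted, and the corrected trace
baseline-corrected and averaged over 0.2-1.2 s. Locomotion onsets are
frames whose preceding 0.5 s averages below 5 cm/s and following 2 s
above it (first frame per bout); because both conditions are window
averages, the detected frame sits where the forward average crosses the
threshold, slightly before a hard speed step. Visual-flow onset
responses average 0.5-2 s after trial onset (the first 20 cm of the
tunnel carry no stimuli), and closed-loop mismatch events are compared
with open-loop flow halts only when onset speed lies in 5-30 cm/s.

## Chemogenetic silencing

Locomotion-modulation curves average activity in speed bins with an
exact-zero stationary bin, half-open (lo, hi] running bins up to
20 cm/s, and faster frames dropped. The locomotion modulation index is
`(run - stat) / (run + stat)` with a 1 cm/s threshold; note the curve's
first running bin (0-5 cm/s) intentionally includes frames between 0
and 1 cm/s that the LMI counts as stationary, mirroring the two
different thresholds in the source analyses.

The per-neuron silencing test averages activity in 30-frame (~2 s)
bins, builds a null of within-pre-session half-mean differences over
all circular shifts of the split point, and compares it against the
pre-vs-post first-half difference. The published text computes the
observed statistic as the average of inter-session differences over the
same shifts with a re-randomized post start (the default,
`observed = "averaged"`); a single-comparison reading is available
(`observed = "single"`). The test is two-tailed with the (k+1)/(n+1)
correction.

**Limitation.** The circular-shift null draws are not independent: the
half-mean difference is a smooth (square-wave-convolution) function of
the shift, concentrated in the lowest Fourier modes of the binned
trace, leaving the null roughly 3-5 effective degrees of freedom
however long the session. Its spread therefore varies strongly between
sessions and the resulting p-values are not uniform under the null:
the bulk is conservative and the extreme tail inflated (about 4x at
p = 0.01 in iid-bin simulations), although the type-I rate at
alpha = 0.05 for the averaged statistic stays near nominal. The
calibration suite demonstrates exactly this: the 5% rejection band
passes while a Kolmogorov-Smirnov uniformity check fails. Neurons
whose activity shares slow behavioural signals (arousal-coupled cells
with multi-second running bouts) violate the bin-exchangeability
assumption outright and inflate the test further; calibration is
therefore probed on neurons without slow coupling. Users should read
borderline p-values from this test with corresponding caution.

## The synthetic-data generator

Generators draw all parameters from a seeded `ground_truth` and are
bit-deterministic given the seed. They emulate the statistical
structure the analyses assume, with known generating parameters for
recovery tests:

* **Passive sessions**: shuffled grating trials (8 directions, 1 s
  stimuli, 4-6 s intervals) whose noiseless amplitudes follow the
  circular-Gaussian tuning model exactly (responses are boxcars over
  the measurement window; no calcium-kernel dynamics). Running speed is
  a clipped, smoothed bout process so that both stationary (<1 cm/s)
  and running (>5 cm/s) epochs exist; pupil area tracks smoothed
  speed. Arousal enters additively as `gain * speed / 10`; ChC gains
  (0.8-1.2) and the frame noise SD (0.05 dFF) were chosen so that
  ChC-running correlations land near the reported ~0.5 and are treated
  as fixed study conditions. Fluorescence is embedded as
  `F = 100 (1 + dFF)` with zero neuropil so the preprocessing chain is
  exercised end to end and recovers the generated dFF exactly in the
  noiseless case.
* **Image responses**: pink-noise images with superimposed Gabors,
  responses from the ground-truth readout on the bundled extractor,
  Gaussian noise per presentation, and a 40-image test set with
  repeats.
* **Tunnel sessions**: a 1 m visual section traversed at a smooth
  running speed followed by a 9 s non-visual section (cue at 1 s,
  reward at 3 s, a post-reward stop and a fresh locomotion onset).
  V-cells respond in the 20-80 cm zone, NV-cells and ChCs at the
  start, in the non-visual section, at locomotion onsets and at
  mismatch events (0.5 s flow halts inserted between 20 and 80 cm
  during running). `cluster_strength` scales the V/NV difference; 0
  gives identical expected profiles for calibration runs.
* **Chemogenetic pairs**: two sessions with independently drawn but
  statistically matched locomotion; post-session noiseless activity is
  multiplied by the per-neuron silencing effect.

What passing tests on these data do **not** show: the generator has no
calcium-indicator kinetics, spike inference, eye movements, slow drift,
or realistic pairwise noise correlations beyond shared behavioural
coupling, so the tests certify the estimators' correctness and
calibration under their stated assumptions rather than performance on
raw recordings.

## Problem sizes used in the test and acceptance suites

Recovery and calibration runs use desk-scale sizes chosen to keep the
whole suite in a few minutes while leaving comfortable statistical
margins: readout recovery fits 50 neurons on 640 training images;
tuning batteries use 48-96 parameter combinations; BD and silencing
calibrations use 500 and 400 null simulations with 1000 and ~100
permutations each; the decoding chance check uses 34 neurons, 40
classes and 10 repeats with 50 split runs (averaged over 10 datasets in
the acceptance script).
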