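---
title: "Nested cross-validation for imagined-speech EEG decoding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested cross-validation for imagined-speech EEG decoding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`bcidecode` implements, end to end, a hyperparameter-optimization study for
imagined-speech EEG decoding: synthetic multi-subject EEG generation,
preprocessing (band-limiting, ICA-based blink screening, resampling),
relative wavelet energy (RWE) and filter-bank common spatial pattern
(FBCSP) features, six decoders (three compact convolutional networks and
three classical baselines), a nested cross-validation (nCV) driver with
exhaustive grid search and two hyperparameter-selection modes, and the
statistical layer that compares them. This vignette records the models, the
defaults and the design decisions that were genuinely open.

# The decoding problem

The reference acquisition records six EEG channels (F3, F4, C3, C4, P3,
P4, 10–20 system) at 1024 Hz while subjects imagine speaking one of six
Spanish words or one of five vowels; each 4 s trial is repeated 40 times
per class for each of 15 subjects. Recordings are distributed band-limited
to 2–40 Hz. Decoding is per subject and per task: given a trial's
channels-by-samples array, predict its class. Chance accuracy is 16.67%
(words) or 20% (vowels). Because the recordings themselves are not
redistributable, the package ships a generator that emulates the
protocol's structure so that every downstream stage is testable
offline; all claims validated on synthetic data concern the *machinery*
(calibration, selection logic, statistics), not decodability of real
imagined speech.

# Synthetic EEG model

Each trial is the sum of:

* **Background**: Gaussian noise with a $1/f^a$ amplitude spectrum
  (default exponent $a = 1$, the canonical EEG-like slope), synthesized in
  the frequency domain and band-limited to 2–40 Hz with the same
  windowed-sinc FIR family the preprocessing module uses. Per channel it is
  normalized to unit variance, so generated units are arbitrary; no
  microvolt calibration is claimed.
* **Class signal**: narrow-band Gaussian oscillations added on a small set
  of class-specific channels. The default assignment cycles each class
  through a canonical band (theta, mu, lower beta, upper beta, delta,
  gamma) on a rotating pair of channels, which makes classes separable
  exactly through band-power features — the representation every decoder
  in the study targets. The `snr` parameter is the variance ratio of the
  class signal to the background on affected channels; `snr = 0` removes
  the class signal entirely, so labels are statistically independent of
  the data (the null condition used for chance calibration).
* **Subject variability**: a log-normal whole-signal gain per subject
  (default sd 0.2 on the log scale) and log-normal jitter on per-class
  effect sizes (half that sd). This gives subjects different overall
  amplitudes and different class-separability profiles, which is what
  makes the intra- vs inter-subject selection comparison non-trivial.
* **Blinks**: a 300 ms biphasic template (positive lobe, smaller negative
  rebound — predominantly below 4 Hz), scaled to 5 times the per-trial
  background SD on frontal channels and attenuated over the montage
  (F ≈ 1, C ≈ 0.4, P ≈ 0.15). Counts per trial are Poisson with
  configurable rate. The amplitude is chosen so the 0.8-correlation
  component screen detects the component reliably without the artefact
  dominating the record.

What the generator does **not** emulate: cortical source geometry and
volume conduction, non-blink artefacts (EMG, line noise), overt-speech
trials, non-stationarity across a session. Passing tests on this generator
therefore demonstrate correctness of the pipeline and its calibration, not
performance on real recordings.

# Preprocessing

* **Band-pass**: zero-phase (forward–backward) windowed-sinc FIR, Hamming
  window, order $3 f_s / f_{lo}$ (even-rounded). The study's recordings
  come already filtered to 2–40 Hz; the module reproduces that operation
  for synthetic data and applies no further filtering.
* **Resampling** to 128 Hz (4 s trials become 512 samples) by zero-phase
  anti-alias low-pass filtering followed by integer decimation. The
  anti-alias cut-off is $0.45 \times f_{s,\text{target}}$, i.e. 90% of the
  target Nyquist: a cut-off at 45% of the Nyquist would destroy the
  28–40 Hz gamma band that the FBCSP filter bank consumes, so the cut-off
  is placed just under Nyquist with the transition band arranged to alias
  only above 40 Hz.
* **Blink screening**: FastICA (symmetric decorrelation, log-cosh
  contrast, deterministic seeded initialization) is fit per subject on the
  trial-concatenated recording, internally decimated by a factor of 3 for
  speed — the unmixing is purely spatial, so it transfers to the
  full-rate data. Component topographies are correlated with a blink
  template topography and flagged at $|r| \ge 0.8$. Absolute correlation
  is used because ICA component signs are arbitrary; a template matching a
  sign-flipped component is the same artefact. The original study's
  subject-one template is unavailable, so the template is config-supplied
  (the generator exports its own blink topography). The study's "visual
  inspection" step is replaced by an optional accept/reject override list
  to keep the pipeline non-interactive. ICA is fit on concatenated trials
  (the continuous record is not distributed); this is an assumption, noted
  as such.

# Features

**RWE**: five-level discrete wavelet transform per channel with
fourth-order Daubechies filters (db4) and symmetric boundary extension
(verified coefficient-exact against an independent wavelet
implementation). At 128 Hz, detail levels D2–D5 cover 16–32, 8–16, 4–8 and
2–4 Hz and the approximation A5 covers < 2 Hz; D1 (32–64 Hz nominal) is
computed and discarded. Level energies (sums of squared coefficients) are
normalized per channel over the five retained levels, giving a 30-element
vector per 6-channel trial. Since the retained set excludes D1,
normalization runs over the retained levels so each channel's five values
sum to one.

**FBCSP**: a six-band filter bank (delta 2–4, theta 4–8, mu 8–12, lower
beta 12–18, upper beta 18–28, gamma 28–40 Hz; same FIR family, order
scaled per band with a 64-tap floor so the narrow high bands keep usable
roll-off), per-band CSP, log-variance features, and mutual-information
feature selection. CSP solves the generalized eigenproblem of the
trace-normalized class covariances via whitening; `nsf` filter pairs are
retained from the two ends of the eigenvalue spectrum. For more than two
classes the study is silent on the scheme; the package uses one-vs-rest
decompositions per class, pools all filters and keeps the $2 \cdot nsf$
with the most extreme eigenvalues ($|\lambda - 0.5|$). Mutual information
is the plug-in histogram estimator after equal-frequency quantization into
`miql` bins (the estimator itself is not specified in the study; the
plug-in estimator is the simplest one consistent with a "quantization
level" hyperparameter). Ties in the MI ranking break by candidate index.
The `miql` grid defaults to (6, 8, 10, 12); the alternative level set
(2, 4, 6, 8) that appears in the study's selection tables is accepted via
configuration because the printed grids disagree, and the package treats
the methods-section grid as canonical.

Band filtering and RWE are label-free per-trial transforms, so they are
computed once per subject before cross-validation; everything supervised
(CSP, MI ranking, classifier fits) is re-fit inside each training fold.

# Decoders

Class scores $f_k$ become probabilities through a max-stabilized softmax.
Two losses are available: negative log-likelihood (mean of
$-\log p_{\text{true}}$) and a summed per-class binary cross-entropy
averaged over trials. Probabilities are clamped at $10^{-12}$; both losses
are exactly zero iff predictions are exact one-hot truths. The binary
cross-entropy's class index is read as running over all $k$ classes (the
printed formula's upper index is taken as a typographical slip for the
class count).

The three CNNs follow their original architecture publications, scaled to
a 6 × 512 input; all sizes are overridable via the `arch` argument:

* **shallow**: 40 temporal filters (kernel 25) → spatial convolution over
  all channels (40 filters) → batch norm → activation (square by default)
  → mean-pool (75, stride 15) → log → dropout 0.5 → dense softmax.
* **deep**: initial temporal (25 filters, kernel 10) + spatial block, then
  three identical blocks of dropout 0.5 / convolution (50, 100, 200
  filters) / batch norm / activation / max-pool 3.
* **EEGNet-style**: temporal convolution (8 filters, kernel 64, same
  padding) → depthwise spatial convolution (2 per map) → batch norm /
  activation / mean-pool 4 / dropout → separable convolution (depthwise
  16 + pointwise to 16) → batch norm / activation / mean-pool 8 / dropout
  → dense softmax.

Parameter counts at the default shape order EEGNet < shallow < deep. The
hyperparameter-controlled activation (ELU, square, ReLU, leaky ReLU with
negative slope 0.01) replaces the principal nonlinearity in all three
networks, including EEGNet's internal ones — the study does not pin this
down, and applying the HP uniformly is the reading that makes the
activation factor comparable across architectures. Inputs are z-scored per
channel per trial (input scaling is unstated in the study; without some
normalization the arbitrary-unit synthetic data would dominate the
learning-rate grid). Training uses ADAM (β₁ = 0.9, β₂ = 0.999) with batch
size 64 at the grid's learning rate, epoch count and loss, implemented
with an in-package backpropagation engine (gradient-checked against finite
differences). A fit whose loss goes non-finite is recorded as diverged and
predicts uniform probabilities; the surrounding grid search scores it 0
rather than aborting, which keeps exhaustive searches total under the
learning-rate grid's aggressive upper end (1.0).

The classical baselines are: SVM (via `e1071`, kernels
linear/RBF/polynomial/sigmoid with C and γ grids) and random forest (via
`randomForest`, features-per-split, tree count and minimum leaf size
grids), both on RWE vectors; and a shrinkage-regularized LDA on FBCSP
features, with the pooled covariance shrunk toward a scaled identity at
the Ledoit–Wolf analytic intensity (the study cites regularized LDA
without a coefficient; the analytic intensity removes the free parameter).
A `majority` baseline (constant majority-class prediction) is included for
chance calibration checks.

# Nested cross-validation

`make_folds()` builds stratified outer folds (per-fold class counts within
one trial) and, per outer fold, stratified inner folds over the
concatenated k−1 training folds. Stratification is a design choice the
study does not state; it removes class-composition noise from fold
accuracies. With k = 4, outer folds are 75% training / 25% testing and
inner splits 75/25 again. Inner fold assignments are re-seeded
deterministically from (master seed, outer index); per-cell fits are
seeded from (master seed, outer, inner) so duplicated grid entries score
identically and runs are bit-reproducible.

For each hyperparameter combination the driver records one validation
accuracy per (outer, inner) cell; the selected combination maximizes the
mean over all such cells (ties resolve to the earliest combination in
enumeration order — the study is silent on ties). The final model is then
trained per outer fold at the selected combination and tested on the held
fold; reported accuracy is the mean across outer folds. Intra-subject mode
selects per subject; inter-subject mode maximizes the across-subject mean
of the per-combination inner means, then trains and tests each subject at
the shared combination. Inner k equals outer k (the study's design); the
full inner table is exported so per-hyperparameter marginal means can be
recomputed downstream.

# Statistics

Per-hyperparameter effects on benchmark classifiers use a one-factor
repeated-measures ANOVA (subject × level table, subject-by-level
interaction as error term). CNN hyperparameter effects and decoder
comparisons use fixed-effects two-way ANOVA with interaction, Tukey HSD
post-hoc at α = 0.05, and per-class precision (TP / (TP + FP); classes
never predicted are excluded from the macro mean). Accuracies enter the
ANOVAs untransformed, matching how the study reports them; an
arcsine-square-root transform is available behind a flag. Degrees of
freedom are reported from the actual design rather than matched to any
published table, since the error-term construction behind the published
df is ambiguous; consequently printed F statistics of the original
analysis are not an acceptance surface here.

# Numerical and scale choices

* Zero-phase filtering uses reflective edge padding and FFT convolution;
  the batched path (`mvfft` over all trials and channels) is numerically
  identical to the per-signal path to ~1e-14.
* CSP guards singular composite covariances with a ridge
  (`1e-8 · mean diag`) and a logged warning; still-singular input errors.
* The equal-frequency quantizer collapses duplicate quantile breaks, so
  `miql` never exceeds the number of distinct feature values.
* Chance-level calibration (tests and the acceptance script) runs the
  rLDA-FBCSP pipeline because it exercises the full supervised feature
  path at a desk-scale cost. Data for these runs are generated directly at
  128 Hz — the generator's band-limited model makes generation at 1024 Hz
  followed by decimation equivalent in distribution — with 3 subjects and
  20 trials per class over 10 seeds, and a two-point hyperparameter grid:
  under the null, selection pressure does not change expected accuracy,
  while the nested structure stays fully exercised. The test suite uses
  2 subjects and 10 trials per class for the same check.
* The snr-recovery property is averaged over three paired seeds on the
  grid snr ∈ {0, 0.5, 1, 2}.

# Known limitations

* The CNN engine is a compact pure-R implementation: correct (gradient
  checked) but slow; full 128-combination CNN grids at study scale are
  impractical on one desk CPU and are exposed through configuration, not
  run in tests.
* The synthetic class structure is stipulated, not fitted to real imagined
  speech; the study gives no characterization of the discriminative
  spectral structure of its recordings, so none is claimed here.
* One dataset container format (RDS + CSV manifests) is provided rather
  than an HDF5-style hierarchical file.
* ICA-based cleanup assumes blink-like artefacts dominate a single
  component; overlapping artefact sources are out of scope.
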