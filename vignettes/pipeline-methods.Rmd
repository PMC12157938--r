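---
title: "Methods: EEG motor-execution gesture classification with empirical wavelet and Hilbert–Huang features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG motor-execution gesture classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
signal model, the two feature-extraction variants, the classifiers, the
evaluation protocol, and — importantly — the places where the design was
genuinely open and what was decided there.

## Signal model and assumptions

The pipeline targets motor-execution EEG: 8 electrodes over the sensorimotor
strip (F3, F4, C3, Cz, C4, P3, Pz, P4 in the 10-20 system), sampled at
250 Hz, cut into 5 s trials (1250 samples), seven gesture classes, multiple
subjects. The working assumptions are the standard ones for sensorimotor
BCIs:

* the class-discriminative signal lives in the mu (8–13 Hz) and beta
  (13–25 Hz) rhythms, expressed as amplitude/frequency modulation over a
  subset of channels;
* the background is colored (approximately 1/f) noise plus a mains line
  component at 60 Hz;
* trials are exchangeable within (subject, gesture) — the pipeline builds
  generalized (not subject-personalized) models.

## The synthetic generator

`generate_trialset()` emulates exactly this structure, because the pipeline
must be exercisable end to end without external recordings. Each trial is
the sum of

1. per-channel pink noise, `1/f^alpha` with `alpha = 1` by default (the
   conventional EEG background spectrum), synthesized by spectral shaping of
   white Gaussian noise and normalized to unit standard deviation;
2. a 60 Hz sinusoid of amplitude `line_amp` (default 1) with random phase;
3. a common sensorimotor rhythm — amplitude-modulated 10 Hz and 20 Hz
   components, amplitude `rhythm_amp` (default 2) — identical in law for all
   gestures. This term guarantees that the empirical wavelet transform finds
   genuine mu/beta spectral peaks even under the null, and that the
   "most sensitive mode" is a physiologically sensible one;
4. a gesture-specific AM–FM term scaled by `class_separation`: each of the
   seven shipped patterns fixes a channel subset, mu/beta amplitude gains,
   center-frequency offsets (±1.5 Hz around 10 Hz, ±3 Hz around 20 Hz), and
   an FM depth between 0.5 and 3.5 Hz.

Because the entire gesture term is multiplied by `class_separation`, setting
it to 0 makes the gesture-conditional distributions *identical*, which is
the package's null condition: any classifier's held-out AUROC must be ≈ 0.5
there, and the tests check this by Monte Carlo. The four higher-order
statistics used downstream are location-invariant (MAD, IQR) or
location-scale-invariant (skewness, kurtosis), so the gesture patterns were
deliberately designed to modulate *dispersion and shape* — envelope depth,
amplitude gains, FM depth — rather than merely shifting a mean the features
could never see.

What the generator does **not** model: event-related
desynchronization/synchronization time-courses, volume conduction between
electrodes, inter-subject variability beyond independent noise draws, motion
or ocular artifacts, and any posture effect (a `"standing"` flag is recorded
for the last two repetitions, mirroring the acquisition protocol, but no
effect is attached to it — there is nothing quantitative to model). Passing
tests on synthetic data therefore demonstrates that the pipeline recovers
the statistical structure it assumes, not that it attains any particular
accuracy on real recordings.

All randomness flows from the single `seed` argument; the global RNG state
of the session is saved and restored, and the same seed reproduces the
trial array bit for bit.

## Preprocessing

* **Mains notch.** The mains component is removed by a 5th-order Butterworth
  bandstop. Only the 60 Hz target is prescribed; the edges are a design
  choice, set to 58–62 Hz (a ±2 Hz notch is standard practice), with a
  50 Hz preset (`c(48, 52)`) for other mains regions.
* **Zero-phase application.** Filters are applied forward–backward
  (`signal::filtfilt`). This is an offline pipeline, and instantaneous phase
  and frequency are computed downstream, so phase distortion in the passband
  is unacceptable; a causal single-pass mode exists for streaming use.
* **Windows.** Trials are segmented with 60% overlap. The window *length* is
  a free parameter; 50 samples (0.2 s) is adopted because it is the unique
  length that yields 61 windows over a 1250-sample trial at 60% overlap with
  the step rule `step = round(0.4 * window_len)` (ties rounded away from
  zero): step 20, `floor((1250 - 50)/20) + 1 = 61`. Windows are half-open
  sample ranges; window `w` starts at `w * step` (0-based).
* Windowing is done **per trial** (61 windows each), not over concatenated
  recordings — the protocol ties 61 windows to one trial.

## Empirical wavelet transform

The EWT segments the magnitude spectrum on `[0, π]` adaptively and extracts
one mode per segment with Meyer-type filters.

* **Boundary detection.** The spectrum is smoothed with a Gaussian kernel
  (standard deviation `smoothing` bins, default 2 — wide enough to kill
  bin-level noise peaks on 1250-sample trials, narrow enough to keep mu and
  beta apart), the K largest local maxima are retained, and each boundary is
  the global minimum of the smoothed spectrum between consecutive maxima.
  If fewer than K maxima exist, K is *reduced with a warning* — fabricating
  boundaries in a flat spectrum would create meaningless modes silently.
  An optional brute-force grid search (`tune_smoothing()`) scores candidate
  widths by mean normalized spectral entropy of the resulting modes (lower =
  more compact) and picks the best; this makes the usual "hyperparameters
  were optimized" step concrete and reproducible without hiding it inside
  the default path.
* **Filter bank.** The scaling function covers `[0, ω₁]`, wavelet k covers
  `[ω_k, ω_{k+1}]` (the last extends to π), with C¹ transitions
  `β(x) = x⁴(35 − 84x + 70x² − 20x³)` of relative half-width `gamma`. With
  `gamma = "auto"` the largest admissible value
  `min_k (ω_{k+1} − ω_k)/(ω_{k+1} + ω_k)` (π appended) is scaled by 0.99;
  an explicit `gamma` beyond the bound errors out, reporting the bound. The
  bank is a tight frame: `Σ_k |ψ_k(ω)|² = 1` to 1e-10 on the whole grid, and
  a property test asserts this for 100 random boundary sets.
* **Analysis and synthesis.** The FFT length equals the signal length (no
  padding), modes are `ifft(X · conj(ψ_k))`, ordered low→high frequency.
  Reconstruction re-applies the filters before summation
  (`x̂ = Σ_k m̂_k ψ_k`), the dual-frame inverse that the tight-frame
  condition makes exact — the plain sum of modes is *not* an inverse for
  Meyer transitions (cos/sin overlaps sum to 1 only in squares), and the
  round-trip requirement (max abs error < 1e-8; measured ~1e-14) settles the
  choice.
* **Scope.** Decomposition is performed on each full 5 s trial per channel,
  then the selected mode is windowed — decomposition before windowing
  follows the pipeline's stage order. K defaults to 10 modes per channel.

## Hilbert–Huang features

* The analytic signal is built by the frequency-domain Hilbert transformer
  (zero negative frequencies, double positive ones). Instantaneous amplitude
  is `|z|`; instantaneous phase is the unwrapped argument (zero where
  `z = 0` by convention).
* Instantaneous frequency discretizes `dθ/dt` by **central differences**
  (second-order accurate; one-sided at the endpoints), with a forward-
  difference mode by flag. On closed-form fixtures (`make_tone()`,
  `make_chirp()` carry their IA/IF truth by construction) the estimators
  recover the truth on interior samples within 1% (IA) and 0.5 Hz (IF);
  edge samples are excluded because the circular Hilbert transformer wraps.
* The most task-sensitive mode maximizes Welch-PSD mass **above 2 Hz**
  (slow drifts excluded); ties go to the lowest index. Welch defaults:
  segment length `min(256, n)`, 50% overlap, Hann taper — standard practice.
  A max-bin criterion and a per-channel (majority-vote) mode scope are
  available by flag; the default selects per trial and channel.
* The four statistics are implemented exactly as defined: MAD with a 1/n
  factor; IQR from half-sample medians (overall median excluded when n is
  odd — for `c(1,2,3,4,5)` this gives `4.5 − 1.5 = 3`); skewness and
  kurtosis with biased 1/n moments and **no** small-sample correction,
  kurtosis non-excess (Gaussian → 3). Zero-variance windows make the moment
  ratios undefined; the scalar functions error, while the tensor builder
  maps them to 0 (`degenerate = "zero"`) so a flat window cannot abort a
  whole extraction run.
* Bandpower (variant 1) is the time-domain mean square of the already
  bandpassed window — the simplest reading of "bandpass, then bandpower".
* The "no feature extraction" condition is ambiguous between the variants,
  so both readings are exposed: `raw_band` (windowed bandpassed samples) and
  `raw_mode` (windowed samples of the sensitive mode; the default reading of
  the variant-2 condition).

## Classifiers

* **Hybrid network.** conv(32@5) → pool/2 → conv(64@3) → pool/2 →
  BiLSTM(64) → dense(64, ReLU) → dense(1, sigmoid). "Same" padding keeps the
  61-step sequence alive through both poolings (61 → 30 → 15); channel ×
  feature axes are flattened into the per-timestep feature vector, the
  window axis is the sequence. No deep-learning backend exists in the
  package's dependency set, so the forward and backward passes (including
  BPTT through both LSTM directions) are implemented in base R with BLAS
  matrix products; correctness is enforced by a finite-difference gradient
  check (relative error < 1e-4 on every parameter block) and a closed-form
  parameter-count oracle (81,889 parameters for a 61 × 8 input). Training:
  Adam (learning rate 1e-3 — the optimizer's conventional default, as none
  is prescribed), binary cross-entropy, batch size 16 (inside the prescribed
  6–20 range), and "epochs adjusted to optimize performance" is
  operationalized as early stopping on a stratified 15% validation split
  (patience 10, cap 200 epochs, best-validation weights restored) — a
  reproducible stand-in for manual tuning. Glorot-uniform initialization,
  forget-gate bias 1.
* **Shrinkage LDA.** The flattened tensors have p (up to ~3900) ≫ n, where
  the classical pooled-covariance estimate is singular, so the package
  implements LDA with Ledoit–Wolf shrinkage toward the scaled identity and
  solves the discriminant through the Woodbury identity (only an n × n
  system is factorized). On low-dimensional, well-conditioned data it agrees
  with `MASS::lda`, and on two shared-covariance Gaussians at n = 2000 it
  approaches the closed-form Bayes rule — both are tests.
* **SVM.** RBF kernel, C = 1, features standardized on the training portion
  only (via `e1071::svm(scale = TRUE)`); no kernel or regularization is
  prescribed, so the defaults of standard practice apply. Decision values
  are mapped monotonically to (0, 1) by the logistic function, oriented so
  larger means the target gesture.
* **One-vs-rest.** Each gesture's model relabels target → 1, rest → 0, on a
  stratified trial-level 80/20 split (stratification by gesture label;
  subject-grouped splitting is available for the cross-validation harness).
  Class balance is restored by seeded random oversampling of the minority
  class — duplication only, originals always retained — applied to the
  training portion only (the network applies it after carving out its
  validation split, so no duplicated row straddles the early-stopping
  boundary). The decision threshold is fixed at 0.5, ties to the positive
  class.

## Evaluation

* k-fold cross-validation (k = 5 default) with folds shared across
  classifiers and gestures, so comparisons are paired per (gesture, fold).
  Fold sizes differ by at most one (1386 trials → 278 + 4 × 277). The
  baselines run under k-fold per the protocol; the network defaults to its
  80/20 split in `train_ovr()` but runs under the same k-fold inside
  `run_experiment()` so the paired Wilcoxon comparison is symmetric.
* Aggregation over the seven one-vs-rest models is the unweighted mean of
  per-gesture binary metrics, with per-gesture, per-fold values retained in
  the report — the aggregate is always recoverable from the parts.
* F1 with no positives anywhere (TP + FP + FN = 0) is defined as 0 and
  logged via a message rather than failing silently.
* The Wilcoxon signed-rank test drops zero differences, mid-ranks ties, and
  computes the exact null distribution of W⁺ for n ≤ 25 by the
  generating-function recursion over doubled (hence integral) mid-ranks —
  exact even under ties, where the classical lookup refuses. Above 25 pairs
  it uses the normal approximation with continuity and tie corrections.
  Two-sided p-values at α = 0.05 are the default reading. Tests verify the
  exact branch against full 2ⁿ enumeration up to n = 12 and the approximate
  branch against `stats::wilcox.test`.

## Problem sizes and numerical tolerances

The test suite and the acceptance script exercise the full pipeline at
deliberately modest scale — 4–8 subjects × 7 gestures × 4–6 repetitions
(112–336 trials), class separation 3 for the separable condition and 0 for
the null, network capped at 40 epochs with patience 8 — sizes chosen so the
whole suite runs in minutes on one CPU while keeping every per-gesture
held-out set large enough for the stated thresholds (accuracy > 0.9 per
gesture on separable data; mean AUROC within 0.5 ± 0.1 on the null).
Key tolerances: tight-frame deviation < 1e-10; EWT round trip < 1e-8;
IA within 1% and IF within 0.5 Hz of fixture truth on interior samples;
kurtosis of 10⁶ Gaussian draws within 3 ± 0.05.

## Known limitations

* The synthetic generator validates mechanism, not clinical performance;
  absolute accuracies on real motor-execution EEG are not claimed anywhere
  in this package.
* Per-window Hilbert transforms on 50-sample windows carry circular edge
  bias; the HOS features absorb this in practice (all windows share it), but
  IA/IF *values* near window edges should not be interpreted individually.
* The EWT boundary detector is the local-maxima/inter-peak-minimum scheme;
  spectra with heavily overlapping bands can place boundaries unstably, and
  the optional smoothing-width search mitigates but does not remove this.
* The native network implementation is single-threaded BLAS-bound R; it is
  sized for hundreds of trials, not for large-scale training.
* EDF/EDF+ ingestion is not provided; trials enter as in-memory arrays or
  via the plain-text directory container (`write_trialset()` /
  `read_trialset()`).
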