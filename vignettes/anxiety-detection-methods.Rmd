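---
title: "Methods: on-line anxiety level detection from wearable biosignals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: on-line anxiety level detection from wearable biosignals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Problem and study design

The package implements a pipeline for detecting a person's momentary anxiety
level (low / medium / high) from three wearable biosignals: ECG, electrodermal
activity (EDA) and respiration (RSP), all sampled at 100 Hz. The session
structure mirrors a fear-exposure protocol for spider-fearful subjects:

* a **training session** holding a 5-minute rest used to compute per-subject
  baselines, and
* an **exposure session** consisting of a 1-minute demo clip, 16 one-minute
  anxiety-inducing video clips, a 4-point subjective arousal rating collected
  after every fourth clip (a 20-s pause), and a final 5-minute rest —
  1400 s in total.

The pipeline turns these sessions into labeled fixed-length windows (10 s or
60 s), extracts up to 25 time-domain features, trains one of nine classifier
configurations, evaluates it with pooled 10-fold cross-validation, and can
replay a session on-line with one prediction every 10 s.

## Signal processing

**ECG.** R-peaks are detected with the Pan–Tompkins algorithm: band-pass
5–12 Hz, five-point derivative, squaring, 150-ms moving-window integration,
adaptive dual thresholds (update factors 0.125/0.25), a 200-ms refractory
period, and a search-back when a gap exceeds 1.66× the running RR mean. Peak
positions are refined to the band-passed maximum within ±75 ms. All filters
are zero-phase (forward–backward Butterworth), so no group-delay bookkeeping
is needed; the input is extended by odd reflection at both ends so filter
startup transients cannot leak into short slices. Normal-to-normal intervals
(NNIs) outside 300–2000 ms are discarded as implausible.

**EDA.** The tonic component is the 1.5 Hz low-passed signal; the phasic
component additionally removes content below 0.05 Hz. The high-pass uses a
first-order design (an effective second-order zero-phase magnitude response):
a steeper filter produced post-response undershoot comparable to the 0.03 µS
detection threshold and created spurious detections. Orienting responses
(ORs) are local maxima of the phasic signal whose rise from the preceding
trough is at least 0.03 µS; the onset is the *last* weak local minimum before
the peak (so a flat lead-in does not inflate durations), and the offset is
the half-recovery point capped at 10 s after the peak. Note the 0.05 Hz edge
attenuates slow responses somewhat (a 0.5 µS response with a 4-s decay
constant measures ≈ 0.43 µS); counts and relative comparisons are unaffected.

**RSP.** Breaths are maxima of the 0.1–0.4 Hz band-passed chest signal at
least 2 s apart. The spacing floor must stay below the 2.5-s period of the
0.4 Hz band edge, otherwise breathing at the top of the physiological range
is undercounted. A literal 24 Hz upper cutoff is available for audit via
`literal_cutoff`.

## Features

Each window yields up to 25 features, 11 ECG + 7 RSP + 7 EDA, following the
study's time-domain definitions: for each channel a normalized mean (window
mean minus the resting mean; for EDA the Lykken range correction
`(x − min_rest) / (max_rest − min_rest)` instead), the standard deviation,
and normalized first/second differences of the within-window z-scored series
(a constant window yields 0, not NaN). The interval-based family adds the
signed-difference variability statistic (which telescopes to
`(last − first)/N` and flips sign under time reversal — implemented as
printed), avNN, sdNN, rMSSD (`sqrt(Σd²/(N−1))`), and NN50/pNN50/pNN20.
The threshold counts use successive *differences* (the standard HRV reading;
the oracle `pNN20([800, 810, 790, 805]) = 1/3` fixes this); the literal
interval-count reading of the printed formulas is available behind
`literal_counts` for audit. The final six-feature set retained by sequential
forward selection is `HRNmean`, `HRstd`, `EDANmean`, `EDANFD`, `EDAnOR`,
`EDAmmOR`.

Structurally missing values (e.g. mean OR magnitude in a window with no OR)
are imputed as 0 for the classifiers but flagged beside the matrix, never
silently.

## Labeling

Five approaches, each with 10-s and 60-s windows and 2- or 3-level classes:

* **SB** (subjective): the clip right before each rating is labeled high
  (rating 3–4) or medium (1–2); low is the last 3 minutes of the training
  rest.
* **HR1/EDA1** (clip-based): one cohort-level ranking of the 16 clips by the
  mean baseline-normalized signal; top 3 high, ranks 7–9 medium, low as in SB.
* **HR2/EDA2** (subject-based): each subject's own ranking; top 8 high,
  remaining 8 medium, low is the full 5-minute rest. Three-level shares are
  8/21, 8/21, 5/21 of labeled minutes — 38/38/24 on the percentage scale.

Windows tile each labeled segment from its start; a remainder shorter than
the window is discarded and no window crosses a segment boundary. Ranking
ties break by ascending clip index, making labels deterministic.

## Classifiers and evaluation

Nine configurations: decision tree (Gini, at most 100 splits), LDA, QDA,
kNN (k = 1 and 10, Euclidean), SVM (linear and quadratic kernel, box
constraint 1), Gaussian naive Bayes, and bagged trees (30 learners). Bagged
trees use `randomForest` with `mtry = p` (all features per split), which is
exactly bagging. Distance- and kernel-based families receive per-feature
standardization fitted on training folds only. Evaluation pools out-of-fold
predictions from stratified 10-fold cross-validation into one confusion
matrix; reported are accuracy, per-class true rates (recall), precision,
one-vs-rest ROC/AUC, and Cohen's kappa with the Landis–Koch bands
([0, 0.2] slight, (0.2, 0.4] fair, (0.4, 0.6] moderate, (0.6, 0.8]
substantial, (0.8, 1] almost perfect). Window-level folding mirrors the
study; grouped (subject-held-out) folds are available via `group` for
leakage-safe estimates. Sequential forward selection greedily adds the
feature with the best CV accuracy and stops when nothing strictly improves.

## On-line playback

`playback()` emits one prediction every 10 s after a one-interval warm-up.
Causality is structural: the shared `window_features()` path processes a
bounded lookback slice (default 120 s) that *ends at the window end*, so no
feature can depend on samples after its emit time, and batch extraction of
the same windows is bit-exact at the feature level. The 120-s lookback gives
the slow EDA filters context to settle while keeping the on-line state
bounded. (Class *scores* from batch vs row-by-row prediction can differ at
~1e-16 through BLAS rounding; hard predictions agree exactly.)

## Synthetic cohort generator

The simulator is first-class, tested code and the ground truth for the
acceptance analyses. Each clip carries a latent arousal level a ∈ {0, 1, 2}
(default multiset 5 high / 6 medium / 5 calm, permuted per subject) that
drives every channel:

* **ECG**: beat times from an AR(1)-jittered RR process (φ = 0.8, stationary
  SD 40 ms at rest, shrunk ×0.8 per arousal level); mean HR is
  `rest_hr + a · hr_arousal_delta`. Rendered as Gaussian R waves (SD 12 ms)
  plus a T wave, 0.25 Hz baseline wander and sensor noise. Because the
  jitter is autocorrelated, a single 60-s clip mean fluctuates by ~1 bpm;
  recovery claims therefore average over clips.
* **EDA**: tonic level + slow drift + a 30-s-smoothed arousal-dependent
  elevation (tonic shifts are sub-band by definition, so they do not leak
  through the 0.05 Hz phasic high-pass), plus biexponential SCRs (rise
  0.75 s, decay U(2, 6) s, amplitude U(0.1, 0.6) µS) from a Poisson process
  whose rate is linear in arousal, thinned to a 5-s inter-onset refractory
  because orienting responses are scored as discrete events.
* **RSP**: a phase-continuous sinusoid at `br_rest + a · br_arousal_delta`.
* **Ratings**: `max(1, 2a)` flipped by ±1 with probability `rating_noise`.

Two presets pin the acceptance conditions. `simulation_config_strong()`
(n = 40) raises high clips by 15 bpm, quadruples the SCR rate and uses
noiseless ratings — a cohort where the pipeline must succeed.
`simulation_config_null()` (n = 20) zeroes every arousal effect *and* the
tonic drift (drift would otherwise make training-rest vs exposure windows
separable for reasons unrelated to arousal), so any kappa far from 0 would
reveal leakage. Cohort sizes are the package's own test choices, not claims
about the original study.

Effect-recovery claims on these presets use
`arousal_contrast_labels()` — ground-truth high-arousal clips versus calm
clips — rather than the signal-ranked labeling approaches. Signal-ranked
labels are circular for this purpose: clips are ranked by their mean
normalized signal and the same signal then feeds the features, so even a
null-effect cohort scores above chance (measured κ ≈ 0.27 on a null cohort
with HR2 labels — a selection effect, not leakage). The contrast labels also
keep both classes inside the exposure session (no session-level confound)
and are exactly balanced under the default 5/6/5 assignment, making the
majority share coincide with chance accuracy. These recovery analyses fold
by subject (`kfold_cv(..., group = )`): windows cluster within subjects,
and with balanced within-subject labels a held-out window's class is
anti-correlated with its own subject's training labels (4/9 against 5/9
among the remaining nine windows), so window-level folds bias null-data
accuracy *below* chance (measured ≈ 0.44 where 0.50 is chance).

## Limitations

* The generator's waveform realism is limited: no ectopic beats, motion
  artifacts, electrode pops or breathing modulation of the ECG; detector
  performance on real recordings will be worse than the near-perfect
  recovery reported on synthetic data.
* Window-level cross-validation shares subjects between folds, as in common
  practice for this design; subject-held-out estimates (via `group`) are
  more conservative and the honest choice for generalization claims.
* The signed-difference variability statistic is implemented as printed even
  though it telescopes; it carries little information beyond the window's
  endpoints.
* The 0.05 Hz phasic high-pass attenuates slow SCRs by up to ~15%; magnitude
  features are comparable within the pipeline but not calibrated to raw µS.
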