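# anxiodetect

On-line detection of a person's momentary anxiety level (low / medium /
high) from three wearable biosignals: electrocardiogram (ECG),
electrodermal activity (EDA) and respiration (RSP), all sampled at 100 Hz.

The pipeline targets a fear-exposure protocol: a **training session** whose
5-minute rest provides per-subject baselines, and a 1400-s **exposure
session** of 16 one-minute anxiety-inducing video clips with periodic
4-point arousal ratings and a closing rest. Sessions are cut into labeled
fixed-length windows (10 s or 60 s), each window yields up to 25
time-domain features, one of nine classifier configurations is trained and
evaluated with pooled 10-fold cross-validation, and a playback engine
replays a recorded session to emit one prediction every 10 s under strict
causality.

## Method sketch

* **ECG** — Pan–Tompkins R-peak detection (band-pass 5–12 Hz, derivative,
  squaring, 150-ms moving-window integration, adaptive dual thresholds,
  search-back), normal-to-normal intervals (NNIs), heart-rate and HRV
  features: `HRNmean = mean(HR) − HR_rest`, `std`, normalized first/second
  differences of the z-scored series, avNN, sdNN,
  `rMSSD = sqrt(Σ dᵢ² / (N−1))`, NN50/pNN50/pNN20.
* **EDA** — tonic (low-pass 1.5 Hz) and phasic (additionally high-pass
  0.05 Hz) components; orienting responses (SCRs) as phasic rises ≥ 0.03 µS
  with onset/peak/half-recovery scoring; Lykken range correction
  `(x − min_rest) / (max_rest − min_rest)` for the normalized mean.
* **RSP** — breaths as band-passed (0.1–0.4 Hz) signal maxima; breathing
  rate and interval statistics.
* **Labeling** — subjective ratings (SB), cohort-level clip ranking
  (HR1/EDA1) or subject-level ranking (HR2/EDA2); two or three classes;
  the subject-based 3-level split gives 38% / 38% / 24% class shares by
  construction.
* **Classification** — decision tree, LDA, QDA, kNN (k = 1, 10), SVM
  (linear, quadratic), Gaussian naive Bayes, bagged trees (30 learners);
  pooled 10-fold CV reporting accuracy, per-class true rates, precision,
  one-vs-rest ROC/AUC and Cohen's kappa with Landis–Koch bands; greedy
  sequential forward feature selection. The retained six-feature set is
  `HRNmean, HRstd, EDANmean, EDANFD, EDAnOR, EDAmmOR`.
* **Synthetic cohorts** — a first-class simulator renders all three
  channels from a latent per-clip arousal level with full ground truth
  (R-peak times, SCR events, breath rate, ratings), so every stage is
  testable without clinical recordings.

See `vignettes/anxiety-detection-methods.Rmd` for the full method
description and design rationale.

## Worked example

```r
library(anxiodetect)

# simulate a small cohort with ground truth
coh <- generate_cohort(simulation_config(n_subjects = 4, seed = 7))
subjects <- lapply(coh, `[[`, "subject")
coh[[1]]$truth
#> <ground_truth> S001: clip arousal [1201201110100222]; 1712/62 exposure R-peaks/SCRs

# per-subject resting baselines from the training sessions
baselines <- lapply(subjects, compute_baseline)
names(baselines) <- vapply(subjects, `[[`, character(1), "subject_id")
str(unclass(baselines[[1]]))
#> List of 6
#>  $ subject_id  : chr "S001"
#>  $ hr_rest_mean: num 70.1
#>  $ br_rest_mean: num 14
#>  $ eda_rest_min: num 1.98
#>  $ eda_rest_max: num 2.6
#>  $ rest_window : num [1:2] 0 300

# label windows (subject-based HR ranking, 2 levels, 60-s windows)
cfg <- labeling_config("HR2", levels = 2, window_s = 60)
win <- label_cohort(subjects, cfg, baselines)
table(win$label)
#> high  low
#>   32   20

# extract the final six-feature set
fs <- extract_features(subjects, win, baselines = baselines)
head(round(fs$features[final_feature_set()], 3))
#>   HRNmean HRstd EDANmean EDANFD EDAnOR EDAmmOR
#> 1   9.231 2.288    1.045  0.003      5   0.222
#> 2   5.211 3.080    0.742  0.003      3   0.314
#> 3  10.494 2.265    1.118  0.003      5   0.260
#> 4   6.158 3.610    0.794  0.002      2   0.325
#> 5   5.189 3.100    0.934  0.003      4   0.316
#> 6  11.144 2.972    1.634  0.004      7   0.305

# train bagged trees and cross-validate
rep <- kfold_cv(classifier_config("bagged_trees"),
                fs$features[final_feature_set()],
                droplevels(fs$labels), k = 10, seed = 1)
c(accuracy = rep$accuracy, kappa = rep$kappa)
#> accuracy    kappa
#>        1        1
rep$confusion
#>       predicted
#> true   low high
#>   low   20    0
#>   high   0   32

# replay one exposure session on-line, one prediction every 10 s
model <- train_classifier(classifier_config("bagged_trees"),
                          fs$features[final_feature_set()],
                          droplevels(fs$labels), seed = 1)
ev <- playback(subjects[[1]]$exposure$records, model, baselines[[1]],
               update_s = 10,
               labels = win[win$subject_id == "S001", ])
head(ev[!is.na(ev$true_label), c("start", "end", "true_label", "predicted")])
#>    start end true_label predicted
#> 13   120 130       high      high
#> 14   130 140       high      high
#> 15   140 150       high      high
#> 16   150 160       high      high
#> 17   160 170       high      high
#> 18   170 180       high      high
playback_accuracy(ev)
#> [1] 0.9791667
```

(The default simulator injects a clear arousal effect, so CV on window-level
folds of a small synthetic cohort is near-perfect; this is not a claim about
real recordings, where subject-held-out folds via `kfold_cv(..., group = )`
are the honest estimate.)

## Command line

A thin CLI over the same functions ships in `inst/cli/anxiodetect`:

```sh
Rscript inst/cli/anxiodetect simulate --out-dir /tmp/demo --subjects 1 \
        --seed 9 --preset strong
Rscript inst/cli/anxiodetect playback --dir /tmp/demo/S001 \
        --approach HR2 --levels 2 --out /tmp/demo/events.csv
#> events: 140; labeled agreement: 100.0%
```

`simulate` writes per-subject `training.csv` / `exposure.csv` (with JSON
layout sidecars readable by `read_session()`) plus a ground-truth summary;
`playback` reads a subject directory, builds the baseline, labels and
trains, then replays the exposure session on-line.

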