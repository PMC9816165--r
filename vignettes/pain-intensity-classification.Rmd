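---
title: "Classifying pain intensity from EEG band power: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying pain intensity from EEG band power: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`painerd` implements a two-stage externally validated analysis for
classifying low versus high pain intensity from single-trial peri-stimulus
EEG, together with a synthetic-EEG generator that makes every stage of the
analysis verifiable without any recorded data. This vignette explains the
model and procedure, the tunable parameters and their defaults, what the
generator does and does not emulate, and the design choices made where the
problem left the design genuinely open.

## The analysis in one paragraph

Two simulated experiments mirror a pressure-pain paradigm: a training study
(three blocks of 40 trials over touch/low/high intensities, 1 s stimulus
rise + 3 s hold) and a validation study (three blocks of 48 trials in a
2 × 2 intensity-by-rise-time design). Epochs spanning −4 to 6 s around
stimulus onset are band-pass filtered (0.5–70 Hz), notch filtered
(50 ± 2 Hz) and resampled to 256 Hz. A sliding-window multitaper PSD
(1 s windows, 0.05 s steps, 1–70 Hz at 1 Hz) is converted to event-related
desynchronisation, `ERD% = (A − R)/R × 100`, against the mean power of the
−3.5 to −0.5 s baseline, and collapsed over theta (4–7), alpha (8–12),
lower beta (16–24), upper beta (25–32) and gamma (33–70 Hz). Fifteen
summary statistics of each channel-by-band ERD time course form the
candidate features (9600 for a 128-channel montage; 600 at the desk-scale
default of 8 channels). After MAD-based outlier interpolation and 0–1
scaling, univariate ANOVA-F ranking plus sequential forward selection keep
the top 50 features; seven classifier families are fitted and assessed by
stratified 10-fold cross-validation, then frozen and evaluated on the two
external sets (EV1: fast rise, matching stimulation; EV2: slow rise,
different stimulation), reporting accuracy, precision, recall, F1, AUC,
Brier score, ROC curves and reliability diagrams.

## The synthetic generator

Each channel is the sum of `1/f^beta` background noise (`beta = 1`,
RMS `noise_sd = 1` a.u.) and five independent band-limited Gaussian
oscillators (per-band RMS defaults: theta 1.5, alpha 2.0, lower beta 1.2,
upper beta 0.8, gamma 1.0 a.u.), synthesised in the frequency domain.
Stimulus effects are imposed multiplicatively: during the stimulation
window the variance of targeted oscillators is scaled by `1 + ERD/100`,
ramped linearly over the rise time, held through the 3 s plateau, and
returned to baseline along a 1 s half-cosine after offset. The smooth
return matters: an abrupt gain step smears broadband transient power into
every band and produces a spurious, condition-dependent post-stimulus
synchronisation.

The default modulation profile follows the tonic-pain EEG literature:
theta increases frontally/centrally (+10 % low, +25 % high pain), alpha
and lower beta desynchronise centrally/parietally (−15/−10 % low,
−40/−25 % high), and gamma increases centrally (+8 % low, +25 % high).
Slow-rise (3 s) stimulation attenuates every target by the factor
`slow_rise_atten = 0.5`, which is what makes the second external
validation harder than the first — the qualitative pattern
CV ≥ EV1 ≥ EV2 that the evaluation stage reports. These effect sizes were
fixed once, as a profile whose single-trial discriminability is comparable
to what the paradigm's published accuracies imply (cross-validated
accuracies in the 70 % range), and are not tuned per run.

Channel "regions" are three contiguous index groups (frontal, central,
parietal) standing in for scalp topography; there is no electrode
geometry, no volume conduction, no artifacts (ocular, cardiac, EMG), and
no inter-trial EEG — epochs are generated independently, which is
adequate because the analysis consumes epochs only. Passing tests on this
generator therefore demonstrate the correctness and statistical behaviour
of the pipeline, not that real EEG supports any particular accuracy.
Inter-participant variability is a per-participant log-normal factor
(sdlog 0.1) on band amplitudes. Behavioural ratings follow a
condition-mean model on the 0–100 scale (low 36.87, high 62.65, SD 14,
touch 8), minus a rise-time effect of 4 points for slow rise, plus a
between-study shift of 12.3 points for the validation study; values are
clipped to [0, 100].

Trial schedules are drawn by sequential sampling with a feasibility
invariant: a condition is eligible for the next slot only if choosing it
leaves per-block counts that can still be ordered without two consecutive
trials of the same condition (max remaining count at most `ceil(n/2)`, and
at most `floor(n/2)` for the condition just placed). Any schedule
satisfying the quota and no-repeat constraints is acceptable; the sampler
weights eligible conditions by their remaining quota.

## Numerical choices

**Filtering.** The 0.5 Hz high-pass (order 2), 70 Hz low-pass (order 4)
and 48–52 Hz band-stop (order 2) Butterworth designs are applied
zero-phase as a frequency-response multiplication with each filter's
squared magnitude — exactly the response a forward–backward IIR pass
realises, without its edge transients. The contract (≥ 20 dB stop-band
attenuation, no group delay) is normative, not the realisation.
Resampling from 1000 to 256 Hz is Fourier resampling: spectrum truncation
at the new Nyquist (ideal anti-aliasing) and inverse transform on the
coarser grid, preserving duration exactly.

**Multitaper.** Slepian tapers are computed from the standard symmetric
tridiagonal eigenproblem, with time–bandwidth product 2 (2 Hz
half-bandwidth at 1 s windows) and 3 tapers — a conventional
resolution/variance trade-off; both are configurable. Window centres run
−3.5 to 5.5 s in 0.05 s steps (181 windows); a window belongs to the
baseline iff its centre lies in [−3.5, −0.5] s (centre attribution is the
documented choice for windows straddling the boundary). PSD scaling is
one-sided density; the convention cancels in the ERD ratio.

**ERD estimation and ratio bias.** Per-trial ERD divides by a per-trial
baseline estimated from ~3 s of data; because `E[A/R] > E[A]/E[R]` for a
noisy denominator, single-trial ERD is biased upward by roughly 15–20 %
of `(1 + g)` at these window counts. This inflation affects every
condition multiplicatively and therefore preserves class contrasts — the
classification features inherit it harmlessly — but parameter-recovery
checks use the classical grand-average estimator (`tf_average()` before
`compute_erd()`), which is consistent: averaging power over trials first
makes the baseline concentrate and the recovered band ERD converge to the
generator's target (residual ~1–3 points from taper leakage across band
edges and in-band background power).

**Bands.** Band collapse is the unweighted mean of ERD over the band's
inclusive integer-Hz bins; the 13–15 Hz gap between alpha and lower beta
is preserved (those bins are unused), so theta has 4 bins and gamma 38.

**Statistics.** The 15-statistic catalogue follows the conventions of the
numerical environment whose built-ins it names: sample (n−1) variance/SD;
biased population skewness; raw kurtosis (normal ≈ 3); `rms =
sqrt(mean(x^2))`; `squared_mean = mean(x)^2`; mode with ties broken
toward the smallest value (on continuous data this approaches the
minimum; retained for fidelity); and the wavelet-entropy forms
`shannon = -sum(x^2 log x^2)`, `log_energy = sum(log x^2)` with
`0·log 0 := 0`, `log 0 := 0`.

**Outliers.** Values beyond 3 scaled MADs (1.4826 × MAD) of the group
median are interpolated linearly between the nearest surviving
neighbours in acquisition order (boundary values take the nearest
survivor). Grouping is per feature within intensity class crossed with
dataset — each dataset is cleaned independently. A zero MAD flags any
deviating value and leaves identical values untouched. An entirely
flagged group is an error, never silently imputed.

**Scaling and leakage.** Default scaling is per dataset (training, EV1
and EV2 each fit their own min/max), mirroring independent data
management across studies; a strict `scale_mode = "train-only"` applies
the training scaler to the external sets. Feature selection runs once on
the full training table by default (`selection_scope = "global"`, which
leaks across CV folds but never into external validation); a fully nested
mode re-ranks and re-scales inside every training fold. The no-leakage
property of the nested path is tested by perturbing held-out rows and
checking that fitted transforms are unchanged.

**Evaluation conventions.** Positive class = high pain throughout;
classification threshold 0.5; AUC is the rank statistic (ties ½), which
equals the trapezoidal ROC area by construction; calibration uses 10
equal-width bins (configurable, recorded in reports); CV metrics are
mean ± SD over folds; metrics with zero denominators report 0 with a
warning. Stratified folds assign each class round-robin after a seeded
shuffle, guaranteeing per-fold class counts within one of proportionality.

## Models and hyperparameters

Seven families: AdaBoost (discrete boosting of exhaustive-search decision
stumps with learning-rate shrinkage, written in-package), shrinkage LDA
(pooled covariance shrunk toward scaled identity, closed form,
in-package), L1 logistic regression (glmnet, `lambda = 1/(nC)` matching
the liblinear parameterisation), Gaussian naive Bayes (with sklearn-style
variance smoothing, in-package), random forest (ranger), RBF-SVM (e1071,
built-in Platt-scaled probabilities) and XGBoost. Defaults are the
reference optima: AdaBoost learning rate 0.1 / 2500 estimators; LDA
shrinkage 0.4; LR C = 1 (L1); RF 350 trees, depth 10, `log2` features;
SVM C = 1, gamma = 0.1; XGBoost depth 2, gamma 1.5, min child weight 1,
subsample 1, colsample 1. One caveat: ranger does not offer an
entropy/information-gain split criterion, so the forest uses Gini
splitting; the remaining forest parameters follow the optima. Naive Bayes
has nothing to optimise. Default grids are small neighbourhoods around
each optimum and contain it; grid search evaluates the Cartesian product
by mean stratified-CV accuracy with ties broken by grid order. One
pipeline seed fans out deterministically to every stochastic component
(schedules, epochs, fold shuffles, forests, boosting, SVM calibration),
making whole reports bit-reproducible.

## Problem sizes

Desk-scale defaults keep every stage runnable on one CPU in minutes:
8 channels (the feature-count law `channels × 5 × 15` is checked at 128
channels symbolically by building one 128-channel trial), 120 + 144
simulated trials per pipeline run, 200 trials for spectral
parameter-recovery checks, 300 trials for permutation-null checks. The
boosting families use reduced ensemble sizes (tens of estimators instead
of the production 2500) in null-distribution checks, where chance-level
behaviour is independent of ensemble capacity. The ordering property
(CV ≥ EV1 ≥ EV2 in the median) is assessed over 10 independent pipeline
seeds with the random-forest family, the best external generaliser in
this class of problems.

## Known limitations

Single-trial ERD carries the baseline ratio bias discussed above; reports
are internally consistent but absolute single-trial ERD levels are
inflated relative to the grand-average estimate. The generator's
artifact-free, stationarity-between-events world makes external
validation easier than reality; accuracies obtained here characterise the
pipeline, not the sensor modality. The mode statistic is nearly the
minimum on continuous data (kept for fidelity). The forest's split
criterion deviates from the stated optimum (Gini vs entropy) for backend
reasons. Regression of continuous ratings, topographic visualisation,
source analysis and artifact simulation are out of scope.
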