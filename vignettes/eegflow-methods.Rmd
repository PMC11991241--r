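---
title: "EEG engagement analysis for adaptive game difficulty: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG engagement analysis for adaptive game difficulty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegflow)
```

`eegflow` implements an end-to-end analysis of mental engagement during
computerised cognitive gameplay, monitored passively through consumer-grade
EEG. The pipeline has five scientific stages: per-player difficulty
calibration from in-game metrics, self-report engagement labeling via the
flow state scale, spectral EEG features (the classical engagement indices),
nonparametric group statistics across difficulty levels, and supervised
high/low engagement classification. A synthetic cohort generator makes every
stage testable without access to human recordings.

## Difficulty calibration: the Performance Index

Players differ widely in skill, so each player's "optimal" difficulty must
be estimated from their own play-through of the game's ten levels. Three
in-game counts are recorded per level: rings collected (TC), rings missed
(TM) and obstacle hits (OH). Each metric is min–max normalised across the
ten levels and combined with importance weights 5 (collect), 5 (miss) and
2 (obstacle), normalised to 0.4167/0.4167/0.1666:

$$\mathrm{PI} = 0.4167\,\mathrm{TC}' - 0.4167\,\mathrm{TM}' - 0.1666\,\mathrm{OH}'.$$

Collected items reward performance; misses and obstacle hits penalise it —
the worked-example datasheet shipped with the package is numerically
consistent only under this sign convention, so it is the one implemented.
The PI column is itself min–max normalised to a 0–100 scale (%PI′); the
level scoring 100 is the player's optimal level, level 1 is the easy level,
and the hard level sits four levels above optimal.

Two numerical choices matter here:

* **Weight rounding.** The default `"paper-rounded-4dp"` mode rounds each
  adjusted weight to four decimals and balances the last one so the set sums
  to exactly 1, giving 0.4167/0.4167/0.1666. This reproduces the reference
  datasheet bit-for-bit (exact fractions 5/12 and 2/12 give, e.g.,
  PI = 0.150681 instead of the printed 0.150701 at level 3). An
  `"exact-fraction"` mode is provided for principled use; in that mode PI is
  invariant to rescaling all raw weights.
* **Degenerate inputs.** A metric constant across levels normalises to 0
  rather than NaN, so one flat column cannot poison the index; all three
  constant is a calibration error. Ties in %PI′ resolve to the lowest level
  (the most conservative difficulty). A hard level beyond level 10 is capped
  with a warning — the capping rule is this package's choice, flagged in the
  output, since the source procedure never addresses optimal levels above 6.

```{r calibration}
metrics <- read_metrics_csv(system.file("extdata", "worked_example_metrics.csv",
                                        package = "eegflow"))
calibrate_levels(metrics)
```

## Engagement labeling: the flow state scale

After each 2-minute session at the easy, optimal and hard levels the player
answers the 14-item flow state scale for occupational tasks (items 0–7). The
rated score is the raw sum divided by 14; sessions at or above 4.5 points
are labeled high engagement and below 4.5 low. The source procedure also
excludes participants whose scores sit at the undecided midpoint of 4; the
two rules are reconciled here as a configurable neutral band (default
4 ± 0.25) that produces a third, excluded label. A subject enters
within-subject classification only if, after neutral removal, they have both
a high and a low session — a binary classifier is undefined otherwise.
Exclusion is per-subject by default (per-session labeling is what the table
of labels reports, so per-session workflows remain possible).

## EEG preprocessing

Recordings are 14-channel (AF3 … AF4 montage), 128 Hz. Preprocessing is
deliberately light, matching common practice for consumer headsets:

* **Band-pass 0.5–45 Hz**, fourth-order Butterworth, applied
  forward–backward (zero phase, magnitude response squared). Zero-phase
  filtering is the standard offline choice because it does not delay band
  power relative to epoch boundaries. The 45 Hz edge plus the bidirectional
  pass leaves a 60 Hz line component at well under 1% amplitude.
* **Optional ICA muscle-artifact removal** (`"ica-infomax"`), an
  extended-infomax decomposition on PCA-whitened data. Components whose
  20–45 Hz to 0.5–20 Hz power ratio exceeds 1.0 are flagged as muscle,
  zeroed together with any manually listed components, and the channels are
  reconstructed. The spectral-ratio rule is this package's explicit
  operationalisation of "automatic muscle component removal"; the per-component
  ratios are reported, never silently applied. The stage defaults to off:
  the synthetic data used in the tests carries its muscle contamination as
  an explicit, controlled component, so the pipeline's contracts are
  checked both with and without it.
* **Epoching** into contiguous, non-overlapping 1-s windows of 128 samples
  (half-open sample ranges, 0-based); a 2-minute trial yields exactly 120
  epochs, and any trailing remainder is dropped with its count logged.

## Spectral features: multitaper band powers and engagement indices

Per epoch and channel the power spectral density is estimated by the
multitaper method with DPSS (Slepian) tapers, computed from the classical
symmetric tridiagonal formulation and cached per epoch length. Band powers
are trapezoidal integrals of the one-sided density over
theta 4–8 Hz, alpha 8–13 Hz and beta 13–30 Hz; bands sharing an endpoint
integrate additively, so the three bands plus their complement reconstruct
the total power exactly. The three engagement indices are

$$E_1 = \frac{\beta}{\theta + \alpha}, \qquad
  E_2 = \frac{\beta}{\alpha}, \qquad
  E_3 = \frac{1}{\alpha},$$

with denominators floored at $10^{-12}\,\mu V^2$ (floored epochs are flagged,
not dropped). Engagement raises beta power and suppresses alpha, so all
three indices are expected to increase with engagement.

**Time–bandwidth choice.** The default is NW = 2 with 2·NW − 1 = 3 tapers.
On a 1-s, 128-sample epoch this gives a ±2 Hz spectral concentration band,
matched to the 4–5 Hz widths of theta and alpha: a 10 Hz alpha rhythm stays
inside 8–13 Hz. NW = 4 (a common default for longer windows) would spread
the same rhythm over ±4 Hz, leaking substantial alpha energy into theta and
beta and biasing all three indices; it is available via the `nw` argument
but not recommended at this epoch length.

For classification, features are per-channel (3 indices × 14 channels = 42
columns for the combined set), since all electrodes feed the classifier;
for the group statistics the indices are averaged across channels first.

## Signal quality

Per channel, SNR in dB is `10*log10(signal/noise)` with signal = theta +
alpha + beta power of the trial-averaged 1-s multitaper PSDs and noise = the
30–45 Hz muscle band plus a ±1 Hz window around the 60 Hz line frequency.
The SNR is computed on the unfiltered recording: after the 45 Hz band-pass
the line operand would be vacuously zero, so the pre-filter signal is the
only meaningful operand (this choice is recorded in the report metadata).
Channel SNRs are averaged across a subject's three sessions and flagged:
bad at or below 0 dB, marginal below 3 dB, excellent above 10 dB. Zero or
negligible noise power caps at a configurable ceiling with a flag.

## Group statistics

Rated scores and channel-mean indices are compared across the three levels
with a Friedman rank test (within-subject ranks, average ranks on ties, the
tie-correction factor always applied — Likert-derived scores tie often),
followed by Dunn-type pairwise comparisons
$z = (\bar R_i - \bar R_j)\big/\sqrt{k(k+1)/(6n)}$ with two-sided normal
p-values and Bonferroni adjustment over the three pairs. A Shapiro–Wilk
screen per condition is reported for the decision path, but the pipeline
always proceeds nonparametrically. The tie-corrected statistic is
implemented directly (the base-R Friedman test applies no tie correction and
reports no mean ranks); on tie-free data the two agree to machine precision,
which the test suite asserts.

At the cohort sizes this design uses (n ≤ 27, k = 3) the chi-square
reference distribution is an approximation to a coarsely discrete exact
permutation law. The test suite verifies, against an exact
dynamic-programming enumeration, that the chi-square p tracks the exact p
within 0.05 throughout the rejection-relevant region (exact p ≤ 0.3);
deeper in the null region the exact law's discrete atoms (gaps of ~0.1 in
probability) make any continuous approximation deviate more, which is
irrelevant to inference at α = 0.05.

## Classification

Random-forest and SVM classifiers separate high from low engagement epochs.
The design reconciles an 80/20 split with cross-validated tuning: reported
metrics always come from a stratified 20% holdout, and all hyperparameter
search (10-fold for single-index within-subject models, 5-fold for combined
and cross-subject models, nested 5-outer/3-inner for the combined
within-subject design) runs inside the 80% training partition. The scaler
(mean 0 / SD 1 per feature) is fitted on training rows only. Splits are
stratified by label to preserve the roughly 2:1 high:low imbalance; F1 (with
high as the positive class, recorded in the report metadata) is the primary
metric because accuracy flatters imbalanced data.

The SVM tuning grid is C ∈ {0.1, 1, 10, 100}, gamma ∈ {scale, auto}
(1/(p·var(X)) and 1/p respectively), kernel ∈ {RBF, linear}. The
random-forest grid is expressed in `randomForest`'s native controls —
`ntree` {100, 200, 300}, `nodesize` {1, 2, 4}, `maxnodes` {unrestricted,
32, 256} as the tree-size analogue of a depth limit, `replace`
{TRUE, FALSE} — because the conventional depth / min-samples-split
parameterisation has no direct equivalent in this implementation of CART
forests.

Cross-subject evaluation defaults to pooled-epoch splitting (one model over
all subjects, stratified 80/20). Pooled splitting lets the same subject
appear in both partitions, an optimistic-validity caveat noted in the
report; a leave-one-subject-out mode is provided for the stricter question
of generalisation to unseen players.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
the biophysics of EEG:

* **Signals.** Per band (theta/alpha/beta), amplitude-modulated sinusoids at
  band-centre frequencies with random phase and a slowly varying envelope of
  unit mean square, so expected band power is exactly amplitude²/2. High
  engagement defaults to beta amplitude 8 µV / alpha 3 µV, low engagement
  the reverse (8/3 swapped); theta 4 µV in both. The 1/f background is
  spectrally shaped white noise (default RMS 4 µV, slope 1), plus an
  optional 60 Hz line sinusoid and 0.5-s 30–45 Hz muscle bursts. No
  published effect sizes exist for the band-power difference between
  self-reported high and low engagement at the epoch level, so the class
  amplitudes are explicit, documented knobs — a clear class separation by
  default, and `band_amp_low = band_amp_high` as the null configuration.
* **Subject structure.** Per-channel, per-band gain jitter (U(0.8, 1.2)) is
  drawn once per subject — electrode placement and anatomy are stable within
  an experiment — so that sessions of one subject differ only through class
  amplitudes and noise. Drawn per session, the gains would act as a session
  fingerprint that a pooled-split classifier could exploit even under the
  null. Subjects flagged older-adult get a global amplitude attenuation
  (0.8) and an extra 1 µV white-noise floor: a deliberately phenomenological
  stand-in for the lower signal quality observed in older cohorts, not a
  physiological claim.
* **Gameplay metrics.** Collected counts grow linearly with level; misses
  and obstacle hits grow slowly (penalty increment 0.03 per level in
  normalised units) up to the configured peak level and steeply after it.
  This guarantees, noise-free, that the PI peaks exactly at the configured
  level. The peak must lie in 1–9: with non-decreasing counts, min–max
  normalisation pins every normalised metric to 1 at level 10, forcing
  PI(10) = −0.1666 — the global minimum — so a level-10 peak is
  mathematically impossible under the generator's own monotonicity
  invariants.
* **Flow responses.** Item scores are integer-rounded draws around the
  session mean plus a subject offset and a subject-by-level interaction.
  Session means default to 4.91/5.51/4.59 (easy/optimal/hard) — the
  reference study's conditions — and the variance decomposition
  (between-subject SD 0.55; interaction SDs 0.5/0.25/1.0; item SD 1.0) was
  chosen once so the simulated per-level rated-score SDs land near the
  study's 0.81/0.65/1.15. Under these defaults roughly a third of simulated
  subjects end up with both high and low sessions and enter within-subject
  classification, somewhat below the 16-of-27 retention of the reference
  cohort; the band is wide because retention hinges on rare below-threshold
  hard-level scores.

One master seed drives everything through named substreams keyed by
(subject, session, generator), so adding a generator never perturbs the
draws of another, and identical configurations are bit-identical.

**What passing tests do and do not show.** The generator's oscillations are
narrowband and stationary, its classes differ by construction, and its
artifacts are simple; real EEG has broadband nonstationary rhythms, volume
conduction, eye blinks and drifting electrodes. Green pipeline-recovery
tests therefore demonstrate the correctness of the machinery (no leakage,
correct spectral estimation, faithful evaluation protocol) — not that the
classifier would reach comparable F1 on human recordings.

## Problem sizes used by the test suite

The statistical and classification suites run at reduced, fixed sizes chosen
as representative desk-scale experiments: Friedman calibration uses 1000
null replicates at n = 27; pipeline-recovery uses a 12-subject cohort with
60-s trials (within- and cross-subject) and 4-subject, 30-s cohorts across
10 seeds for the feature-set comparison; hyperparameter grids are reduced to
a 2-point SVM grid where the grid itself is not under test (the full grids
remain the defaults). Design-arithmetic checks (120 epochs per 2-minute
trial; 5760 feature rows from 16 subjects × 3 sessions × 120 epochs) run at
full scale.

## Known limitations

* The Performance Index is specific to this game's three metrics; no attempt
  is made to generalise it.
* Gamma-band indices are deliberately out of scope, as are ERD/ERS features
  and regression-based ocular/cardiac artifact removal (the target headset
  has no dedicated EOG/ECG channels).
* The ICA stage assumes artifacts are separable as high-frequency-dominant
  components; slow eye-movement artifacts would need a different flag rule.
* Cross-subject pooled metrics share subjects across partitions (see above);
  treat them as the optimistic bound and LOSO as the conservative one.
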