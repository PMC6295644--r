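---
title: "Methods: core temperature prediction from wearable biosignals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core temperature prediction from wearable biosignals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coretemp)
```

# The problem and the data

Core body temperature is the central quantity in heat-strain
monitoring, but its reference measurements are invasive. `coretemp`
implements prediction of rectal temperature from 18 non-invasive
channels logged at 0.1 Hz during a two-session heat protocol: each
session comprises 15 min baseline seated rest at room temperature,
15 min seated rest in a hot chamber (≈35 °C), 20–60 min of cycling
(stopped when rectal temperature rises 1.5 °C above baseline or
reaches 38.5 °C), and 30 min seated recovery outside the chamber.
Session 1 is cycled at 75 % of the participant's maximal heart rate in
light clothing; session 2 at 50 % in insulating protective clothing.

A session is held as a `session_record`: a data frame of channel
columns named `<modality>_<site>` on a shared time base, per-sample
missingness (`NA`), and per-sample phase labels. Phase intervals
(half-open, 0-based) are derived from the labels on demand; labels
rather than intervals are stored internally because they survive
complete-case filtering and lag truncation without fragmenting.

# Signal conditioning

The preprocessing chain, in order:

1. **Calibration** — precomputed affine corrections per channel
   (`gain·x + offset`); missing stays missing.
2. **Heart-rate smoothing** — a 60-point (10-min) *trailing* moving
   average. The window includes the current sample and shrinks at the
   series start: a causal filter usable in real time, without
   discarding baseline data. Output is missing only where the window
   holds no present value.
3. **Heat-flux filtering** — a zero-phase (forward–backward)
   second-order Butterworth low-pass. The nominal 0.2 Hz cutoff
   presumes an acquisition rate well above the 0.1 Hz logging rate; at
   0.1 Hz the Nyquist frequency is 0.05 Hz, so the default
   configuration resolves the cutoff automatically — 0.2 Hz whenever
   the input rate admits it, otherwise 0.4× Nyquist (0.02 Hz at
   0.1 Hz). An explicit cutoff at or above Nyquist raises an error
   rather than being silently clamped. Because forward–backward IIR
   filtering carries a startup transient, each contiguous segment is
   padded by odd reflection (≥ 12 cutoff periods) before filtering;
   interior gaps of ≤ 5 samples are bridged by linear interpolation
   (and re-marked missing afterwards), longer gaps split the series
   into independently filtered segments.
4. **Artifact removal** — heat-flux samples outside the *closed*
   interval [−100, 300] W/m² become missing (removed, not truncated);
   boundary values are retained, reading "above"/"below" strictly.
5. **Heat-flux smoothing** — a 40-point (6.7-min) trailing moving
   average, capturing the recent heat gain/loss history.
6. **Lag alignment** — rectal temperature trails the predictors by
   about 12.5 min (75 samples); the rectal channel is advanced by a
   fixed 75 samples so that rectal(t + lag) pairs with predictors(t),
   shortening the record accordingly. The lag is a configuration
   constant in the prediction path; `estimate_peak_lag()` (mean-removed,
   unnormalized cross-correlation over non-negative lags ≤ 200, ties to
   the smallest lag) is provided for diagnostics and development.

A caveat on the lag estimator: on *trending* signals the unnormalized
cross-correlation is maximized a few samples away from the true shift,
because shorter-overlap windows trade alignment against extra
large-amplitude terms. On stationary delayed-copy input the estimate
is exact, and after alignment the residual lag is exactly zero; on raw
protocol-shaped sessions the estimate is typically within a minute of
the built-in delay. This bias is inherent to the estimator definition
and is why the prediction path uses the fixed average lag.

# Outlier screening

Screening is a single pass on complete cases. Time points whose
squared Mahalanobis distance over the 18 predictors exceeds the χ²
critical value for df = 18 at tail p = 0.001 (42.31) are removed; a
working regression is then fitted and points with internally
studentized residuals outside ±3 are removed. The working regression
defaults to the component regression (rectal on the two component
scores), matching the model actually fitted downstream; a
raw-predictor regression is selectable. Mahalanobis distances use the
sample mean and sample covariance (denominator n − 1), so their mean
over rows is exactly p(n − 1)/n, and they are invariant under affine
changes of basis — both properties are tested.

# Model development

Participants are split at the participant level (both sessions stay
together) into near-even development and validation groups (7/6 for
13), under a recorded seed.

**Adequacy.** KMO (overall and per item) is computed from the
correlation and anti-image partial-correlation matrices; Bartlett's
sphericity statistic is χ² = −(n − 1 − (2p + 5)/6)·ln det R with
df = p(p − 1)/2 (153 for 18 items).

**PCA.** Performed on the correlation matrix (matching the score
equation's standardization). Components with eigenvalue > 1 (Kaiser)
are retained; the retained loadings are varimax-rotated with Kaiser
normalization (tolerance 1e-6); each component's largest-magnitude
loading is made positive. Score coefficients follow the regression
method, W = R⁻¹Λ, so scores on the development data have unit variance
and near-zero inter-correlation.

**Regressions.** The component regression is a forced-entry OLS of
rectal temperature on the scores. The reduced model starts from
collinearity pruning: repeatedly, the pair with the largest |r| > 0.9
is found and the member with the smaller p-value (ties: larger |t|) in
an SPSS-style stepwise regression (entry p ≤ 0.05, removal p > 0.10)
is kept. Backward reduction then drops the term with the smallest
|standardized β| one at a time, stopping before a refit would violate
SEE < 0.5 °C or a *cumulative* adjusted-R² drop > 0.05 relative to the
full pruned model (read as total tolerated degradation, not per step);
removed terms are never re-entered.

**Validation.** Raw predictions on the held-out participants are
corrected by the mean offset (predicted − measured) over the
validation pool, then summarized by regressing measured on predicted:
SEE = √(SS_res/(n − 2)) and adjusted R² = 1 − (1 − R²)(n − 1)/(n − 2).
An alternative "difference" mode (SEE as the RMSE of the differences)
is selectable and labeled in the report, since "SEE between measured
and predicted" admits both readings.

# The shipped prediction models

The published equations are shipped at full printed precision:
Max-Input `T = 0.2978·s₁ + 0.2471·s₂ + 37.2539` (offset −0.15 °C) over
Eq.-style component scores whose coefficients, means and SDs are the
development-set values — incoming data are *never* re-standardized
against their own statistics, so scores are reproducible on new data;
Min-Input `T = 0.0100·HR + 0.0837·T_ins,scapula + 33.1735` (offset
−0.06 °C); and an external-model wrapper carrying the published
+0.24 °C offset slot for a user-supplied prior equation whose
coefficients are not distributed here. Offset correction is
`corrected = raw − offset` with offsets stored as printed. "Factor
score" and "component score" are treated as the same quantity, and the
parenthesized Table values accompanying the channel means are taken to
be SDs, as the score equation's notation implies.

# The simulator

The simulator exists so that every operation above is testable without
participant data. It emulates: the phase structure and stop rule
(cycling duration follows a per-session heating rate, first passage of
+1.5 °C/38.5 °C, bounded to 20–60 min); participant-level HRmax ~
N(181, 9²); heart rate approaching phase targets (baseline 75,
chamber rest 95, cycling at 75 %/50 % HRmax, recovery decaying toward
95 beats/min) with AR(1) noise (coefficient 0.95 at 0.1 Hz — chosen
for plausible slow drift, not a published value); 17 channels as
affine maps of two latent processes scaled to the published
development means/SDs — a skin-temperature factor (rises with chamber
entry and exercise, decays slowly) and a heat-flux factor (drops on
entering hot air as the skin–air gradient collapses, recovers with
sweat evaporation, spikes on returning to cool air) — with
channel-specific residual noise set by the published loadings;
heat-flux artifacts outside [−100, 300] W/m²; and per-channel missing
runs (mean length 10 samples).

Rectal temperature has two generation modes, because the real
generative process is unknowable from summary statistics:
`"physical"` (default) lags and smooths the thermal drive — realistic
traces, no exact oracle; `"model_faithful"` generates
rectal(t + 75) = 0.0100·HR_smoothed(t) + 0.0837·T_ins,scapula(t) +
33.1735 + ε — an exact inverse construction against which the
prediction path is tested to machine precision at ε = 0.

What the simulator does *not* emulate: biophysical heat balance
(clothing, sweat evaporation), inter-channel residual correlations
beyond the two-factor structure, device-specific noise spectra, and
imposed heart-rate statistics — HR is emergent from the protocol, so
its pooled mean/SD only approximate the published 111.3 (34.1)
beats/min. Passing tests on simulated cohorts therefore demonstrate
the correctness and stability of the *procedures*, not the field
validity of the models on new human data.

# Numerical choices and problem sizes

Degenerate inputs fail loudly: singular covariance (Mahalanobis, KMO),
non-positive-definite correlation (Bartlett), constant series (lag
estimation), zero-variance predictions (validation), rank-deficient
designs (regression). In stepwise entry, a candidate collinear with
the current model is treated as non-enterable (p = 1) rather than an
error. Ties in the lag search break toward the smallest lag; ties in
"higher significance" break toward larger |t|.

Test and acceptance runs use cohorts of 13 participants (25 sessions,
≈70 000 samples pooled) for end-to-end checks, n = 5000 for
parameter-recovery fits, and n ≤ 5000 property fixtures; the complete
suite runs in a few minutes on one core.
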