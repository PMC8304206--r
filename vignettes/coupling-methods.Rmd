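---
title: "Quantifying cardiac mechano-electric coupling from beat-interval series"
author: "cardiocoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac mechano-electric coupling from beat-interval series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiocoupling)
```

## The problem

The heart's electrical activity (captured by the ECG) and its mechanical
activity (captured by heart sounds, the PCG) are coupled in both
directions: excitation drives contraction, and the mechanical state feeds
back on myocardial electrophysiology. In coronary artery disease this
coupling degrades — ischemia blunts the immediate mechanical response to
electrical excitation — so the *statistical* coupling between
beat-by-beat electrical and mechanical interval series is a candidate
noninvasive marker of stenosis severity.

`cardiocoupling` implements that analysis end to end. The raw inputs are
per-beat fiducial annotations (landmark times in ms produced upstream by
ECG delineation and PCG segmentation, which are out of scope here). From
them the package builds six beat-interval series:

* **RRI** — R peak to next R peak (heart period),
* **QTcI** — QT interval, Bazett-corrected: $QTc = QT / \sqrt{RR\,[s]}$,
* **TpeI** — T-wave peak to T-wave offset,
* **TpeQTI** — the ratio TpeI/QTI,
* **STI** — S1 offset to S2 onset (electromechanical systole as heard),
* **DTI** — S2 offset to next S1 onset (diastole).

The four electrical series are each paired with the two mechanical
series, giving eight pairs in a fixed canonical order. Every pair is
z-normalized, so all tolerance parameters below are in SD units.

## The six coupling measures

**Cross sample entropy (XSampEn).** Templates
$X_m(i) = (x_i, \dots, x_{i+m-1})$ from one series are compared with
templates from the other under the Chebyshev distance. With
$B^m(r)$ the fraction of cross-template pairs within tolerance $r$ at
length $m$ (we average over the first $N - m$ templates at both lengths,
the standard sample-entropy convention that keeps the two counts
comparable),
$$\mathrm{XSampEn} = -\ln\frac{B^{m+1}(r)}{B^{m}(r)},$$
with defaults $m = 2$, $r = 0.2$. If no pair matches at either length the
entropy is undefined; the package raises a distinct
`undefinedEntropyError` rather than returning an infinity, and downstream
stages impute the feature with the cohort maximum (no matches = maximal
irregularity).

**Cross fuzzy entropy (XFuzzyEn).** The hard threshold is replaced by the
Gaussian membership $A(d) = e^{-\ln 2\,(d/r)^2}$, which equals $1/2$
exactly at $d = r$ and never vanishes, so XFuzzyEn is always defined.

**Joint distribution entropy (JDistEn).** Each series is delay-embedded
with $m = 2$, $\tau = 3$ ($N - m\tau$ vectors); the per-series Chebyshev
distance matrices $D_1, D_2$ are rescaled to $[0,1]$ by their own maximum
off-diagonal entry and combined element-wise as
$$JD = J - \sqrt{(J - D_1) \circ (J - D_2)},$$
the geometric-mean combination of the method's original formulation; a
plain-product variant is available via `sqrtForm = FALSE`. The value is
the Shannon entropy of the histogram of $JD$'s upper-triangle entries
(fixed support $[0,1]$, bin count from Doane's rule), normalized by
$\log_2 B$, hence always in $[0,1]$. Identical series give $JD = D$ and
the measure reduces to the single-series distribution entropy. A fully
degenerate distance matrix (constant series) is defined as 0.

**Magnitude-squared coherence (MSCF).**
$C(f) = |P_{xy}|^2 / (P_{xx} P_{yy}) \in [0,1]$ on the beat-frequency
grid. The interval series are treated as evenly sampled in the *beat*
domain (frequencies in cycles/beat, DC excluded, Nyquist 0.5): the
measures operate directly on beat-indexed series, so no wall-clock
resampling is involved. Spectra are Welch-averaged periodograms —
Hamming taper, segment length 128 beats, 50% overlap by default. For
records shorter than ~2.5 segments the segment length is capped so that
at least two segments always fit (`segLength * (2 - overlap) <= N`);
with a single segment coherence is identically 1 and meaningless, so
that case errors. The feature pair is the mean and SD of $C(f)$ over the
grid.

**Imaginary cross power spectral density (ICPSD).**
$|\mathrm{Im}\,S_{xy}(f)| = A_x A_y |\sin \Delta\phi_{xy}|$: phase-lagged
covariation that is exactly zero for in-phase or anti-phase coupling.
Mean and SD over the grid are the features.

**Mutual information (MI).** A Gaussian-kernel plug-in estimate in bits,
$$\bar I = \frac{1}{N}\sum_i \log_2
  \frac{\hat P_{xy}(x_i, y_i)}{\hat P_x(x_i)\,\hat P_y(y_i)},$$
with covariance-scaled Silverman bandwidths
$h = (4/(d+2))^{1/(d+4)} N^{-1/(d+4)}$ — the $d = 2$ rule for the joint
density and the $d = 1$ rule for the marginals (`marginalRule = "d2"`
makes the marginals share the joint bandwidth). Densities at the sample
points are evaluated *leave-one-out*: including the self term inflates
the joint density more than the marginal product and biases MI upward by
about +0.06 bits on independent data at $N = 300$, which would swamp the
small negative plug-in bias the estimator should have there. With the
leave-one-out convention the estimator lands within ±0.04 bits of 0 on
independent Gaussians and tracks the closed form
$-\tfrac12 \log_2(1-\rho^2)$ within KDE bias at $N = 300$. Slightly
negative values on near-independent data are reported as computed, not
clipped.

Per subject this yields **64 features**: 3 entropies × 8 pairs (24),
MSCF mean/SD × 8 (16), ICPSD mean/SD × 8 (16), MI × 8 (8), named
`<electrical>-<mechanical>-<code>`, e.g. `TpeI-DTI-JD`.

## Anomalous beats and the 10% rule

Clinical over-reading of interval series is codified as two configurable
screens: physiologic bounds (RRI 300–2000 ms, STI 150–600 ms, DTI
100–1500 ms, TpeI 20–200 ms) and a rolling-median/MAD outlier rule
(window 11 beats, $k = 5$). A beat flagged in any series is deleted from
*all* series, keeping the pairs beat-aligned. A subject whose flagged
fraction strictly exceeds 10% is invalid and excluded; 10.0% exactly is
still valid ("went beyond" is read as a strict inequality). At least 30
usable beats are required — entropy estimates below that are unreliable.
QTc uses the same-beat RR by construction; heart-rate influence on QT is
known to act with a lag, so this is a documented simplification rather
than a physiological claim.

## The synthetic cohort generator

The study's clinical recordings are private, so the package generates
labeled cohorts whose *coupling strength* is controlled. Everything is
generated in the beat domain. RRI is a mean-reverting AR(1) around 900
ms. Every other series sits on a physiologic baseline (systole ≈ RR/3;
diastole the rest of the cycle net of 100 ms S1 and 80 ms S2 sound
durations; group-level QTI and TpeI baselines) and is an AR(1) driven by
the shared-innovation convex mixture
$$\varepsilon_k = \frac{\rho\, e_{RR} + (1-\rho)\,\eta_k}
  {\sqrt{\rho^2 + (1-\rho)^2}},$$
so a single scalar $\rho \in [0,1]$ moves the innovation correlation
monotonically from 0 to 1 — a mechanism every coupling measure in the
package should detect, chosen over phase coupling for exactly that
reason. Baselines are constants, not beat-wise functions of RRI, so
$\rho$ is the *only* channel that couples the electrical and mechanical
innovations.

Group defaults (see `defaultGroupProfiles()`): coupling
$\rho$ = 0.2 / 0.5 / 0.8 for severe / mild-to-moderate / CPNCA —
coupling degrades as stenosis worsens — and dispersion/autocorrelation
profiles that encode the qualitative series morphology of the three
groups: stable RRI (SD 15 ms, AR 0.8) but elevated, widely fluctuating
TpeI (mean 120 ms) in severe disease; large dispersed RRI and DTI
fluctuation (SD 50/35 ms, AR 0.3) in mild-to-moderate disease; and
concentrated TpeI (75 ms, inside the 40–110 ms normal range) and Tpe/QT
(≈0.19, inside 0.15–0.25) in the normal-angiography group. No
quantitative group effect sizes are published for these series, so the
dispersion values are plausibility choices — fixed once and documented,
not fitted to any outcome. Because entropy and coupling measures operate
on z-normalized series, group mean shifts carry no class signal; only
coupling and autocorrelation structure do.

`genAnnotations()` inverts the construction exactly (a series set of
length $L$ becomes $L+1$ annotation rows; QTI is recovered from QTcI by
inverse Bazett), and `extractIntervalSeries()` recovers the series to
1e-9 ms, so the annotation-file path and the in-memory path are
interchangeable. `injectAnomalies()` replaces a chosen fraction of RRI
values with out-of-range values (uniform over 100–250 or 2200–3000 ms)
to exercise the screening rule; "anomalous" has no published definition
beyond the 10% rule, so out-of-physiologic-range corruption is the
model.

What the generator does **not** emulate: waveform morphology,
arrhythmia, respiration- or circadian-driven nonstationarity, missed or
false fiducial detections with realistic error structure, and the
real-data relationship between series means and disease. Passing tests
on synthetic cohorts therefore demonstrate that the measures detect
shared-innovation coupling and that the pipeline's bookkeeping is
correct — not that the printed clinical accuracies would be reproduced
on real patients.

## Group statistics and classification

Per feature, each group is screened for normality with the
Lilliefors-corrected Kolmogorov–Smirnov test (parameters are estimated
from the data, so the plain KS test would be anti-conservative; it
remains available via `lilliefors = FALSE`, and groups under 5
observations fail the screen by construction). If every group passes at
0.05, one-way ANOVA is the omnibus test with pairwise t tests post hoc;
otherwise Kruskal–Wallis with pairwise Wilcoxon tests. The Bonferroni
family is the 3 pairwise comparisons of one feature
($p_{adj} = \min(1, 3p)$); no cross-feature correction is applied,
matching per-series significance reporting. Stars follow `* p < 0.05`,
`** p < 0.01`.

Classification follows the published protocol shape: per pairwise group
task, a stratified 70/30 split; z-scoring, NA imputation, SVM-RFE
ranking (linear cost-1 SVM, smallest squared weight eliminated per
iteration, ties to the earlier column) and hyperparameter/k selection by
stratified fivefold CV — all confined to the training 70% — then a
gradient-boosted tree model with per-sample weight $w = 2.5$ on the
minority class, evaluated on the untouched test split (accuracy, F1 as
the harmonic mean of sensitivity and precision, sensitivity,
specificity, AUC; the more-stenosed group is the positive class, the
convention under which sensitivity tracks the majority class in an
imbalanced severe-vs-other task). A single 30% split of a desk-scale
cohort is one noisy realization, so the default protocol repeats the
split 10 times with derived seeds and reports mean metrics; the retained
feature count $k$ is chosen per split from {5, 10, 15, 24} by training
CV, since published subset sizes are data-dependent. Feature-family
masks (`entropy` = the 24 cross-entropy features, `spectral` =
MSCF/ICPSD/MI, `all`) mirror the single-family versus joint comparisons.

## Numerical choices and degenerate inputs

* Chebyshev (max-norm) template distance throughout the entropy family.
* JDistEn embedding count $N - m\tau$ per series (the printed indexing),
  histogram over fixed $[0,1]$ with empty bins contributing 0; Doane's
  bin count $B = \mathrm{round}(1 + \log_2 n + \log_2(1 + |g_1|/\sigma_{g_1}))$
  floored at 1.
* Constant series cannot be z-normalized and error out at pairing;
  constant features are reported "untestable" by the screening stage.
* MSCF is clamped to $[0,1]$ against floating-point overshoot of the
  Cauchy–Schwarz bound; MSCF/ICPSD summaries average the full band above
  DC (no physiological band restriction; the band is configurable).
* All generators and protocols are pure functions of (config, seed);
  derived seeds come from a single integer-safe mixing function
  (`deriveSeed`), so cohort, splits, folds and model fits are exactly
  reproducible.

## Problem sizes used by the test and acceptance runs

The bundled verification suite works at desk scale, chosen as the
smallest sizes at which the statistical checks have comfortable margins:
cohorts of 60 subjects per group with 300 beats per subject (the
5-minute recording scale) for screening-calibration and classification
checks; 20-seed Monte-Carlo sweeps for coupling sensitivity; 50-seed
sweeps at $N = 300$ for MI calibration; 200 label permutations for
family-wise-error calibration. The full 114/37/40 cohort structure is
the generator's default and is exercised for structure, not power.

## Known limitations

* The coupling mechanism is a single shared innovation; real
  mechano-electric coupling is frequency- and phase-structured, so the
  relative sensitivity of the six measures here need not transfer to
  clinical data.
* Beat-domain spectra ignore wall-clock irregularity of beat timing.
* The XGBoost hyperparameter grid is deliberately small (depth 2–3,
  50/150 rounds, eta 0.1); the synthetic tasks saturate well before the
  grid matters, and a clinical application would widen it.
* Three-way (multi-class) classification is out of scope; tasks are
  pairwise.
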