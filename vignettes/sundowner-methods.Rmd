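---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sundowner` implements the computational core of a sundowning-phenotype
study design: linking time-of-day dependent behavior in mouse dementia
models to brain-wide immediate-early-gene activity maps, sleep architecture,
and circadian rhythmicity. This vignette describes each statistical
component, the assumptions behind it, the tunable parameters and their
defaults, and the design decisions taken where conventions genuinely vary.
Everything is exercised on synthetic data with planted structure; the last
section discusses what that does and does not establish about real data.

## Behavioral partial least squares correlation (PLSC)

PLSC relates a subjects × behaviors block $X$ (arm/zone times in seconds,
distance in cm, movement-syllable frequencies) to a subjects × regions block
$Y$ (activity densities, cells/mm³). Both blocks are column-standardized and
the cross-block Pearson correlation matrix
$R = X_z^\top Y_z / (n - 1)$ is decomposed by SVD,
$R = U \,\mathrm{diag}(\delta)\, V^\top$. Each latent variable (LV) pairs a
behavior salience vector (column of $U$) with a brain salience vector
(column of $V$); $\delta_i^2 / \sum_j \delta_j^2$ is the LV's share of the
total cross-block covariance ("inertia", $\sum_j \delta_j^2 = \|R\|_F^2$).

Choices that needed fixing where the literature varies:

* **"Centered, scaled, then decomposed"** is implemented as
  column-standardizing both blocks before forming $R$, so $R$ is exactly the
  behavior × region correlation matrix and the decomposition inherits that
  interpretation. Re-centering $R$ itself would destroy it.
* **Missing brain data.** Regions with more than 2 missing values in any
  group are removed; the rest are imputed with the group-wise region median
  (missingness treated as missing at random). The default cap of 2 reflects
  cohorts of 6–8 animals per group.
* **Permutation inference.** Subject rows of the brain block are permuted
  relative to the behavior block (10,000 permutations by default), the
  singular values recomputed each time, and per-LV p-values estimated with
  the add-one rule $(k + 1)/(n_{perm} + 1)$ — never exactly zero, with floor
  ≈ 1e-4 at 10,000 iterations. An LV is flagged significant when its
  observed singular value exceeds the 95th percentile of its permutation
  null. Permuting rows is the scheme that yields a valid null for
  brain–behavior covariance while preserving each block's internal
  structure; shuffling region labels within subjects would leave the
  singular-value spectrum of a correlation matrix essentially unchanged and
  produce no usable null.
* **Bootstrap ratios.** Subjects are resampled with replacement (10,000
  resamples by default); each replicate's saliences are sign-aligned per LV
  to the original solution using the sign of the combined dot product of the
  behavior and brain salience columns with the originals (the two sides of
  one LV must flip together). The BR is the original salience divided by the
  standard deviation (ddof = 1) of aligned replicate saliences, and features
  are flagged at strict $|BR| > 2$, the z-like convention approximating a
  95% confidence interval. Alignment is rank-wise only (no Procrustes
  rotation), which is a known limitation when singular values are closely
  spaced.
* **SVD sign convention.** The largest-magnitude element of each behavior
  salience column is made positive and the paired brain column follows, so
  results are deterministic across platforms.
* **Latent scores.** Subject scores are the standardized blocks projected
  onto an LV's saliences; group-mean confidence intervals are percentile
  bootstrap (2.5/97.5), resampling subjects within group. Percentile rather
  than normal-approximation intervals were chosen because group sizes of
  6–8 do not support a normality assumption on the mean.

The package's calibration suite verifies on simulation that (i) under a
global null the LV1 rejection rate of the 95th-percentile rule recovers that
percentile up to binomial Monte-Carlo error, and (ii) the share of
truly-null features with $|BR| < 2$ is close to the nominal 95% — slightly
below it, as expected for a ratio statistic with estimated denominator at
n = 100.

## Region co-activation networks

Within each group, pairwise-complete Pearson correlations are computed
between all region pairs, with two-sided p-values from the asymptotic
transform $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom (the
Fisher-z alternative was rejected to match the stated test). Pairs with
fewer than 4 complete observations are undefined. Heatmap masks use strict
$p < \alpha$.

Joined networks place all groups on a shared node set (regions with defined
correlations in every group) and, per group independently, retain the edges
with smallest p-values up to a target edge density (default 1.5% of all
possible pairs; ties broken by larger $|r|$, then lexicographic pair label,
for determinism — the thresholding provenance is recorded on the network).
Topology metrics treat the network as simple, undirected, unweighted:

* mean degree $2E/N$;
* global efficiency = mean over ordered pairs of $1/d(u,v)$, with
  disconnected pairs contributing 0;
* mean local clustering (triangles over possible; 0 for degree < 2);
* mean betweenness, pair-normalized by $(N-1)(N-2)/2$.

These conventions are stated because the metric names alone do not pin them
down. The threshold sweep evaluates the metrics on networks built at each
alpha of a grid over [0.001, 1] (default: 40 log-spaced points; the range is
prescribed, the spacing is not), using strict $p < \alpha$, so edge sets are
nested and mean degree is non-decreasing along the grid. Standard graph
algorithms are delegated to igraph; the test suite checks them against
brute-force shortest-path/triangle-counting oracles on exhaustively
enumerated small graphs.

## Hierarchical clustering of co-activity

Correlation matrices are converted to the dissimilarity
$d = 1 - |r|$: strongly positive *and* strongly negative correlations are
both short distances (co-regulated activity), uncorrelated regions sit at
the maximum of 1. Regions with any undefined pair are dropped first and
reported. Clustering is UPGMA (average linkage) via `stats::hclust`; ties in
merge heights are broken by `hclust`'s deterministic order (ties have
measure zero for the continuous dissimilarities this pipeline produces).
The elbow curve sums all within-cluster pairwise dissimilarities for each
k — the pairwise-sum definition is the only one requiring no embedding of
the regions — and attaches an advisory elbow at the maximum second
difference of the curve. The advisory value is deliberately not binding:
the elbow heuristic is a visual one, and with several equally sized planted
blocks the maximum-second-difference rule sits at the first large gap.

## Behavioral classification

Multinomial logistic regression (maximum likelihood with a negligible
L2 ridge of 1e-8, solely for numerical stability on separable data)
classifies subjects into group × time-of-day classes from behavioral
features. Cross-validation is stratified 8-fold with 200 repeats; features
are standardized inside each training fold (leakage-free), and held-out
class probabilities are pooled across repeats. The chance reference
shuffles class labels 50 times with 4 repeats per shuffle (200 randomized
repeats). Reports include the row-normalized confusion matrix (rows = true
class), one-vs-rest ROC curves pooled across repeats (pooling matches a
single curve per class rather than averaging per-repeat curves), and
per-class precision/recall/F1 with t-based confidence intervals over the
200 repeat-level values (mean ± t₍₁₋α/2, n−1₎·SE, α = 0.01). A repeat in
which a class receives no predictions has undefined F1; it is recorded as 0
and counted, a convention needed because an 8-fold split of small cohorts
can starve a class.

## Circadian rhythms and sleep architecture

Cosinor analysis fits $y = M + \beta_1\cos\omega t + \beta_2\sin\omega t$
($\omega = 2\pi/24\,h$) by least squares; amplitude is
$\sqrt{\beta_1^2+\beta_2^2}$ and acrophase $\mathrm{atan2}(\beta_2,\beta_1)
\cdot 24/2\pi$ wrapped into [0, 24) hours after lights-on (ZT0). A constant
trace has amplitude 0 and an undefined, NA-flagged acrophase. Traces are
activity in arbitrary units (typically 0–0.3) in 10-minute bins over 5 days.

Hypnogram statistics define a bout as a maximal run of identical state
labels. Phase boundaries are fixed at ZT0/ZT12 (12 h light/dark cycle);
when summarizing per phase, a bout crossing ZT12 is split and counted once
in each phase with the durations divided at the boundary. Transition counts
obey exact run-length identities (total transitions = bouts − 1;
transitions into a state = bouts of that state minus one if the record
starts there), which the tests assert exactly. The proprietary
piezo sleep/wake classifier is not re-implemented; the module consumes
already-scored hypnograms or sleep fractions.

## EEG spectra and sleep staging

Spectrograms are Hann-tapered one-sided periodograms over a 5-s window
stepped by 2 s (0.2 Hz resolution). Band limits are delta 0.1–4, theta
4–10, alpha 10–13, beta 13.1–30, gamma 30.1–50 Hz, kept exactly as
conventionally printed — grid points in the small (30, 30.1) gap belong to
neither band. Average spectra over a chosen set of bins are normalized by
the mean power across 0.1–50 Hz (the pre-log normalized power averages to
exactly 1 over that range) and log2-transformed; band power is the
trapezoidal AUC of the log2-normalized spectrum (the quantity conventionally
plotted), with the pre-log variant available behind a flag.

Staging follows the conventional qualitative criteria, made quantitative
with record-relative thresholds: per 2-s bin, EMG RMS, delta power and the
theta/delta ratio are z-scored over the record; EMG z above +0.5 SD gives
Wake, otherwise a theta/delta z above +1.0 SD gives REM, otherwise NREM,
with optional 3-bin majority smoothing. Both cutoffs are configurable.
Because the features are record-relative, staging presupposes a mixture of
states; a record consisting almost entirely of one state (no contrast for
the z-scores) will be scored poorly, and a feature with zero spread is
treated as uninformative (z = 0). The calibration suite checks end-to-end
recovery of generated ground-truth states on 1-hour records — long enough
to contain several bouts of each state at the generator's default dwell
times, which is the regime the thresholds are meant for.

## The synthetic-data generator

The generator produces datasets with exactly the second-moment structure
the pipelines consume, because PLSC and Pearson networks are second-moment
methods — any covariance-targeting generator suffices, and a Gaussian
factor model is the simplest one:

* **Brain–behavior cohorts**: per subject, `latent_rank` shared standard
  normal factors load (scaled by `latent_strength`) on designated behavior
  and region subsets plus independent noise (`noise_sd`, default 1).
  Region clusters with a target within-cluster correlation $t$ add a common
  factor with scale $s = \sigma\sqrt{t/(1-t)}$, from the closed-form factor
  correlation $t = s^2/(s^2+\sigma^2)$. Missingness is
  missing-completely-at-random in the region block only, matching the
  pipeline's MAR-imputation assumption. Defaults mirror the motivating
  study design: 4 groups (control/model × sunrise/sundown), 8 subjects per
  group, 137 regions. Activity magnitudes are arbitrary units around a
  baseline of 100 (per-region variance scales for real activity densities
  are not published); adding a constant leaves all correlation-based stages
  unchanged.
* **Class-separable behavior tables** for the classifier: designated
  "signal" features receive Gaussian class-mean shifts of scale
  `effect_size` (default 2 noise SDs — separable but not trivially so at
  10 subjects per class); the remaining features are pure noise.
* **Activity traces**: cosine plus Gaussian noise, clipped at 0, in
  10-minute bins; defaults (mesor 0.15, amplitude 0.1, acrophase ZT18,
  5 days) mimic piezo activity of a nocturnal animal.
* **Hypnograms**: a three-state semi-Markov chain with geometric dwell
  times (mean bout lengths: Wake 600 s, NREM 360 s, REM 90 s — typical
  murine scales) and phase-biased entry probabilities; REM is reachable
  only from NREM, so the transition set is exactly W-N, N-R, N-W, R-N,
  R-W. A non-finite REM dwell removes REM entirely. The phase bias acts on
  entry probabilities, not dwell times, so light/dark differences in total
  sleep are present but modest.
* **EEG/EMG**: per epoch, the EEG is frequency-domain-shaped Gaussian noise
  following the state's band-weight profile (NREM delta-dominant, REM
  theta-dominant, Wake broadband), scaled to a common RMS so states differ
  in spectral content rather than total power; the EMG is white noise at
  the state's RMS level (Wake 3, NREM 0.5, REM 0.3).
* **Trajectories**: a Metropolis random walk over the arena whose target
  density is the requested zone preference divided by zone area, so
  long-run occupancy converges to the preference itself. The nose keypoint
  leads the centroid along the heading and may cross open-arm edges, which
  is how head dips arise.

One user-facing integer seed fans out to fixed per-generator child streams
(a frozen MINSTD-style map), so every generator is bit-reproducible and
independent of the others.

What the generator does *not* emulate: raw microscopy, piezo pressure
waveforms, video, 1/f EEG background shape, non-Gaussian behavioral
distributions, or any group-level mean differences in regional activity.
Passing tests therefore establish that the algorithms are implemented
correctly and calibrated under their stated assumptions — not that those
assumptions hold in any particular animal dataset.

## Arena geometry

The open field is a 50 × 50 cm square on a 5 × 5 grid of 10 × 10 cm cells;
the central 3 × 3 block is the center zone. The elevated plus maze has four
26.5 × 8 cm arms around an 8 × 8 cm center; head-dip zones are 2-cm strips
bordering each long edge and the distal end of the open arms (the width is
a convention of this package — only the zones' existence is prescribed).
The absent-explorer screen excludes a trial only when *both* criteria hold:
≥ 180 consecutive seconds within 1 cm of a run-start position (the 1-cm
epsilon operationalizes "same position" and is configurable) *and* one zone
holding > 95% of the test time (> 285 s of a nominal 300 s trial). Frames
outside every zone are attributed to the nearest zone and counted, so zone
times always sum to the trial duration. Syllable frequencies are onset
events per second (with occupancy as a companion measure), optionally
log2-normalized against reference-group means; syllable transition matrices
exclude frame-to-frame persistence and are row-normalized.

## Numerical conventions and degenerate inputs

* p-value estimators are add-one, never zero; BR flags are strict
  (`|BR| > 2` excludes the boundary).
* Bootstrap replicates with a zero-variance column are redrawn (counted,
  capped), since a correlation is undefined there.
* Zero-variance columns in the input blocks are an error naming the column.
* A constant activity trace yields amplitude 0 and NA acrophase; a class
  with no predictions in a repeat yields F1 recorded as 0 with a flag;
  rows of a transition matrix with no outgoing transitions stay zero and
  are flagged.
* All simulation entry points take explicit integer seeds; identical seeds
  give bit-identical outputs.

## Problem sizes in the test suite

The calibration suite runs at desk scale: 200 null datasets × 1,000
permutations for the permutation-percentile check; 50 planted datasets ×
2,000 bootstrap resamples for BR coverage; 20 one-hour recordings for
staging recovery; 200-repeat cross-validation at 40 subjects for the
classifier ordering; exhaustive graph enumeration at ≤ 5 nodes plus 100
random graphs at ≤ 8 nodes for the topology oracles. These sizes were
chosen to put Monte-Carlo error well inside the asserted tolerances while
keeping the whole suite to a few minutes.

## Known limitations

* Bootstrap alignment is sign-only per LV; closely spaced singular values
  can rotate across replicates and inflate BR denominators.
* The BR ≈ z approximation is slightly anti-conservative at moderate n
  (null coverage just below 95% at n = 100), a property of the ratio
  statistic rather than of the implementation.
* Rule-based staging is record-relative and needs a state mixture; it is a
  stand-in for semi-automated scoring with manual validation, not a
  replacement.
* The elbow suggestion is advisory; k remains an analyst choice.
* Proportional thresholding keeps the top edges by p-value only; no
  multiple-comparison correction is applied or implied at the network
  stage.
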