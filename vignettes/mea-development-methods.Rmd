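---
title: "Methods: characterizing and predicting developing MEA network activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing and predicting developing MEA network activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(meadev)
```

`meadev` analyzes the spontaneous multi-channel spiking of cultured neuronal
networks on microelectrode arrays (MEAs) across early development (days in
vitro, DIV, 6–18), and predicts third-week activity from first-week
activity. This vignette documents the models and procedures, the parameters
that matter, the numerical conventions, and what the synthetic validation
cohorts do and do not establish.

## Input data and quality control

The unit of analysis is an `MEARecording`: per-channel sorted spike-time
vectors (seconds) from one dish on one DIV, nominally 60 channels and 300 s.
Spike times are quantized to the 0.04 ms grid of a 25 kHz acquisition system;
duplicates within a channel are coalesced. Channel ids are 1-based, and DIV
intervals (6–8, 9–12, 13–18) are inclusive on both ends.

Quality control mirrors standard acceptance practice for developing
cultures:

* a channel is **active** when it fires *strictly* more than 3 spikes/min;
* a recording qualifies with ≥ 10 active channels;
* a dish is kept when it has one qualifying recording at DIV 6–8 and at
  least one at DIV 9–18;
* a dish is discarded when any recording lists more than 6 excluded
  channels, or when the network spike rate drops by more than 50% between
  consecutive second-week recordings.

Two conventions required a decision. Noise-channel detection by waveform
shape needs raw voltage, which spike-time input does not carry; it is
replaced by an explicit per-recording channel exclusion list
(`# exclude=` metadata). And "a drop during the second week" is interpreted
as a comparison of consecutive recordings whose DIVs both fall in 9–14; an
extremum-based reading would reject more dishes and is not what a
consecutive-recordings log suggests.

## The 18 electrophysiological features

Features are means over channels or bursts, never spike-weighted. Features
that are undefined for a recording (e.g. burst statistics when no burst
exists) propagate as `NA` and are only imputed where a complete matrix is
required (PCA, regression), with a message.

**Bursts** use the max-interval method: scan inter-spike intervals (ISIs);
open a candidate burst at the first ISI ≤ 0.1 s; extend while ISIs ≤ 0.2 s;
merge candidates separated by < 0.2 s (spikes inside the merged gap join the
burst); finally require ≥ 3 spikes and ≥ 3 ms duration. Merging precedes the
size/duration filters, matching the reference implementation order of the
max-interval detector. The burst surprise is the Poisson surprise
`S = −ln P(X ≥ n)` with `X ~ Poisson(r_ch · T_burst)` and `r_ch` the
channel's overall rate; the logarithm base is configurable (natural log by
default) because the feature's original software does not document it.

**Network events** have no public definition in the original analysis
software, so the package documents its own and keeps it configurable: a
*network spike* is a maximal run of 100 ms bins in which ≥ 25% of active
channels fire; a *network burst* is a maximal interval during which
≥ max(2, 25% of bursting channels) single-channel bursts overlap.

**Synchrony.** The spike time tiling coefficient for trains A and B is

$$STTC = \frac{1}{2}\left(\frac{P_A - T_B}{1 - P_A T_B} +
\frac{P_B - T_A}{1 - P_B T_A}\right)$$

with Δt = 100 ms. `T_A` is computed as the exact union length of the
± Δt windows clipped to `[0, duration]`, divided by the duration — not a
binned approximation — and `P_A` by neighbor search in the sorted partner
train. Conventions: an empty train gives STTC = 0 (no measurable
correlation, and it keeps matrix means finite); a denominator of exactly 0
falls back to the other term (both degenerate → 0), with a message. The
matrix mean is over the strictly upper triangle of the active-channel
matrix. DBSCAN on the distance `1 − STTC` (eps 0.2, minimum 3 samples)
counts highly synchronized electrode clusters; by default a core point needs
3 neighbors *excluding itself*, but `selfCounting = TRUE` reproduces the
sklearn convention of the original analysis, since the two conventions
differ on 3-point groups and the source is ambiguous.

**Connectivity.** Spike counts in 100 ms bins; Pearson correlation for all
active-channel pairs; two-sided p-values from the exact t transform with
`nBins − 2` degrees of freedom (≈ 3000 bins, so the normal/t distinction is
immaterial); an undirected binary edge requires `p < 0.05` *and*
`|r| ≥ 0.35`. No multiple-comparison correction is applied, matching the
source analysis; with ~1770 pairs this inflates the edge count under the
null, which the weight threshold largely absorbs. Zero-variance count
vectors yield no edge. Node set = active channels, so isolated active
channels legitimately contribute degree 0; graph metrics are the mean
degree, the mean local clustering coefficient (0 where degree < 2), and
global efficiency (mean inverse shortest-path length over ordered pairs,
disconnected pairs contributing 0).

## Trajectory clustering

Per-dish trajectories are interval means of two representative network
features — bursting channels and mean STTC — at the three intervals
(a 6-dimensional vector), z-scored columnwise. The full 18-feature table is
used only for PCA overlays and cluster summary tables.

The self-organizing map is a 5 × 5 hexagonal lattice trained sequentially:
50 full passes, best-matching unit (BMU) by Euclidean distance, Gaussian
neighborhood. The learning rate decays linearly 0.05 → 0.01 and the radius
from 2/3 of the grid diameter to 1; these schedules are not fixed by the
procedure this package follows and are configurable — they are conventional
sequential-Kohonen defaults. Training is deterministic under a seed.

k-means (50 restarts) runs on the codebook vectors of *occupied* units
(BMU of ≥ 1 dish): the map's output cells are meaningful through the input
cases that activate them, and unoccupied interpolating units otherwise
distort model selection. Candidate k = 2…6. The Davies–Bouldin index

$$DB = \frac{1}{k}\sum_i \max_{j\neq i}\frac{\sigma_i + \sigma_j}{d(c_i, c_j)}$$

is evaluated on the *induced partition of the dish trajectories*, not on the
codebook points themselves: with only ~10–15 occupied units, unit-level DB
degenerates (singleton unit-clusters have σ = 0, biasing selection toward
large k), whereas the dish-level index scores the partition the analysis
actually reports. Coincident centroids give DB = ∞, so degenerate partitions
are never selected. On cohorts of 60 dishes the selected k is modally 3; a
single cohort occasionally splits one archetype into adjacent subgroups
(k = 4) without harming label agreement — at larger cohort sizes the
dish-level index is cleanly minimized at the programmed 3.

PCA on the z-scored 18-feature table reports percent explained variance,
feature contributions (100 × squared loading share per component), and the
significant-contribution reference line 100/p (5.55% for 18 features).
Zero-variance columns are dropped with a warning.

## Prediction of third-week features

Predictors are the 18 DIV 6–8 interval means; the target is the DIV 13–18
mean of STTC, bursting channels, or MFR. DIV 9–12 is deliberately excluded
from predictors: the question is what the *first week* determines. Dishes
lacking either interval are excluded; remaining missing cells are
mean-imputed columnwise. All scaling statistics are fit on training rows
only, and the train/test split (75/25) is at dish level so no dish leaks
across the split.

Hyperparameters are fixed, not searched: MARS with interaction degree 5 and
35 maximum terms; random forest with 100 trees and 8 candidates per split;
SVM with RBF kernel `k(x, y) = exp(−γ‖x − y‖²)`, γ = 0.125, C = 6 (the
"sigma" naming of some implementations maps to this γ). The SVM target is
standardized with training statistics and predictions back-transformed, as
the reference implementations do internally; without this, the fixed
ε-insensitive tube (0.1 in raw target units) would swallow small-scale
targets such as STTC. MARS is implemented in-package: greedy forward
selection of reflected hinge pairs multiplied into existing basis terms
(knot candidates thinned to ≤ 20 quantiles per predictor; forward pass stops
at the term budget or when the relative RSS gain falls below 1e-4), followed
by backward pruning under generalized cross-validation with the customary
penalty of 3 per knot for interaction models.

Evaluation: test R² = 1 − SS_res/SS_tot (undefined and flagged for a
constant test target), RMSE in target units, and REC curves (fraction of
test cases whose |error|, standardized by the s.d. of the observed test
targets, falls within a growing tolerance).

Feature-group importance balances four groups of two features each
(spikes: active channels + MFR; bursts: bursting channels + mean bursting
rate; synchrony: STTC + DBSCAN cluster count; connectivity: clustering
coefficient + efficiency). Strategies: all 18 features, the 8 group
features, leave-one-in (2 features), and leave-one-out (the 8 minus one
group — the balanced set, not all 18, is the base so that removals are
comparable). Each strategy is scored by SVM under fourfold cross-validation
repeated 10 times (40 out-of-fold R² values, reported with SEM); fold
assignments are shared across strategies so they differ only in the columns
they see. SMOTE (k = 20 nearest neighbors in the joint predictor + target
space, interpolation `row + λ·(neighbor − row)`, λ ~ U(0,1), ratio 2, target
interpolated jointly with the predictors since this is regression) augments
*training folds only* — synthetic rows never enter an evaluation fold, which
the implementation records and the tests assert.

## The synthetic cohort generator

No public recordings accompany the procedure this package implements, so
validation uses a generative model of dense-culture development with
recoverable ground truth. Per channel: homogeneous Poisson background at
`lambdaBg` Hz on `nActive` channels; network events as a Poisson process at
`nuNb` events/min, each recruiting active channels independently with
probability `pPart`; a recruited channel fires a burst of ~`burstLen` spikes
whose ISIs are a 2 ms refractory floor plus an exponential tail (mean
20–25 ms — well below the 0.1 s burst-opening threshold, while background
ISIs at < 1.6 Hz sit well above it), starting at the event time plus
Gaussian onset jitter (10–20 ms s.d.). A configurable number of
tightly-synchronized 5-electrode groups fire a shared source train with
0.5 ms spike jitter, emulating electrodes dominated by a common hub/unit;
these groups are what the STTC-DBSCAN cluster count recovers.

Three archetypes anchor each parameter at DIV 6 and DIV 18 (linear
interpolation between): (1) early-synchronized high-bursting, (2)
late-emerging synchrony — starting as sparse as archetype 3 in bursting but
distinguishable in rate and active-channel count, converging toward
archetype 1 by DIV 18, and (3) persistently sparse. This gives the three
trajectory clusters a triangular geometry (high→high, low→high, low→low)
rather than collinear grades, which is what makes the cluster count itself,
and not only the labels, recoverable.

Dish heterogeneity is a lognormal factor (s.d. 0.15 on the log scale)
multiplying rates (log-odds shift for `pPart`, proportional for `nActive`);
the third-week factor is the first-week factor times `exp(noiseLink · z)`,
log-interpolated across DIV 9–12. Week-3 activity is therefore a noisy
monotone function of week-1 activity *by construction*. `noiseLink = 0.1`
was calibrated once so that the oracle ceiling — the late-interval target
regressed on what week 1 determines (archetype and early dish factor) —
is ≈ 0.9; the ceiling, not the learner performance, was the calibration
target. The default schedule records each dish at DIV 7, 10 and 15 (one
recording per interval, matching the ~3 recordings/dish density of typical
developmental MEA datasets), 60 channels, 300 s.

Reproducibility: one cohort seed deterministically derives per-dish and
per-recording substream seeds by integer mixing, so cohorts are
bit-identical under a fixed seed and independent of iteration order.

**What the generator does not emulate:** raw voltage and waveform noise
(hence no waveform-based channel rejection), electrode-position effects,
within-recording nonstationarity (rates are homogeneous within 300 s),
burst-internal rate profiles (ISIs are i.i.d., real bursts accelerate then
adapt), culture-to-culture batch effects, and dish death or detachment.
Passing the validation suite therefore shows the *pipeline* recovers known
structure of this kind; it does not certify accuracy on any particular real
culture.

## Problem sizes and runtime choices

Validation runs use the generator's default study conditions: cohorts of 60
dishes × 3 DIVs × 60 channels × 300 s; 5 cohort seeds for cluster recovery;
10 seeds for rate-recovery checks; 200 random train pairs (0.1–5 Hz) for the
STTC oracle; 1000 fuzzed trains for burst invariants; 200 random ≤ 15-node
graphs and 100 random ≤ 20-channel matrices for the graph and DBSCAN
oracles. Oracle equivalence is asserted at 1e-10 (STTC) and 1e-12 (graph
metrics, Davies–Bouldin); rate recovery at 5% (MFR) and 15% (network-burst
rate at `pPart ≥ 0.85`), averaged over seeds.

## Known limitations

* Network spike/burst thresholds are package conventions; absolute values of
  those two features are not comparable to other software without matching
  the definitions.
* The Pearson edge test is uncorrected for ~1770 simultaneous pairs (by
  design, to match the source analysis).
* Davies–Bouldin model selection on 60-dish cohorts has finite-sample
  variance (occasionally k = 4); report the modal k across seeds when the
  cluster count itself is the question.
* The SVM with fixed γ and C is sensitive to the number of irrelevant
  feature dimensions; leave-one-out importance comparisons should be read
  against the 8-feature baseline, not the 18-feature one.
* A single 75/25 split has high variance at n ≈ 50 dishes; `evaluateModels`
  takes a seed so splits can be repeated externally.
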