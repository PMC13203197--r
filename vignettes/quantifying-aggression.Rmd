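---
title: "Quantifying crab aggression from pose tracks and classifier confidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying crab aggression from pose tracks and classifier confidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taiscore)
```

## The measurement problem

Aggressiveness in swimming crabs is a stable individual trait with direct
economic consequences in aquaculture (injury, limb loss, cannibalism).
The measurement pipeline this package supports replaces manual scoring of
resident–intruder trials with two upstream models: a pose-estimation
network that emits per-frame pixel coordinates and a likelihood for 13
anatomical landmarks (carapace spines, head, swimming-leg and cheliped
points), and a supervised classifier that emits a per-frame confidence
that the animal is performing each of three ethogram categories — anxious
behavior, demonstration displays, and fighting. `taiscore` takes those two
per-frame signals as its inputs. Training the upstream networks is out of
scope; the package consumes their standard CSV exports.

## From confidence traces to bouts

A bout is a maximal run of frames whose confidence strictly exceeds the
threshold (default 0.5 — frames at exactly 0.5 are excluded, since the
calling rule is "greater than") and that lasts at least the minimum bout
duration (default 180 ms). The millisecond minimum converts to frames with
a ceiling, `max(1, ceiling(ms/1000 * fps))` — 6 frames at 30 fps — because
a minimum duration is a bound the bout must meet, not round to. An
optional gap-merge step (off by default) can join runs separated by short
sub-threshold dips before length filtering, mirroring what some
classification toolkits do; it is disabled because the published
processing chain does not mention it.

One consequence worth knowing: total bout *duration* is monotone
non-increasing as the confidence threshold rises (the supra-threshold
frame set shrinks), but the bout *count* is not — an interior dip can
split one long bout into two shorter ones that both pass the length
filter. The test suite asserts the true invariant.

Frame indexing is 0-based with intervals inclusive at both ends, so
`duration_s = (end - start + 1)/fps`; this matches the
start-frame/end-frame/duration row layout of classifier bout exports.

## The Time-weighted Aggression Index

Per trial, with `D_anx`, `D_dem`, `D_fight` the per-category summed bout
durations, `T_first` the start time of the earliest fighting bout and
`T_total` the trial length:

$$\mathrm{TAI} = \frac{w_a D_{anx} + w_d D_{dem} + w_f D_{fight}}{T_{total}}
 + w_{lat}\,\frac{T_{total} - T_{first}}{T_{total}}$$

with default weights (0.14, 0.21, 0.35, 0.30), which sum to 1.00. Trials
with no fighting bout set `T_first = T_total`, so the latency reward term
is exactly zero and the index stays defined. Repeated trials (five per
individual by default) are averaged field-wise before the index is
computed.

Two deliberate decisions here:

* **Range.** The index is described upstream as 0–1 scaled, but with the
  default weights and temporally exclusive categories its supremum is
  0.65 (all time fighting, immediate first attack). The discrepancy
  resolves only if categories may overlap in time or an unstated
  rescaling is applied. The package implements the formula verbatim and
  offers `rescale_max = TRUE`, which divides by the configuration's
  attainable maximum; neither behavior is silently guessed as intent.
  Category traces are independent, so overlapping categories are
  permitted and durations are never cross-normalized.
* **Aggressive acts.** The frequency numerator counts bouts across all
  three categories by default — they are the three index components — but
  `aggregate_durations(count_behaviors =)` restricts it (e.g. to fighting
  only), since the upstream definition does not say which was meant.

`derive_weights()` re-derives the weights from data: OLS of frequency on
`D_anx`, `D_dem`, `D_fight` and the pre-transformed latency
`(T_total - T_first)` (so its coefficient is positively signed, matching
the reward term), intercept fitted and discarded, coefficients normalized
to sum to one in absolute value. That normalization is the one that
reproduces the published weight set and guarantees non-negative weights; a
negative duration coefficient survives only as magnitude and triggers a
warning. In the noiseless limit the generating ratios are recovered to
machine precision (a property the tests exercise), and at 5% response
noise with n = 200 each weight lands within ±0.02 of truth.

## Kinematic features from pose tracks

Keypoint observations below the likelihood threshold (default 0.95) are
marked missing; interior gaps of at most 5 frames are filled by linear
interpolation per coordinate, longer gaps and gaps touching either end of
the track stay missing — no extrapolation, and no rows are ever dropped.
The body centroid is the mean of the available carapace landmarks (LBODY,
RBOD, HEAD), valid only when at least two are present.

* **Relative movement distance (X1)** is the centroid path length over
  valid consecutive frame pairs divided by the median carapace width
  (LBODY–RBOD distance). The upstream literature uses this feature
  without defining its normalization; carapace width is the only size
  proxy available from the landmark schema, makes the feature
  dimensionless and cancels camera scale (the tests verify invariance to
  translation, rotation and uniform rescaling). The choice is exposed in
  configuration.
* **Freezing duration (X2)** totals maximal runs where centroid speed
  (central difference over valid neighbors, one-sided at the ends) stays
  below 0.2 carapace widths/s for at least 2 s. These two thresholds are
  module defaults, not published values — freezing is not operationally
  defined upstream — and both are configurable.
* **Keypoint error** (mean ± SD Euclidean pixel distance against manual
  annotation, with a per-keypoint breakdown) reproduces the evaluation
  metric used for pose-model accuracy.

The external reference model `Y = 0.023 X1 − 0.001 X2 − 0.002` consumes
these features and serves as the comparison method in the agreement
battery (z-scored on both sides, Pearson R, two-way consistency ICC,
Bland–Altman).

## Validation statistics

* **Stratification**: the `floor(0.25 n)` largest index scores form HA,
  the `floor(0.25 n)` smallest LA, the rest MA — 50/100/50 at n = 200.
  Boundary ties are broken by stable input order, which makes the
  partition deterministic; a normality gate (Shapiro–Wilk by default,
  Kolmogorov–Smirnov selectable) documents whether the quartile split
  sits on an approximately normal distribution.
* **ICC**: ICC(C,1) and ICC(C,K) come from the two-way mean-square
  decomposition, `(MS_R − MS_E)/(MS_R + (k−1) MS_E)` and
  `(MS_R − MS_E)/MS_R`, with F-based confidence intervals. The direct
  average-measure value and the Spearman–Brown transform of the
  single-measure value agree to 1e-12 (tested); the published pair
  0.554 → 0.713 is the instant check.
* **Bland–Altman**: mean difference, 1.96·SD limits, CI of the mean
  difference and the fraction of points inside the limits (≈95% for
  normal differences; tested at n = 10,000).
* **Clustering**: k-means (10 restarts, best inertia) on z-scored
  (TAI, 5-HT) with mean silhouette; bootstrap Jaccard stability matches
  each original cluster to its best counterpart per resample (B = 100
  default), computed on the resampled multiset. On six points the
  assignment equals an exhaustive minimization over all 2-partitions
  (tested).
* **Pairing trials**: tie-corrected Kruskal–Wallis (df = contexts − 1),
  Dunn's pairwise z from mean ranks with the tie-corrected variance, and
  Bonferroni adjustment over all pairwise comparisons — implemented
  directly since no post-hoc package is among the dependencies, and
  checked against the hand rank-formula statistic.

## The synthetic cohort generator

No behavioral videos or assay tables ship with the package, so the
generator reproduces the statistical structure the analysis assumes:

* A latent aggressiveness `a` per individual, normal (mean 0.5, SD 0.15)
  clipped to [0, 1]. Mean category durations rise linearly in `a` (maxima
  240/300/420 s for anxious/demonstration/fighting at `a = 1`, i.e. at
  most ~53% of the trial in scored behavior), mean first-attack latency
  falls linearly (to 15% of the trial at `a = 1`), locomotion speed rises
  and freezing propensity falls. Because the index is close to linear in
  these quantities, the induced TAI distribution is approximately normal:
  across seeds the Shapiro–Wilk gate stays parametric in well over 90% of
  cohorts (tested over 20 seeds).
* Frame-level trials run an independent two-state renewal process per
  category (exponential dwell times; mean bout 4 s) whose occupancy
  matches the profile's mean duration, with the first fighting off-dwell
  drawn around the profile latency. Classifier confidence sits near 0.9
  inside true bouts and 0.1 outside (±0.05 jitter). The pose track is a
  correlated random walk with fighting-elevated speed, freezing spells,
  a rigid 13-keypoint layout at 50 px carapace width, and occasional
  likelihood dropouts.
* Hemolymph serotonin follows `40 + 120 a` ng/mL with SD-8 noise for the
  concordant majority. A 20% discordant subcluster, drawn from the lower
  half of `a`, receives the serotonin level of a highly aggressive animal
  plus 55 ng/mL. This construction makes k-means on the z-scored
  (TAI, 5-HT) plane recover the 20% minority with silhouette ≈ 0.5 and
  bootstrap Jaccard well above 0.75 — the cluster geometry of the assay.
  The trade-off is honest and documented: the *pooled* TAI–serotonin
  correlation is diluted toward zero by the discordant block, weaker than
  the clearly positive pooled correlation seen in real cohorts. Passing
  cluster tests on this generator therefore demonstrates the clustering
  machinery, not the field correlation structure.
* Pairing-trial attack counts are negative binomial (size 3; the assay's
  SDs exceed its means) with context means 7.08 (H-H), 0.96 (L-L), 2.41
  (H-L), 2.25 (M-M) and structural zero inflation 0.48 for L-L. The
  zero-inflation parameter is the structural zero probability; for
  `pi < 1` the NB mean is scaled by `1/(1 - pi)` so the configured mean
  is the marginal mean, and `pi = 1` degenerates to all-zero counts.
* Determinism: every generator derives a fixed substream seed from the
  top-level seed and the individual id, so results do not depend on
  iteration order.

What the generator does *not* emulate: two-animal interaction geometry
(the pose track is one centroid process, not two bodies in contact),
classifier confusion structure between similar categories, molt/size/sex
covariates, and day-to-day drift across the five repeats (repeats are
exchangeable draws). Conclusions from passing tests transfer to real data
only insofar as those simplifications are irrelevant to the statistic
under test.

## Numerical conventions and degenerate inputs

Strict `>` at the confidence threshold; ceiling conversion of the minimum
bout duration; per-category duration clipping to `T_total` with no
cross-category renormalization; `T_first = T_total` for attack-free
trials; stable-order tie-breaking in stratification; missing keypoints
encoded as NA coordinates with likelihood 0 rather than dropped rows;
zero-variance inputs to z-scores, correlations and normality tests are
errors, not NaNs; rank-deficient weight designs fail naming the offending
predictor. Durations in bout files are validated against the frame
interval at 1 ms tolerance on read.

## Problem sizes

The test suite and acceptance script work at desk scale by choice:
frame-level simulations use 20–60 s trials (full 30-minute geometry is
exercised once to pin the 54,000-frame contract), cohort statistics use
n = 200–500, Monte-Carlo property checks use 10–25 replicates or 10,000
draws where a distributional fraction is asserted, and bootstrap
stability uses B = 50–100. The statistics of interest are invariant to
these sizes; the vignette states them so results are reproducible as
printed.

## Known limitations

The pooled serotonin correlation caveat above; freezing and relative-
distance definitions are documented guesses where the upstream literature
is silent; the index's 0–1 claim is unresolved and both behaviors are
exposed; Dunn's test uses the normal approximation (no exact small-sample
p), and no multiple-testing control beyond Bonferroni is offered.
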