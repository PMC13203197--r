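# taiscore

Quantitative scoring of aggression in swimming crabs (*Portunus
trituberculatus*) from machine-learning behavioral pipelines.

Aggression is a consistent individual trait in decapod crustaceans, and in
commercial crab farming it is an expensive one: fighting causes injury, limb
loss and cannibalism. Modern pipelines replace manual scoring with
markerless pose estimation (per-frame keypoint coordinates with a
likelihood) and supervised behavior classification (per-frame confidence
that the animal is performing each ethogram category). `taiscore` implements
everything downstream of those models for the resident–intruder assay: it
turns classifier confidence traces into discrete behavioral bouts, computes
per-trial durations, first-attack latency and pose-derived kinematic
features, combines them into a single **Time-weighted Aggression Index
(TAI)**, stratifies a cohort into aggression groups, and runs the full
validation battery (method agreement, serotonin clustering, pairing-trial
statistics). A synthetic-cohort generator with the same statistical
structure as the assay makes every stage testable without video data.

## The index

For one 30-minute trial (`T_total = 1800` s at 30 fps), bouts are maximal
runs of frames whose classifier confidence strictly exceeds 0.5, lasting at
least 180 ms (6 frames). With `D_anx`, `D_dem`, `D_fight` the summed bout
durations of the three scored categories and `T_first` the start time of
the earliest fighting bout (`T_total` if none):

```
TAI = (0.14 D_anx + 0.21 D_dem + 0.35 D_fight) / T_total
      + 0.30 (T_total - T_first) / T_total
```

The four weights are re-derivable from data: aggression frequency (bouts
per second) is regressed by OLS on the three durations and the transformed
latency `(T_total - T_first)`, and the coefficients are normalized to sum
to one in absolute value (`derive_weights()`).

Supporting statistics: quartile stratification (top 25% HA / bottom 25% LA
/ middle 50% MA), Shapiro–Wilk normality gating, Pearson/Spearman
correlation, two-way consistency ICC with the single-to-average
(Spearman–Brown) relation, Bland–Altman limits of agreement, k-means with
silhouette and bootstrap-Jaccard stability for TAI × hemolymph serotonin,
and Kruskal–Wallis with Dunn/Bonferroni post hoc for pairing-trial attack
counts.

## Worked example

Score one simulated trial, then analyse a 200-animal cohort:

```r
library(taiscore)

params   <- sim_params(n = 12, t_total = 60, seed = 42)  # short demo trials
profiles <- generate_profiles(params)
cfg      <- tai_config(trial_duration_s = 60)

trial <- simulate_trial(profiles[7, ], params)
bouts <- extract_bouts(trial$trace, "all", cfg)
head(bouts, 4)
#> # A tibble: 4 × 5
#>   behavior      start_frame end_frame duration_s mean_confidence
#>   <chr>               <int>     <int>      <dbl>           <dbl>
#> 1 demonstration         181       919     24.6             0.901
#> 2 demonstration        1324      1336      0.433           0.893
#> 3 fighting              237       298      2.07            0.898
#> 4 fighting              330       379      1.67            0.898

filtered <- filter_low_likelihood(trial$pose)
summ <- summarize_trial(
  bouts, cfg,
  x1 = relative_movement_distance(filtered, cfg),
  x2 = freezing_duration(filtered, cfg)
)
compute_tai(summ)
#> [1] 0.3700111
```

This crab spent 25.1 s in demonstration and 3.7 s fighting, attacked
7.9 s into the trial, and covered 51.9 carapace widths — a moderately
aggressive score of 0.37 (on the published-weights scale, whose maximum
with temporally exclusive categories is 0.65).

Cohort level:

```r
cohort <- simulate_cohort(sim_params(n = 200, seed = 1))
cohort$group <- stratify(cohort$tai)
table(cohort$group)
#>  HA  MA  LA
#>  50 100  50

z  <- cbind(tai = zscore(cohort$tai), ht = zscore(cohort$ht_ng_ml))
km <- kmeans_silhouette(z, k = 2, seed = 1)
km
#> k-means (k = 2): sizes 160/40 (80.0%/20.0%), silhouette 0.56
bootstrap_jaccard(z, km$labels, B = 100, seed = 1)
#> # A tibble: 2 × 3
#>   cluster mean_jaccard n_resamples
#>     <int>        <dbl>       <dbl>
#> 1       1        0.960         100
#> 2       2        0.940         100
```

The cohort splits into the expected 50/100/50 aggression groups; the
serotonin plane resolves into a large concordant cluster (80%) and a small
high-serotonin/low-aggression cluster (20%), both stable under bootstrap
(Jaccard > 0.75). `pairing_analysis()` on `simulate_pairing_trials()`
output gives the Kruskal–Wallis H, Dunn z and Bonferroni-adjusted p per
context pair; `autoplot()` methods and `plot_*()` helpers draw the
Bland–Altman, cluster, distribution and bout figures.

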