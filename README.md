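# laggedsense

Lagged repeated-measures correlation of smartphone sensing and symptom
change.

`laggedsense` is an R implementation of a digital-phenotyping analysis
pipeline for longitudinal studies in which participants carry a smartphone
that passively records GPS fixes, call/SMS logs and foreground apps, while
completing depression (PHQ-8), generalized-anxiety (GAD-7) and
social-anxiety (SPIN) questionnaires every three weeks over 16 weeks. The
scientific question the pipeline addresses is *temporal ordering*: do
changes in sensed behavior precede changes in symptom severity, or the
reverse?

The pipeline:

1. **Sensor features.** Seven GPS mobility features per two-week window
   (location variance, visited location clusters, location entropy and its
   normalized form, circadian movement via the Lomb periodogram, distance
   traveled, average velocity), daily semantic-location dwell minutes (with
   participant-provided labels propagated from assessment weeks), daily
   call/SMS aggregates and app-category minutes.
2. **Feature groups.** Every base feature is standardized across the full
   sample and averaged into 14 unit-weighted groups (*Locations*, *Time*,
   *Transitions*, six semantic-location durations, *Calls*, *Text
   Messages*, and three app categories).
3. **Symptom clusters.** k-means on the 32 baseline questionnaire items
   (8 + 7 + 17) with elbow-based selection of k, yielding symptom-profile
   subgroups (minimal symptoms; depression + social anxiety; depression +
   anxiety; multiple comorbidities).
4. **Lagged inference.** For consecutive check-ins, change pairs
   (ΔSn, ΔSx) are formed where the sensor window strictly precedes the
   symptom reports (direction sensor→symptom), or strictly follows them
   (symptom→sensor, using the proceeding windows ΔSn′). The association is
   the repeated-measures correlation — an ANCOVA of y on x with one
   intercept per participant and a single shared slope:

   r_rm = sign(b) · sqrt( SS_x / (SS_x + SS_residual) ),  df = N − n − 1,

   with Benjamini–Hochberg FDR correction within each measure × subgroup ×
   direction family of 14 feature groups. A single missing assessment in a
   pair is replaced by the participant's mean of observed scores; pairs
   with both assessments missing, or missing sensor windows, are dropped.

Because raw cohorts of this kind are rarely shareable, the package includes
a first-class synthetic-cohort generator (`generate_cohort()` for raw event
streams, `generate_window_cohort()` for feature-window level data) with a
calibrated lagged coupling `coupling_rho` between behavior change and
subsequent symptom change, an optional reverse coupling, and
missing-not-at-random assessment dropout — so every stage of the pipeline
can be validated against known ground truth.

## Worked example

Simulate a 200-participant cohort in which a drop in the *Locations*
feature group precedes a rise in depression severity (coupling −0.3),
cluster participants on baseline items, and run the lagged analysis:

```r
library(laggedsense)
library(dplyr)

cfg <- sim_config(n_participants = 200, coupling_rho = -0.3,
                  coupling_group = "locations", seed = 20)
cohort <- generate_window_cohort(cfg)

items    <- baseline_item_matrix(cohort$assessments)
clusters <- assign_clusters(items, k = 4, seed = 20)
clusters$means
#> # A tibble: 4 × 5
#>   cluster  phq8  gad7  spin cluster_name
#>     <int> <dbl> <dbl> <dbl> <chr>
#> 1       1  2.80  3.16  10.3 minimal_symptom
#> 2       2 11.7   4.76  38.4 depression_social_anxiety
#> 3       3 15.6  12.1   15.4 depression_anxiety
#> 4       4 17.5  14.9   47.4 multiple_comorbidities

results <- run_lagged_analysis(cohort$windows, cohort$assessments,
                               clusters$assignments, measures = "PHQ8")
results |>
  filter(frame == "full_sample", group == "locations") |>
  select(group, direction, n_participants, dof_inference, r_rm, p_raw, p_bh)
#>   group     direction     n_participants dof_inference    r_rm    p_raw     p_bh
#> 1 locations sensor->symp…            200           799 -0.316  4.31e-20 6.04e-19
#> 2 locations symptom->sen…            200           599 -0.0577 1.57e- 1 7.54e- 1
```

The forward direction recovers the injected coupling (−0.32, FDR-corrected
p ≈ 6e−19: behavior change predicts subsequent symptom change), while the
reverse direction is null (−0.06, corrected p ≈ 0.75) — the directional
specificity the lag design is built to detect. The design sample size for
detecting |ρ| = 0.2 at α = .05 and power .90:

```r
power_sample_size(0.2, alpha = 0.05, power = 0.90)
#> [1] 255
```

For raw event streams instead of feature windows, use `generate_cohort()`
and `extract_feature_windows()`; `save_cohort()`/`load_cohort()` read and
write a per-participant CSV layout with schema validation.

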