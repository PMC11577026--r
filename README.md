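# territr

Quantitative analysis of territorial dominance in pairs of laboratory mice.

When two unfamiliar male mice share a large two-compartment arena
(120 × 120 cm overall, connected by a 4 cm passage), a dyadic hierarchy
typically emerges within two hours: one animal attacks, chases, explores and
urine-marks the whole arena while the other flees, rears defensively and
retreats to refuges. `territr` turns the raw records of such a session —
multi-animal pose tracks (45 fps), a manually scored ethogram, and
photographs of the dye-marked floor — into the standard measures of that
hierarchy and infers per-pair dominance ranks.

## What it computes

* **ROI dwell metrics** from pose tracks: hiding (time in 12 refuge ROIs,
  after discarding occupancy bouts < 1 s), exploration (time in the
  opponent's compartment minus its refuges), proximity (< 10 cm apart within
  the same ROI), and locomotion (path length, cm).
* **Ethogram statistics**: counts of attack / chase / flight / upright per
  phase, within-pair difference scores and their evolution across 10-min
  subintervals, and attack penetrance per cohort.
* **Flight-aligned kinematics**: for each flight, the frame of steepest
  speed slope inside a −30/+60 s search window is found, an 8-s window is
  centered there, and speed and distance windows pooled over all flights are
  averaged frame by frame (mean ± SEM).
* **Dominance score**: the seven behaviors (attacks, chases, flights,
  uprights, locomotion, exploration and hiding fractions) are z-scored
  across the pooled cohort and decomposed by PCA; the pair member with the
  higher PC1 score (signs oriented so the attack loading is positive) is
  labeled dominant.
* **Re-pairing permutation test**: the mean absolute within-pair difference
  is compared against a null built from uniformly random perfect matchings
  of the cohort — enumerated exhaustively for cohorts of ≤ 10 mice, sampled
  otherwise; `p = #(null ≥ observed) / n`.
* **Urine marking**: yellow (fluorescein) and fuchsia (erythrosin b) marks
  are segmented from floor photographs by a deterministic hue/saturation
  classifier with white-balance normalization and minimum-blob cleanup, and
  reported as percent of arena area per animal.
* **Synthetic cohorts**: a seeded generator produces pose tracks, event
  tables and floor images with planted ground truth (ramping rank-dependent
  rates, flight bursts > 50 cm/s, hide bouts, mark areas), so every stage is
  testable without recordings.

## Worked example

```r
library(territr)

res <- run_pipeline(list(seed = 7, n_pairs = 4, n_perm = 500,
                         kinematics = FALSE, marking = FALSE))
res$pca
#> <dominance_result> 8 mice, PC1 96.5% / PC2 2.0% variance
res$ranks
#>   pair_id  dominant subordinate pc1_diff  tied
#> 1  pair01 pair01_m2   pair01_m1 5.044820 FALSE
#> 2  pair02 pair02_m1   pair02_m2 4.662750 FALSE
#> 3  pair03 pair03_m2   pair03_m1 4.574051 FALSE
#> 4  pair04 pair04_m2   pair04_m1 5.047903 FALSE
res$permutation$attacks
#> <permutation_result> attacks: observed |diff| = 20.5, p = 0.2286
#>   (exhaustive, 105 permutations)
round(res$correlations$r["attacks", ], 2)
#>          attacks           chases          flights         uprights
#>             1.00             0.97            -0.94            -0.93
#>    locomotion_cm exploration_frac      hiding_frac
#>             0.94             0.92            -0.94
res$recovery
#> [1] 1
```

Reading: on this fully divergent synthetic cohort of 4 pairs, PC1 absorbs
96.5% of behavioral variance and separates every pair cleanly (PC1
differences ≈ 4.6–5.0); all four planted dominants are recovered
(`recovery = 1`). Attacks correlate positively with chases, locomotion and
exploration and negatively with flights, uprights and hiding — the
aggressive/explorative versus defensive/hiding axis. The attack asymmetry
(mean |difference| 20.5 per 20 min) sits at the p-value floor of an 8-mouse
exhaustive matching null (24/105 ≈ 0.23): rejection at α = 0.05 needs
cohorts near the study size of 10 pairs.

Individual stages are available directly: `default_layout()`,
`read_pose_table()`, `clean_track()`, `hiding_time()`, `exploration_time()`,
`proximity_time()`, `flight_aligned_kinematics()`, `zscore_behaviors()`,
`dominance_pca()`, `assign_ranks()`, `repairing_permutation_test()`,
`segment_dyes()`, `percent_marked_area()`, `simulate_cohort()`. See the
vignette (`vignettes/territory-analysis.Rmd`) for the methods and the
conventions behind each.

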