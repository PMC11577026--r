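---
title: "Quantifying dyadic territorial dominance in laboratory mice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic territorial dominance in laboratory mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(territr)
```

## The assay and what the package computes

Two unfamiliar male mice, each habituated for two days in one compartment of
a 120 x 120 cm two-compartment arena connected by a 4 cm passage, interact
freely for two hours after the dividing gate opens. Over that time a pairwise
hierarchy typically emerges: one animal (the dominant) attacks, chases,
patrols and marks the whole arena, while the other (the subordinate) flees,
adopts defensive upright postures, and retreats to refuges — the compartment
corners and the tops of the central home cages and food columns.

`territr` turns the raw records of such a session — multi-animal pose tracks
at 45 frames/s, a manually scored ethogram, and post-session photographs of
the dye-marked floor — into the quantitative measures of that hierarchy, and
infers per-pair dominance ranks from them. Because real recordings are bulky
and rarely shareable, the package also ships a seeded synthetic-cohort
generator with planted ground truth, so the entire pipeline is exercised and
tested without any external data.

## Trajectory measures

The arena is described by a set of polygonal ROIs in a fixed frame (origin
at the outer top-left corner, x rightward, y downward, cm — the geometry of
overhead video). `default_layout()` builds the canonical apparatus; twelve
ROIs are refuges: the eight 8 x 8 cm compartment corners, the two cage-top
footprints (the water-dispenser top is part of the cage top) and the two
food-column tops. Boundary points count as inside, which makes membership
deterministic on ROI edges.

Occupancy is processed as *bouts* — maximal runs of consecutive frames inside
an ROI, on half-open 0-based frame intervals — and bouts shorter than one
second are discarded per ROI before anything is summed. This mirrors the
artifact-rejection step used on raw tracking output: spurious one-or-two
frame excursions of a jittery keypoint should not count as refuge visits. A
bout of exactly 1 s (45 frames) is kept. Durations are counted in whole
frames and divided by the frame rate once, so no floating-point accumulation
occurs.

On top of the bout filter the package computes, per mouse and phase:

* **hiding** — time in the union of the 12 refuge ROIs, overlap counted once
  per frame (the food top lies inside the cage footprint);
* **exploration** — time in the opponent's compartment minus time in that
  compartment's refuges; never negative by construction;
* **proximity** — time the two anchors are closer than 10 cm (strict `<`)
  while both animals occupy the same member of the proximity ROI set (each
  compartment, cage top and food top);
* **locomotion** — summed anchor displacement between consecutive frames,
  skipping (not bridging) missing frames.

Tracking cleanup (`clean_track()`) sets samples below a confidence threshold
missing, linearly interpolates missing runs up to a maximum gap, and smooths
with a centered moving average. None of these parameters are published for
the original assay; the package defaults — threshold 0.6, gap 0.5 s, 5-frame
window — are stated as package conventions, exposed in the configuration and
recorded in the run metadata. The occupancy anchor defaults to the middle
back, the most stable centroid-like body part; proximity is measured middle
back to middle back. Both are configurable.

A note on geometry: tracking is 2-D from overhead video, so "on top of the
cage" and "inside the cage" are indistinguishable; cage-top and food-top
ROIs are the 2-D structure footprints, which is a documented approximation.

## Ethogram analysis

Scored events carry a fixed vocabulary (attack, chase, flight, upright) with
onset/offset times. Events are assigned to analysis windows by onset, so an
event straddling a boundary counts once, in its onset window; with that
convention per-subinterval counts conserve the phase total exactly. The
early phase is minutes 0–20. The late phase defaults to the last 20 minutes
of the session, with a 100–110 min variant selectable (`phase_windows()`):
the source material describes both and the package asserts neither as
canonical.

Flight kinematics follow the peri-event averaging procedure: for every
flight, the speed trace is searched in an asymmetric window (30 s before to
60 s after onset) for the frame of steepest positive slope of the smoothed
speed — the moment of maximum acceleration — and an 8-s symmetric window is
centered there. Speed and distance windows from the same centers, pooled
over all flights of all mice, are averaged frame by frame, missing-aware.
Numerical choices: slope is a centered finite difference after a 0.5 s
moving-average smooth (the smoothing span is not published; 0.5 s suppresses
frame noise without displacing a ~1 s acceleration peak); ties break to the
earliest frame; windows partially outside the recording contribute their
available frames, and only fully-outside flights are skipped (and reported).
A single contributing flight has no dispersion, so its SEM is 0 by
convention.

## Dominance inference

Each mouse in a cohort is summarized by seven behaviors in one phase:
attacks, chases, flights, upright postures (counts), locomotion (cm), and
exploration and hiding as fractions of the phase. The columns are z-scored
across *all* mice pooled over strains, so strains share one normalization.
The package uses the sample (n−1) SD by default with a population-SD switch;
the published analysis does not state which it used.

A PCA of the standardized matrix (eigen-decomposition of its covariance via
`prcomp`) yields components ordered by explained variance; in divergent
cohorts the first component separates the aggressive/explorative profile
from the fleeing/hiding profile. Component signs are arbitrary in any PCA,
so the package orients PC1 and PC2 deterministically with the attack loading
positive; "higher PC1" then always reads "more dominant". The pair member
with the higher PC1 score is labeled dominant; exact ties are flagged rather
than broken arbitrarily, and the reported PC1 difference is dominant minus
subordinate.

Whether within-pair asymmetry exceeds chance is judged with the re-pairing
permutation test: the statistic is the mean over true pairs of the absolute
within-pair difference, and the null re-draws a uniformly random perfect
matching of the whole cohort into artificial pairs. The p-value is the
fraction of null draws **at least as large as** the observed statistic. The
`>=` convention (rather than a literal strict `>`) keeps the p-value a valid
test level: identical values give p = 1, and exhaustive enumeration can
never give p = 0 because the observed matching is itself enumerated. No
add-one smoothing is applied to sampled p-values, so a sampled p can be 0 —
a documented divergence from common practice, kept because the estimator is
then exactly the stated fraction. For cohorts of up to 10 mice (at most
10,005 distinct matchings, i.e. 9!! = 945 at n = 10) the null is enumerated
exhaustively and the test is exact; larger cohorts are sampled with a
recorded seed.

One structural property of this statistic deserves note: every matching that
pairs the k lowest cohort values with the k highest yields the *same* mean
absolute difference (the sum of the highs minus the sum of the lows), so the
null distribution is discrete with large atoms at its extreme. For an
8-mouse cohort the p-value can never fall below 24/105 ≈ 0.23; meaningful
rejection at alpha = 0.05 needs cohorts around the study's size (10 pairs),
where the test is well calibrated — the suite verifies its empirical type-I
error over 500 simulated null cohorts of 20 mice.

Correlation matrices among the behaviors default to Pearson (Spearman
selectable) with a per-cell significance mask at alpha = 0.05 and **no**
multiple-testing correction, matching the descriptive use of these matrices;
the adjustment method is recorded in the output metadata so a corrected
variant is one argument away. Group contrasts delegate to `wilcox.test` and
`kruskal.test`; Dunn's pairwise post hoc is computed from the standard
rank-sum z statistic with tie correction and Bonferroni adjustment (no
dedicated implementation is declared as a dependency). Two degenerate-input
conventions: all-zero paired differences give Wilcoxon p = 1, and an
all-identical Kruskal–Wallis input gives H = 0, p = 1.

## Urine marking

Each pair member carries a different systemic dye (fluorescein, yellow-green
in urine; erythrosin b, pink-red), so one photograph of the floor separates
the two animals' marks. The package segments marks with a deterministic
rule classifier: per-channel white-balance normalization against the bright
floor background (95th-percentile scaling), then hue/saturation/value
windows — yellow-green hue 0.10–0.33 for fluorescein, wrap-around 0.83–0.05
for erythrosin, saturation ≥ 0.25, value ≥ 0.15 — followed by removal of
blobs smaller than 0.05 cm² (8-connected components). A pixel satisfying
both hue windows is assigned to the nearer hue centroid. This replaces the
interactively trained pixel classifier used in the original workflow:
reproducibility is preferred over fidelity to a particular trained model,
and an externally computed per-pixel probability raster can be supplied to
`segment_dyes()` by users who train their own. Marking per animal is
reported as the percentage of the arena mask area, plus blob counts and
sizes. Dye doses, latency and persistence are carried as metadata constants
(`dye_protocol`) and play no computational role.

## The synthetic generator

`cohort_spec()` defaults encode the study conditions: 120-min sessions at
45 fps, early/late 20-min phases, and a CD1-like divergence profile. Event
rates per 20 min ramp linearly from parity at gate opening to their full
split at 100 min; the dominant's late attack rate is calibrated to 22.8 per
20 min (the published CD1 figure) with the subordinate's rate floored at
zero, and flights/uprights mirror to the subordinate. Movement is a
two-mode (roam/hide) correlated random walk: roaming at a mean 8 cm/s
(safely under the 20 cm/s baseline ceiling), hide bouts parked inside
corner refuges with rank- and time-dependent rate and duration, flight
dashes with a triangular speed profile peaking at 60 cm/s within ~0.5 s of
onset — the assay's kinematic signature of speeds above 50 cm/s. The
divergence parameter scales all asymmetries: 0 is a null cohort (parity
throughout, as in the non-hierarchical inbred strain), 1 full divergence.
Marked-area targets are 3% (dominant) vs 0.2% (subordinate) at full
divergence. Per-pair seeds derive from the cohort seed as
`seed * 10000 + pair index`, so cohorts are reproducible and pairs
independent.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: identity swaps and occlusion structure of real
multi-animal tracking (dropouts are short and random here), the closed-loop
coupling of the two animals during fights, posture change during uprights,
non-stationary lighting or camera distortion in floor photographs, and any
fitted correspondence to real recordings. It is a test harness with planted
truth, not a behavioral model.

## Problem sizes and verification

The test suite verifies each operation against independent oracles:
brute-force point-in-polygon on random points, run-length-encoded bouts,
windowed-mean convolutions, closed-form chord speeds, hand-computed
schedules for the occupancy metrics, exhaustive enumeration of all perfect
matchings for the permutation test (cohorts of 4 and 6), a closed-form 2x2
eigen-solve for the PCA, and rendered ground-truth rasters for the dye
segmentation (recovery within 2% relative error). Calibration properties
use 500 simulated null cohorts (type-I error within the binomial CI of
alpha = 0.05) and 20-pair synthetic cohorts for rank recovery (>= 95% at
full divergence, chance at zero divergence). The acceptance script
(`scripts/acceptance.R`) re-runs 10-pair cohorts end to end; these sizes
give stable statistics at a few minutes of runtime on one core.

## Known limitations

* All geometry is 2-D; on-top versus inside a structure cannot be
  distinguished, and callers needing to exclude cage interiors must adapt
  the layout.
* The exact corner-ROI placement and the cage footprint (25 x 25 cm default)
  are assumptions, flagged in the shipped layout, since the printed
  apparatus description does not fix them.
* The locomotion convention (skip, don't bridge, missing frames) is one of
  several defensible readings of "total path length"; it is documented and
  applied consistently.
* The rule-based dye classifier is tuned for the two dye hues against a
  near-white floor under reasonable white balance; strongly colored floors
  or lighting require retuned hue windows or an external probability raster.
* The behavior-matrix spreadsheet import reads the package's long-CSV
  export format; a binary spreadsheet must be exported to CSV first.
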