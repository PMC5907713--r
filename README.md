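# pelviclust

Sub-grouping of running gait patterns from pelvic acceleration waveforms.

Runners with patellofemoral pain (PFP) do not share a single "atypical"
gait: clinical studies point to several distinct movement strategies,
especially among women. `pelviclust` implements a complete, testable
analysis chain for finding such homogeneous sub-groups from nothing more
than the 3D acceleration of the pelvis — a signal that is cheap to measure
(one rigid marker cluster, or a single wearable accelerometer) and immune
to the marker-placement errors that plague full lower-limb kinematics. It
is written for gait researchers and biomechanists who want a reproducible
reference implementation of this pipeline plus a synthetic cohort generator
to validate every stage against known ground truth.

## The method

Per subject, from a treadmill run captured at 200 Hz:

1. **Pelvic acceleration.** The centroid of a 4-marker pelvic cluster is
   double-differentiated with a Savitzky–Golay polynomial-derivative filter
   (4th-order fit, 11-point window; the fitted polynomial's derivative is
   evaluated analytically, and half-window edges are marked invalid).
   Global accelerations are rotated into the pelvis-fixed frame via
   per-frame orthogonal-Procrustes (Kabsch) poses against the static
   calibration trial, emulating a pelvis-mounted sensor.
2. **Step waveforms.** Each step cycle `[foot strike, next strike)` is split
   at toe-off, resampled to 80 stance + 20 flight points by linear
   interpolation, averaged over the 60–80 steps of the trial, and the
   VT/AP/ML waveforms are concatenated into one 300-dimensional vector.
   Stacking subjects and z-scoring each column gives the standardized
   feature matrix `X` (n × 300).
3. **Sub-grouping.** Agglomerative clustering per sex stratum: Euclidean
   distances, Ward minimum-variance linkage, and the variance ratio
   criterion `VRC(k) = [tr(B)/(k−1)] / [tr(W)/(n−k)]` maximized over
   k = 2..10. A reference-null check (99 datasets drawn uniformly on the
   PCA bounding box of `X`) flags strata with *no* sub-structure.
4. **Interpretation.** PCA of the pooled standardized matrix; components
   with a large group effect (η² > 0.14 across male/C1/C2) are attributed
   to the VT/AP/ML axes by squared score–column correlations and
   reconstructed as waveforms at group-mean scores.
5. **Statistics.** Assumption-dispatched comparisons (Shapiro–Wilk +
   median-centered Levene → one-way ANOVA/Tukey or Kruskal–Wallis/Dunn with
   Holm adjustment), η² and Cramér's V effect sizes, χ² for categorical
   descriptors, and Pearson correlations of flagged components with the
   variables that differed.

Because no public dataset accompanies the method, the package ships a
**synthetic cohort generator**: three acceleration archetypes (males,
female sub-groups C1 and C2; 44/26/40 subjects) built from Gaussian bumps
per axis with calibrated vertical excursions (104.7/88.8/98.9 mm),
archetype-specific peak timing/amplitude contrasts, peak joint angle and
demographic distributions, and white marker noise. Every generated subject
carries exact ground truth (local accelerations, events, excursion), which
is what makes the kinematic chain testable to percent-level tolerances.

## Worked example

```r
library(pelviclust)

cfg    <- run_config(seed = 42)
cohort <- make_waveform_cohort(default_archetypes(), seed = 42, cfg)
mf     <- run_pipeline(cohort, cfg)
mf
#> <run_manifest> 110 subjects
#>   female: k = 2
#>   male: k = 2 (no sub-structure)
#>   large-effect PCs: PC1 (eta2 0.93, 54.8% var), PC2 (eta2 0.89, 12.2% var)

round(mf$pc_summary[1:2, ], 3)
#>   pc explained_pct eta_squared large_effect vt_loading_pct ap_loading_pct ml_loading_pct
#> 1  1        54.796       0.934            1         38.968         29.553         31.479
#> 2  2        12.211       0.892            1         43.656         22.162         34.182

round(tapply(mf$meta$vertical_excursion_mm, mf$assignments$group, mean), 1)
#>    C1    C2  male
#>  88.0  99.2 104.5
```

Read: the female stratum splits into two sub-groups (the male stratum does
not survive the null check); two pooled components separate the three
groups with large effects and are attributed mostly to the vertical axis;
the group-mean vertical excursions recover the generator's configured
values. `write_report(mf, "out/")` serializes cluster assignments, linkage
tables, the VRC profile, the PC summary and the comparison table as CSVs
plus a YAML run summary.

For marker-level data, build trials with `make_cohort()` (or read your own
via `read_trajectories()` / `read_events()` / `read_cohort()`) and pass
them to the same `run_pipeline()`. A thin shell wrapper lives at
`inst/scripts/pelviclust` (`synth` and `run` subcommands).

## Vignette

`vignettes/pelvic-acceleration-subgrouping.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic cohorts do and do not emulate, and the package's numerical design
choices.
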