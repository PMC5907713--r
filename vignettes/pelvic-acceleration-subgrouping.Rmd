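---
title: "Sub-grouping running gait from pelvic acceleration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-grouping running gait from pelvic acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelviclust)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The worked example in the README shows the
pipeline running; here we document the underlying models, the tunable
parameters, what the synthetic cohorts can and cannot stand in for, and
the numerical decisions a maintainer would want written down.

## 1. The measurement model

The pipeline treats the pelvis as a rigid body observed through a cluster
of four reflective markers at 200 Hz. Three steps turn marker positions
into the analysis signal:

**Centroid and double differentiation.** The cluster centroid (unweighted
per-frame marker mean) proxies pelvis position. Acceleration is obtained by
two sequential Savitzky–Golay first-derivative passes: in each window a
polynomial of order `sg_order` (default 4) is least-squares fitted and its
derivative evaluated *analytically* at the window center. This is the
standard derivative-SG construction; it reproduces derivatives of
polynomials up to the fit order exactly and attenuates high-frequency noise
without the phase lag of causal filters. Each pass invalidates half a
window at each edge; after two passes one full window per edge is marked
`NA` and excluded downstream, rather than padded — trials have hundreds of
spare frames, and padding would fabricate data.

The default window is 11 samples (55 ms). An even window has no center
sample; if one is requested (e.g. `sg_window = 10`), the fit is evaluated
at the true window center, half a sample away from the storage grid, and
the output carries a documented half-sample latency per pass. The centered
odd window is the default because phase fidelity matters more here than
matching a particular window parity: step segmentation indexes the signal
by frame.

**Rigid pose and the local frame.** For every frame the rotation and
translation mapping the static-trial marker configuration onto the current
one are estimated by the orthogonal-Procrustes/Kabsch construction
(SVD of the cross-covariance, with reflection correction so the rotation is
proper). Global accelerations premultiplied by the transposed rotation give
the signal a pelvis-mounted accelerometer would see, up to gravity. The
local frame coincides with the lab frame in the static pose by
construction. The lab convention is fixed as X = antero-posterior (anterior
positive), Y = medio-lateral, Z = vertical (up positive); the three
analysis axes are reported as VT/AP/ML.

**Events.** Foot strikes are the onsets of the prominent vertical
acceleration peaks: peaks at least 0.4 cadence periods apart (cadence from
the dominant 1.2–4.5 Hz spectral line) are located, and each strike is
placed at the last upward crossing of 40% of that peak's height before it.
The 40% level is the detector's design point: on synthetic subjects it
lands within ±10 ms of ground truth for ~98% of steps, whereas lower
thresholds are biased late by the step-frequency component of the
waveform. Toe-off is not detectable from pelvic acceleration alone, so it
is placed at `stance_fraction` (default 0.65) of each strike-to-strike
interval unless an external event table is supplied — generated cohorts
carry exact ground-truth events, and real datasets will usually bring
their own. This detector is a deliberately simplified surrogate: the
joint-angular-acceleration detectors used with full marker sets need
segments this pipeline does not consume.

## 2. From steps to the feature matrix

Each step `[strike, next strike)` is split at toe-off and the two phases
are resampled *independently* to 80 and 20 points by linear interpolation
on closed-endpoint grids. The fixed 80/20 split (rather than per-step
phase durations) makes the columns of the final matrix comparable across
subjects; linear interpolation suffices because the signal is already
band-limited by the SG fit, and it keeps the resampling oracle analytic.
Steps are averaged element-wise, and the per-subject VT, AP and ML
waveforms are concatenated — in that order — into one 300-vector. The
subjects-by-300 matrix is z-scored per column; zero-variance columns are
flagged and left unscaled rather than divided by zero. Standardization is
across subjects (not within subject) because the decomposition and the
distance metric both operate on the assembled matrix.

All frame indices are 0-based and intervals half-open; subject order is
preserved end to end, and all outputs are keyed by `subject_id`, never by
position.

## 3. Clustering and the no-sub-structure check

Sub-groups are sought separately per sex stratum with agglomerative
clustering: Euclidean distances on the standardized vectors, Ward
minimum-variance linkage, and cluster-count selection by the variance
ratio (Calinski–Harabasz) criterion over `k_range` (default 2..10; the
tie-break is the smallest k). Linkage heights are reported in
SSE-increase units, which are directly comparable to an exhaustive greedy
minimum-SSE search — the test suite holds the two equal on small problems.
Clustering is on the standardized vectors by default; principal-component
scores are an equivalent rotation of the same space, so distances are
unchanged up to rank truncation.

The criterion always returns *some* maximizing k, so a separate decision
rule is needed for "this stratum has no sub-groups". The package compares
the observed maximum criterion value with the 95th percentile of maxima
over `n_null = 99` datasets drawn uniformly on the data's PCA bounding box
(the gap-statistic reference distribution): if the observed maximum does
not exceed the reference, the stratum is flagged as unstructured. This is
an extension beyond the plain criterion — labelled as such — chosen because
it is defensible, cheap, and directly testable: single Gaussian clouds
raise the flag in ≥80% of seeds, while the default two-archetype female
cohorts never should.

## 4. Decomposition and interpretation

PCA of the column-centered standardized matrix retains all
`p = min(n − 1, 300)` components: there is no retention rule to inherit,
later components are analyzed when they carry group effects, and
completeness costs nothing at this scale. Sign indeterminacy is fixed by
making each loading column's largest-magnitude element positive — signs
are conventions, not physics, and reports must be reproducible across
platforms.

Components are screened by η² of their scores across the three pooled
groups (males, C1, C2), flagging η² > `effect_size_threshold` (default
0.14, the conventional large-effect boundary). Screening across the three
groups (rather than within females only) is the default because the
downstream comparisons are three-group comparisons; both variants are a
one-line change on the score matrix. Flagged components are attributed to
axes by the squared Pearson correlation between scores and each *raw*
column, summed within the VT/AP/ML blocks and normalized to percentages;
and reconstructed as waveforms at group-mean scores
(`col_means + col_sds * (center + score * loading)`).

PCA is fitted on the pooled cohort (both sexes) while clustering is per
stratum: comparing male and female sub-groups on common components
requires one shared basis.

## 5. The statistics layer

Every scalar variable (demographics, vertical excursion, peak joint
angles, flagged PC scores) is compared across the pooled groups through a
single dispatched path: if all groups pass Shapiro–Wilk and the groups
pass a median-centered Levene test at `alpha` (default 0.05), one-way
ANOVA with Tukey HSD post-hoc; otherwise Kruskal–Wallis with Dunn's
rank-based z-tests, Holm-adjusted (the adjustment is configurable to
`"none"`; unadjusted Dunn tests inflate family error). Effect sizes are η²
on the ANOVA branch and the rank-based analogue `(H − k + 1)/(n − k)`
(clipped to [0, 1]) on the KW branch. Categorical descriptors use Pearson
χ² without continuity correction and Cramér's
`V = sqrt(χ²/(N·(min(r,c) − 1)))`; the uncorrected statistic is the one
consistent with reference values on 3×2 involvement tables. Post-hoc
tables are attached only when the omnibus test is significant. The whole
dispatch is calibrated: under null simulations (normal and skewed) its
type-I rate at α = 0.05 stays within 0.05 ± 0.02.

## 6. What the synthetic cohorts emulate — and what they do not

The generator exists because no public dataset accompanies the method. It
is first-class, tested code, and its defaults *are* the study conditions.

**Waveform model.** Each archetype defines a smooth periodic 3-axis
acceleration over the step cycle, built from Gaussian bumps: a VT impact
peak in early stance (at 15% of stance, amplitude `vt_peak_g`, width 0.07
cycles) balanced by a broad negative bump in flight; an AP
braking/propulsion pair (posterior bump then an anterior bump of amplitude
`ap_peak_g` at `ap_peak_phase` of stance); and a single lateral ML bump at
`ml_peak_phase` of stance with a broad opposite balance. Every axis
integrates to ≈0 over a cycle. Bump widths were chosen so the waveform's
spectral content stays where the 11-point SG filter is accurate to ~1%;
sharper bumps would make the generator test the filter's roll-off rather
than the pipeline's correctness.

**Excursion calibration.** Peak vertical accelerations and vertical
excursions cannot be prescribed independently — position is the double
integral of acceleration. The generator reconciles them with a corrector
added to the VT waveform: a fundamental cosine aligned with the impact
peak *minus* the equally sized aligned 3rd harmonic. The pair cancels
exactly at the peak phase (so `vt_peak_g` × 9.81 is an exact anchor) while
its position response, dominated by the fundamental, is solved by root
finding so the cycle's peak-to-peak vertical displacement equals the
archetype's target (104.7/88.8/98.9 mm for males/C1/C2). Corrector
amplitudes stay at a few m/s².

**Kinematic realization.** The pelvis pose combines the double-integrated
waveform (computed on a 10× oversampled grid so trapezoidal error is
negligible) with a small periodic yaw (default 4°). Yaw only: a roll
component would mix ML acceleration into the vertical channel and destroy
the exact excursion anchor. Four markers ride rigidly on the pelvis
(pairwise distances constant to <0.1 µm before noise) and every coordinate
receives white noise (default SD 0.5 mm, a typical optical-capture residual).
The step period is snapped to an integer number of frames (71 at the
default 170 steps/min) so ground-truth events lie exactly on the frame
grid; the default trial length is 22 s, which yields 61 steps — within the
60–80-step band expected of a 20 s-plus capture at this cadence.

**Between-subject variation.** Amplitudes are jittered with a 6% CV, peak
timing with SD 0.012 cycles, excursion targets with the reference SDs
(2.1/2.7/2.2 mm), and demographics, peak joint angles, involvement and
injury-site indicators are drawn from the reference tables' means and
dispersions. At these defaults the C1–C2 mean-waveform separation is ~3×
the within-archetype spread — strong enough that cluster recovery is near
perfect; the male–C1 pair is deliberately closer (they differ mainly in
ML timing and amplitude), mirroring the qualitative structure the method
reports. The waveform-level fast path (`make_waveform_cohort()`) draws the
same realizations and emits the step-averaged waveform directly (plus
0.25 m/s² residual per-point noise approximating what survives averaging
~60 steps), so simulation studies over many cohorts need not pay for
marker synthesis and pose recovery.

**What passing tests do not show.** The generator has no soft-tissue
artifact, no marker occlusion or gap-filling, no ground-reaction forces,
no left/right asymmetry, no stride-to-stride waveform variability beyond
white noise, no correlation between demographics and waveform shape, and
its toe-offs follow the same fixed stance fraction the pipeline assumes.
Recovery results on synthetic cohorts therefore validate the *machinery*
(differentiation, pose, normalization, clustering, statistics) — they do
not certify event-detection accuracy or clustering performance on real
running data, where within-group heterogeneity is certainly larger.

## 7. Numerical choices and problem sizes

- Tolerances: rotation matrices are proper to 1e-9; standardized columns
  have mean 0 / SD 1 to 1e-9; PCA reconstruction is complete to 1e-8;
  explained variance and per-axis loadings sum to 100 ± 1e-6; η² and
  Cramér's V match brute-force arithmetic to 1e-12.
- Zero-variance columns: flagged, left unscaled, and treated as
  correlation 0 in loading attribution.
- Degenerate inputs fail loudly and early with the offending marker,
  frame, subject or stage named: collinear marker sets, gaps in frame
  numbering, irregular sampling, empty clusters, flat signals, too-short
  windows.
- Ties: cluster-count ties resolve to the smallest k; `hclust`'s merge
  order is deterministic for distinct distances, and equal-distance ties
  are measure-zero for continuous data.
- Seeds: every stochastic stage flows from one configured seed through
  derived per-subject/per-stage streams; identical seed and configuration
  reproduce every number bit for bit, and generator calls restore the
  caller's RNG state.
- Problem sizes used by the shipped tests and acceptance script (chosen as
  the smallest sizes at which each property is meaningfully exercised):
  full marker cohorts of 110 subjects for the end-to-end run;
  waveform-level cohorts of 66 females across 20 seeds for cluster-count
  recovery and 50 seeds for label recovery; 99 reference-null datasets per
  no-sub-structure check; 2000 null simulations for test calibration;
  8-point exhaustive Ward oracles and 12-point scatter-trace fixtures.

## 8. Known limitations

C3D input is feature-gated and not enabled in this build — trajectories
enter through the CSV dialect. The event detector is a surrogate, as
discussed. The no-sub-structure rule is an extension with a specific null
(uniform on the PCA bounding box); other nulls (e.g. a single Gaussian
fitted to the data) would shift its operating point. The statistics layer
applies no multiple-testing control across the *family* of compared
variables, matching the reference analysis it mirrors; within post-hoc
families, Holm adjustment is applied on the Dunn branch and Tukey's own
adjustment on the ANOVA branch. Sex strata are modeled as male/female
only, as in the reference cohort.
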