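---
title: "Linking smartphone sensing to seed-based brain connectivity: models and methods"
author: "phenoconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking smartphone sensing to seed-based brain connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phenoconn)
```

# Overview

`phenoconn` implements a complete pipeline for relating passively sensed
smartphone behavior to resting-state functional connectivity (RSFC) in a
two-cohort design: phone-derived features (daily screen time, circadian
similarity), brief depression surveys (PHQ-2/4/8), a motion-scrubbing
denoising stream for BOLD fMRI, subgenual-cingulate (sgCC) seed maps,
voxelwise brain–behavior correlation with Monte-Carlo cluster-extent
correction, and a discovery-cohort → replication-cohort masking step. A
synthetic-data generator with known ground truth makes every stage testable
without access to raw phone or MRI data.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data do and do not
emulate.

# Phone sensing features

**Unlock duration (screen time).** Each unlock session is the interval from
unlocking the phone to relocking. Daily totals sum session durations per
calendar day; sessions crossing midnight are split at the boundary so that
time is conserved within days and epochs (the alternative, assigning the
whole session to its start day, would not conserve epoch totals). A day
counts as valid when at least 16 hours of it contain any sensor event (the
package's operational definition of "quality coverage", which the source
data description leaves open); subjects enter the analysis with at least 20
valid days. Both thresholds are arguments (`minCoverageHours`, `minDays`).

**Duty-cycled sampling.** The second cohort's phones sample the unlock
stream for 1 minute in every 10-minute cycle, extended to at most 3 minutes
when conversation is detected — 10% minimum and 30% maximum temporal
coverage. Observed epoch minutes are upscaled by the realized per-cell
coverage fraction (`coverageUpscale()`); the generator carries the realized
windows with the stream so this fraction is exact.

**Epochs.** Features are split into three daily epochs — day (09:00–18:00),
evening (18:00–24:00), night (00:00–09:00) — half-open, naive local time,
no daylight-saving adjustment (the synthetic clock has none; determinism
matters more here than calendar fidelity). Unique locations are counted per
epoch after snapping coordinates to a 100 m square grid; the 100 m cell is
a package choice, since only "number of unique locations" is specified
upstream.

# Circadian similarity (NaN-tolerant ICC)

The circadian similarity of a feature is the two-way, single-measure,
*consistency* intra-class correlation — the ICC(3,1) form — of the
day × epoch matrix, with **epochs as targets and days as raters**:

$$\mathrm{ICC} = \frac{MS_\mathrm{epoch} - MS_\mathrm{error}}
                      {MS_\mathrm{epoch} + (k-1)\,MS_\mathrm{error}},$$

with $k$ the number of days contributing data. The consistency form removes
additive day-level shifts, so the statistic measures how reproducible the
*shape* of the day/evening/night profile is. With missing entries, all
means and sums run over observed cells and the error degrees of freedom are
reduced by the number of missing cells; on complete data this reduces
exactly to the textbook ANOVA decomposition (verified against an
independent `aov()` oracle to 1e-10). Degenerate inputs (a constant matrix,
or no estimable between-epoch mean square) return `NA` — an undefined
marker, handled downstream like an exclusion, not an error.

The orientation (epochs vs days as targets) is genuinely ambiguous in
generic ICC descriptions; the chosen orientation is recorded in the output
metadata and `transpose = TRUE` exposes the alternative for sensitivity
analysis. No claim is made about which orientation any particular upstream
implementation used.

# Surveys

PHQ-8 (8 items) and PHQ-4 (4 items; items 1–2 are the PHQ-2 depression
items, 3–4 the anxiety items) are scored as item sums of ordinal 0–3
responses. Item-level missingness is rejected rather than prorated.
Severity bands for the PHQ-8 total (0–4 minimal, 5–9 mild, 10–14 moderate,
15–19 moderately severe, 20–24 severe) live in a configuration table
(`phqSeverityCutpoints()`), not in code, because they come from an external
convention. Repeated EMA administrations are averaged; a single
administration suffices for inclusion, zero administrations exclude.

# The RSFC denoising stream

The per-subject stream is fixed in this order, asserted by a stage log:
**censor → nuisance regression → spectral interpolation → band-pass →
correlate on uncensored frames**.

* **Framewise displacement.** FD is the sum of absolute differentiated
  realignment parameters, rotations converted to millimetres as arc length
  on a 50 mm sphere (the radius is a convention of the FD definition, kept
  in configuration). `fd[1] = 0`.
* **Censoring.** Frames with FD > 0.25 mm are censored (the threshold is
  inclusive on the keep side); surviving contiguous segments shorter than 5
  frames are censored too; runs need ≥ 50 uncensored frames and subjects
  ≥ 5 minutes (300 s, boundary inclusive) of uncensored data across runs.
* **Nuisance regression.** 36 motion regressors (Volterra expansion: the 6
  parameters, their squares, both quantities at lags 1 and 2; lag columns
  zero-filled at the run start), mean CSF, WM and whole-brain signals,
  their backward-difference derivatives, and a constant — 43 columns.
  Coefficients are estimated on uncensored frames only; residuals are
  formed at all frames. No detrending beyond the constant column is
  applied. Rank deficiency is an error naming the offending columns.
* **Spectral interpolation.** Censored frames are reconstituted from the
  uncensored ones by a least-squares spectral fit for non-uniformly sampled
  data, in the spirit of the Lomb–Scargle periodogram: a sine/cosine
  dictionary on a frequency grid over-resolved by a factor of 8 (spacing
  $1/(8\,\mathrm{span})$) is fitted jointly; because the dictionary is
  over-complete, the minimum-norm solution is taken, computed in the dual
  (kernel) space via a truncated-eigenvalue pseudoinverse. Two numerical
  guards matter. First, the reconstruction band is capped at 0.6× the
  mean-rate Nyquist of the censored sampling: at the Nyquist limit itself,
  missing on-grid samples are on the identifiability boundary and the fit
  degenerates (this cap was chosen by sweeping the sinusoid-recovery oracle
  over 50 random censoring patterns at both repetition times, and
  comfortably covers the 0.009–0.08 Hz analysis band at realistic censoring
  rates). Second, reconstructed deviations are bounded at 1.5× the observed
  per-voxel range, because a harmonic extension can overshoot inside long
  censored gaps when the data carry out-of-band power. Earlier designs —
  independent per-frequency amplitude fits with a global SD rescale, and a
  near-interpolating ridge solve — failed the package's own sinusoid oracle
  (reconstructions collapsing to zero on-grid, or exploding inside gaps)
  and were replaced by this formulation. Uncensored frames pass through
  bit-identical.
* **Band-pass.** 0.009–0.08 Hz, FFT-domain masking with a raised-cosine
  taper of 0.004 Hz outside the band edges, applied after interpolation
  when the series is uniformly sampled; zero-phase by construction, exact
  DC rejection.
* **Seed maps.** The seed is a 4 mm sphere at MNI (0, 25, −10) — the sgCC.
  Its mean time course is correlated against every voxel over uncensored
  frames only; Fisher z = atanh(r) with r clipped to ±(1 − 1e−7).
  Zero-variance voxels get z = 0 and are flagged; the seed's own voxels are
  recorded as flagged self-correlations.

# Group statistics

Seed-map stacks are correlated voxelwise across subjects with the
behavioral covariate (Fisher-z values, not raw r, enter the correlation;
recorded in metadata). Degrees of freedom are $N-2$,
$t = r\sqrt{df}/\sqrt{1-r^2}$, p two-tailed.

**Cluster-extent correction.** The reference implementation's
autocorrelation-function cluster simulation is replaced by a documented
single-Gaussian-FWHM Monte-Carlo null: white-noise volumes smoothed to the
estimated FWHM, standardized within the mask, thresholded at the two-tailed
voxel p, and the maximum cluster extent recorded per iteration; the extent
threshold is the smallest cluster size whose null exceedance probability is
at most the corrected alpha. Smoothness is estimated from the variance of
spatial first differences relative to total variance
($\mathrm{FWHM} = \Delta\sqrt{-2\ln 2/\ln(1-v_d/2v)}$), averaged over axes
and maps. This single-FWHM null is simpler than a mixed-ACF model; its
calibration is itself a tested property (corrected false-positive rate ≤
alpha + Monte-Carlo error under a global null). Face (6-neighbor) adjacency
is the default, with edge and corner adjacency available; thresholds are
two-tailed throughout, with positive and negative clusters labeled
separately.

**Replication masking.** The union of corrected discovery-cohort cluster
voxels masks the replication cohort's analysis; the extent threshold is
re-calibrated within the mask volume. Following the directed hypothesis of
a positive relationship, only positive clusters are reported by default
(`positiveOnly = FALSE` gives both signs). Overlap reports count pairwise
and k-way voxel intersections.

# The synthetic-data generator

The generator emulates the study conditions, not the physiology:

* **Phone streams.** Daily unlock totals are a logistic function of a
  standard-normal latent severity trait (90–240 min across ±∞, ~165 min at
  severity 0) plus day-level noise (SD 15 min), allocated across 48
  half-hour slots by a fixed time-of-day intensity profile with jittered
  session onsets (so duty-cycle windows are not phase-locked to sessions).
  The session-level model is an assumption — no session-level distribution
  is specified upstream. Still minutes and unique-location counts have
  epoch-flat baselines plus a per-subject stable epoch pattern scaled by
  `iccConsistency` and day-level (rater) effects, so consistency 0 is a
  true ICC null and consistency 1 approaches ICC 1. Sensor outages
  (`missingDayRate`) leave 14 coverage hours, below the 16 h validity rule.
* **Surveys.** Items threshold latent severity plus noise at fixed normal
  cutpoints (70/88/97%), giving the right-skewed item distributions typical
  of general-population PHQ data.
* **BOLD runs.** All signals are band-limited to 0.01–0.08 Hz — inside the
  analysis passband, so that filtering does not destroy planted structure
  and parameter recovery is a fair test. Seed voxels share a latent signal
  (weight 0.9); target voxels (a 7.5 mm sphere in ventromedial prefrontal
  territory, fully inside the brain mask) carry the latent signal scaled by
  a per-subject connectivity weight $w = 0.5 + 0.22\,(\rho\,x +
  \sqrt{1-\rho^2}\,\eta)$ with behavior $x$ and planted effect $\rho$
  (`effectR`), clipped to [0.05, 0.92]; CSF and WM blocks share tissue
  signals; everything rides on white measurement noise (SD 0.2). Motion is
  a slow drift plus 0.45 mm displacement spikes at `motionSpikeRate` per
  frame (non-adjacent, so each planted spike exceeds the 0.25 mm
  threshold). Defaults: 240 frames at TR 2.5 s (a 10-minute run, matching
  the discovery cohort's acquisition length) on a 20×24×20 grid of 3 mm
  voxels — large enough for cluster statistics, small enough for desk-scale
  tests. The replication cohort's faster TR is *not* emulated; its
  distinctive feature here is the duty-cycled phone sampling.
* **Not emulated:** hemodynamics, physiological noise, realistic GPS
  trajectories, scanner differences, spatial normalization error. Passing
  tests therefore demonstrate the correctness and calibration of the
  *pipeline*, not performance on real data.

A seed-map-level simulator (`simulateSeedMapStack()`) generates smooth
subject z-maps with an exact planted across-subject correlation at target
voxels; it isolates the group-level machinery for calibration and power
studies without the per-subject time-series cost.

# Problem sizes used in tests

Desk-scale defaults keep the full test suite under a few minutes of
statistics plus one full-pipeline study: the end-to-end recovery check runs
80 subjects per cohort at the default grid; null calibration uses 200
group-level replicates of 20 subjects on the 20×24×20 grid with a
1000-iteration extent calibration; the replication-power check uses 50
seed-map-level replicates of 60 subjects per cohort. Sixty subjects per
replicate gives ~93% per-voxel power at the cluster-forming threshold for
the planted effect, so the ≥80% replication-success criterion is tested
away from its own noise floor.

# Reproducibility

Every random stage derives its seed from a master seed via a stable text
label (`deriveSeed()`), so adding a stage never perturbs earlier stages'
draws, and rerunning an identical configuration reproduces the study
manifest byte for byte. The manifest records the verbatim parameter set,
derived seeds, smoothness estimates, extent thresholds and per-stage
subject attrition.

# Known limitations

* The single-Gaussian-FWHM null under-models heavy-tailed spatial
  autocorrelation; on real data a mixed-ACF null typically demands larger
  extents at liberal voxel thresholds.
* The spectral reconstruction is intended to stabilize filtering, not to
  recover censored frames for inference; correlations never use censored
  frames.
* Coverage hours are defined by event presence per hour; a phone that is
  off for 50 minutes of an hour still marks that hour covered.
* Mask erosion fallbacks for degenerate tissue masks are out of scope;
  masks arrive pre-eroded from the generator, and an empty mask is an
  error.
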