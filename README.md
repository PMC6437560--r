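# phenoconn

Digital phenotyping meets resting-state connectivity. `phenoconn` is an R
package for studies that relate passively sensed smartphone behavior —
daily screen time (phone unlock duration) and the day-to-day consistency of
circadian activity patterns — to seed-based resting-state functional
connectivity (RSFC) of the subgenual cingulate cortex (sgCC), with brief
PHQ depression surveys alongside, in a two-cohort discovery → replication
design. It is aimed at researchers building or auditing such pipelines who
need every stage testable against known ground truth.

## What it implements

* **Phone features** — unlock-duration totals per calendar day (midnight
  splitting, 16 h coverage validity, 20-valid-day inclusion), day/evening/
  night epoch features, unique-location counts on a 100 m grid, and exact
  coverage upscaling for duty-cycled sampling (1 min per 10-min cycle,
  extended to 3 min on detected conversation).
* **Circadian similarity** — a NaN-tolerant two-way consistency intra-class
  correlation (epochs as targets, days as raters):
  `ICC = (MS_epoch − MS_err) / (MS_epoch + (k−1)·MS_err)`, reducing exactly
  to the ANOVA ICC on complete data.
* **Surveys** — PHQ-8/4/2 scoring, severity bands, EMA averaging.
* **RSFC denoising** — framewise displacement (rotations as 50 mm arc
  length), 0.25 mm censoring with the <5-frame-segment, 50-frame-run and
  5-minute-subject rules, 36-parameter Volterra motion regression plus
  tissue regressors and derivatives (43 columns), least-squares
  (Lomb–Scargle-style) spectral reconstitution of censored frames,
  zero-phase 0.009–0.08 Hz band-pass, and Fisher-z seed maps from a 4 mm
  sphere at MNI (0, 25, −10), correlated on uncensored frames only.
* **Group statistics** — voxelwise brain–behavior correlation (df = N−2),
  Monte-Carlo Gaussian-smoothness cluster-extent correction, cluster
  tables, discovery-cluster masking of the replication cohort, and voxel
  overlap reports.
* **Synthetic two-cohort generator** — phone event streams, surveys and
  band-limited BOLD runs with a planted across-subject correlation
  `effectR` between behavior and seed–target connectivity, plus censorable
  motion spikes; everything deterministic given one seed.

## Worked example

Simulate a small two-cohort study and run the whole workflow:

```r
library(phenoconn)

sc <- studyConfig(
  cohort1 = cohortConfig(12, "continuous",  rngSeed = 101),
  cohort2 = cohortConfig(12, "duty_cycled", rngSeed = 202),
  nIterations = 300, rngSeed = 9)
res <- runStudy(sc)

res$attrition
#>    cohort total rsfc_passed unlock_20d both
#> 1 cohort1    12          12         12   12
#> 2 cohort2    12          12         12   12

res$calibration1
#> NullCalibration: extent threshold 3 voxels at voxel p < 0.01 ,
#>   corrected alpha 0.05 (FWHM 2.64 mm, 300 iterations)

head(res$clusters1[, c("sign", "peak_x", "peak_y", "peak_t",
                       "extent_voxels", "volume_mm3", "passed_correction")])
#>       sign peak_x peak_y   peak_t extent_voxels volume_mm3 passed_correction
#> 1 positive   -1.5   -6.5 3.177716             1         27             FALSE
#> 2 positive   -1.5   17.5 4.018260             1         27             FALSE
#> 3 positive   -4.5    2.5 3.683563             1         27             FALSE
```

`res$clusters1` lists cohort-1 clusters of the correlation between mean
daily unlock minutes and sgCC seed maps (peaks in mm, extents in voxels,
volumes in mm³, and whether each passed the Monte-Carlo extent threshold);
`res$replication` holds the cohort-2 clusters inside the corrected cohort-1
mask, and `res$truthOverlap` counts how many replication voxels land on the
generator's planted target region. With only 12 subjects per cohort the
planted effect is usually *not* detectable — that is the expected answer at
this scale; the packaged acceptance run uses 80 per cohort.

Single stages are exported directly, e.g.:

```r
fd <- computeFD(motionMatrix)          # mm per frame
cm <- buildCensorMask(fd)              # 0.25 mm threshold + segment rules
sum(censorKeep(cm))                    # uncensored frame count
```

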