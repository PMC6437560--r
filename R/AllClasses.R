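#' @import methods
NULL

#' EventStream: timestamped phone events for one subject
#'
#' Container for a chronologically ordered phone event table. Event types are
#' `unlock_session` (screen on between unlock and re-lock), `still_interval`
#' (phone not moving, from the accelerometer pipeline) and `location_obs`
#' (instantaneous GPS observation). For duty-cycled cohorts the realized
#' observation windows are carried alongside the events so that coverage can
#' be reconstructed exactly.
#'
#' @slot subjectId Character subject identifier.
#' @slot events `data.frame` with columns `event_type`, `start`, `end`
#'   (`POSIXct`, `end` is `NA` for instantaneous observations), `latitude`,
#'   `longitude` (`NA` for non-location events).
#' @slot samplingMode `"continuous"` or `"duty_cycled"`.
#' @slot windows `data.frame` with columns `start`, `end` (`POSIXct`);
#'   zero rows for continuous sampling.
#' @export
setClass("EventStream",
  representation(
    subjectId = "character",
    events = "data.frame",
    samplingMode = "character",
    windows = "data.frame"
  )
)

setValidity("EventStream", function(object) {
  ev <- object@events
  need <- c("event_type", "start", "end", "latitude", "longitude")
  if (!all(need %in% names(ev))) {
    return(paste("events must have columns", paste(need, collapse = ", ")))
  }
  if (!object@samplingMode %in% c("continuous", "duty_cycled")) {
    return("samplingMode must be 'continuous' or 'duty_cycled'")
  }
  if (nrow(ev) > 1 && is.unsorted(as.numeric(ev$start))) {
    return("events must be ordered by start time")
  }
  ok <- is.na(ev$end) | as.numeric(ev$end) >= as.numeric(ev$start)
  if (!all(ok)) return("event end must be >= start")
  un <- ev[ev$event_type == "unlock_session", , drop = FALSE]
  if (nrow(un) > 1) {
    s <- as.numeric(un$start); e <- as.numeric(un$end)
    o <- order(s)
    if (any(s[o][-1] < e[o][-nrow(un)])) {
      return("unlock sessions must be non-overlapping")
    }
  }
  TRUE
})

#' BoldRun: one resting-state fMRI run with motion and tissue masks
#'
#' @slot data 4D numeric array `[x, y, z, t]` of BOLD intensities.
#' @slot trSeconds Repetition time in seconds.
#' @slot voxelMm Isotropic voxel size in mm.
#' @slot affine 4x4 voxel-to-world (mm) map, 1-based voxel indices.
#' @slot motion `t x 6` realignment parameters: x, y, z translations (mm)
#'   and pitch, roll, yaw rotations (radians).
#' @slot masks Named list of logical 3D arrays `csf`, `wm`, `whole_brain`.
#' @export
setClass("BoldRun",
  representation(
    data = "array",
    trSeconds = "numeric",
    voxelMm = "numeric",
    affine = "matrix",
    motion = "matrix",
    masks = "list"
  )
)

setValidity("BoldRun", function(object) {
  d <- dim(object@data)
  if (length(d) != 4) return("data must be a 4D array [x, y, z, t]")
  if (d[4] < 50) return("run must have at least 50 frames")
  if (object@trSeconds <= 0) return("trSeconds must be positive")
  if (!all(dim(object@motion) == c(d[4], 6))) {
    return("motion must be a t x 6 matrix")
  }
  need <- c("csf", "wm", "whole_brain")
  if (!all(need %in% names(object@masks))) {
    return("masks must contain csf, wm and whole_brain")
  }
  for (nm in need) {
    if (!identical(dim(object@masks[[nm]]), d[1:3])) {
      return(paste("mask", nm, "shape must equal the data spatial shape"))
    }
  }
  TRUE
})

#' CensorMask: framewise-displacement censoring decision for one run
#'
#' @slot keep Logical vector, `TRUE` for frames retained after censoring.
#' @slot fd Framewise displacement (mm) per frame; `fd[1] = 0` by convention.
#' @slot fdThreshold FD threshold (mm) used.
#' @slot minSegment Minimum length of a surviving contiguous segment.
#' @slot minRunUncensored Minimum uncensored frames for run inclusion.
#' @slot runIncluded Whether the run passes the per-run frame-count rule.
#' @export
setClass("CensorMask",
  representation(
    keep = "logical",
    fd = "numeric",
    fdThreshold = "numeric",
    minSegment = "integer",
    minRunUncensored = "integer",
    runIncluded = "logical"
  )
)

setValidity("CensorMask", function(object) {
  if (length(object@keep) != length(object@fd)) {
    return("keep and fd must have equal length")
  }
  if (length(object@fd) && object@fd[1] != 0) {
    return("fd[1] must be 0 by convention")
  }
  if (any(object@keep & object@fd > object@fdThreshold)) {
    return("frames above the FD threshold cannot be kept")
  }
  TRUE
})

#' SeedMap: per-subject Fisher-z seed connectivity image
#'
#' @slot z 3D numeric array of Fisher-z correlations with the seed mean.
#' @slot subjectId Character subject identifier.
#' @slot nUncensoredFrames Number of frames the correlations are based on.
#' @slot seedCenterMni Seed centre in world (MNI) coordinates, mm.
#' @slot seedRadiusMm Seed sphere radius, mm.
#' @slot seedVoxels Linear indices of the seed sphere voxels (flagged: their
#'   own z values are self-correlations).
#' @slot flaggedVoxels Linear indices of zero-variance voxels whose z was
#'   set to 0.
#' @slot affine 4x4 voxel-to-world map.
#' @export
setClass("SeedMap",
  representation(
    z = "array",
    subjectId = "character",
    nUncensoredFrames = "integer",
    seedCenterMni = "numeric",
    seedRadiusMm = "numeric",
    seedVoxels = "integer",
    flaggedVoxels = "integer",
    affine = "matrix"
  )
)

setValidity("SeedMap", function(object) {
  if (length(dim(object@z)) != 3) return("z must be a 3D array")
  if (any(!is.finite(object@z))) return("z must be finite everywhere")
  TRUE
})

#' GroupResult: voxelwise across-subject brain-behavior correlation maps
#'
#' @slot rMap,tMap,pMap 3D numeric arrays (NA outside the analysis mask).
#' @slot nSubjects Number of subjects entering the correlation.
#' @slot df Degrees of freedom, always `nSubjects - 2`.
#' @slot covariateName Name of the behavioral covariate.
#' @slot analysisMask Logical 3D array of analyzed voxels.
#' @slot voxelMm Isotropic voxel size in mm.
#' @slot affine 4x4 voxel-to-world map.
#' @export
setClass("GroupResult",
  representation(
    rMap = "array",
    tMap = "array",
    pMap = "array",
    nSubjects = "integer",
    df = "integer",
    covariateName = "character",
    analysisMask = "array",
    voxelMm = "numeric",
    affine = "matrix"
  )
)

setValidity("GroupResult", function(object) {
  if (object@df != object@nSubjects - 2L) return("df must equal nSubjects - 2")
  m <- object@analysisMask
  r <- object@rMap[m]; tt <- object@tMap[m]
  ok <- is.finite(r) & abs(r) < 1
  tExp <- r[ok] * sqrt(object@df) / sqrt(1 - r[ok]^2)
  if (any(abs(tExp - tt[ok]) > 1e-8 * (1 + abs(tExp)))) {
    return("t map inconsistent with r map: t = r*sqrt(df)/sqrt(1-r^2)")
  }
  TRUE
})

#' NullCalibration: Monte-Carlo cluster-extent threshold
#'
#' Result of simulating smooth Gaussian null volumes within a mask,
#' thresholding at the voxelwise p and recording the maximum cluster extent,
#' giving the minimum cluster size controlling the corrected false-positive
#' rate.
#'
#' @slot fwhmMm Gaussian-equivalent smoothness (mm) of the simulated null.
#' @slot voxelP Voxelwise (uncorrected, two-tailed) threshold.
#' @slot nIterations Number of Monte-Carlo null volumes.
#' @slot extentThreshold Minimum cluster extent (voxels) passing correction.
#' @slot correctedAlpha Target corrected false-positive rate.
#' @slot rngSeed Seed used for the simulation.
#' @slot nullMaxima Integer vector of per-iteration maximum cluster extents.
#' @export
setClass("NullCalibration",
  representation(
    fwhmMm = "numeric",
    voxelP = "numeric",
    nIterations = "integer",
    extentThreshold = "integer",
    correctedAlpha = "numeric",
    rngSeed = "integer",
    nullMaxima = "integer"
  )
)

setValidity("NullCalibration", function(object) {
  if (object@extentThreshold < 1) return("extentThreshold must be >= 1")
  if (object@voxelP <= 0 || object@voxelP >= 1) return("voxelP must be in (0,1)")
  if (object@correctedAlpha <= 0 || object@correctedAlpha >= 1) {
    return("correctedAlpha must be in (0,1)")
  }
  TRUE
})

## ------------------------------------------------------------------
## show methods

setMethod("show", "EventStream", function(object) {
  cat("EventStream for", object@subjectId, "(", object@samplingMode, ")\n")
  tab <- table(object@events$event_type)
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  if (nrow(object@events)) {
    cat("  span:", fmtIso8601(min(object@events$start)), "to",
        fmtIso8601(max(object@events$start)), "\n")
  }
  invisible(NULL)
})

setMethod("show", "BoldRun", function(object) {
  d <- dim(object@data)
  cat("BoldRun:", paste(d[1:3], collapse = " x "), "voxels x", d[4],
      "frames, TR =", object@trSeconds, "s, voxel =", object@voxelMm, "mm\n")
  invisible(NULL)
})

setMethod("show", "CensorMask", function(object) {
  cat("CensorMask:", sum(object@keep), "of", length(object@keep),
      "frames kept (FD threshold", object@fdThreshold, "mm);",
      if (object@runIncluded) "run included" else "run excluded", "\n")
  invisible(NULL)
})

setMethod("show", "SeedMap", function(object) {
  cat("SeedMap for", object@subjectId, ":",
      paste(dim(object@z), collapse = " x "),
      "| seed", paste(object@seedCenterMni, collapse = ", "),
      "r =", object@seedRadiusMm, "mm |",
      object@nUncensoredFrames, "uncensored frames\n")
  invisible(NULL)
})

setMethod("show", "GroupResult", function(object) {
  cat("GroupResult:", object@covariateName, "| N =", object@nSubjects,
      "(df =", paste0(object@df, ")"), "|", sum(object@analysisMask),
      "voxels in mask\n")
  invisible(NULL)
})

setMethod("show", "NullCalibration", function(object) {
  cat("NullCalibration: extent threshold", object@extentThreshold,
      "voxels at voxel p <", object@voxelP, ", corrected alpha",
      object@correctedAlpha, "(FWHM", round(object@fwhmMm, 2), "mm,",
      object@nIterations, "iterations)\n")
  invisible(NULL)
})

## ------------------------------------------------------------------
## accessors

#' @describeIn CensorMask-class Logical keep vector.
#' @param object A `CensorMask`.
#' @export
censorKeep <- function(object) object@keep

#' @describeIn CensorMask-class Framewise displacement trace (mm).
#' @export
fdValues <- function(object) object@fd

#' @describeIn CensorMask-class Run-level inclusion flag.
#' @export
runIncluded <- function(object) object@runIncluded

#' @describeIn SeedMap-class Fisher-z 3D array.
#' @param object A `SeedMap`.
#' @export
zMap <- function(object) object@z

#' @describeIn GroupResult-class Voxelwise correlation map.
#' @param object A `GroupResult`.
#' @export
rMap <- function(object) object@rMap

#' @describeIn GroupResult-class Voxelwise t map.
#' @export
tMap <- function(object) object@tMap

#' @describeIn GroupResult-class Voxelwise two-tailed p map.
#' @export
pMap <- function(object) object@pMap

#' @describeIn NullCalibration-class Cluster extent threshold (voxels).
#' @param object A `NullCalibration`.
#' @export
extentThreshold <- function(object) object@extentThreshold

#' @describeIn EventStream-class Event table.
#' @param object An `EventStream`.
#' @export
streamEvents <- function(object) object@events
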