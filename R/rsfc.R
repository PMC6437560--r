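# Resting-state denoising stream: framewise displacement, frame censoring,
# Volterra-expanded nuisance regression, Lomb-Scargle spectral interpolation
# of censored frames, band-pass filtering and seed-map computation.
# Correlations are always computed on uncensored frames only.

#' Framewise displacement from realignment parameters
#'
#' FD at frame i is the sum of the absolute values of the differentiated six
#' realignment parameters (x, y, z, pitch, roll, yaw), with rotations
#' converted from radians to mm as arc length on a sphere of radius
#' `headRadiusMm` before differencing. `fd[1] = 0` by convention.
#'
#' @param motion `t x 6` matrix: translations (mm) then rotations (radians).
#' @param headRadiusMm Head radius for the rotation-to-mm conversion.
#' @return Numeric vector of length `t`.
#' @export
computeFD <- function(motion, headRadiusMm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) {
    stop("validation error: motion must have exactly 6 columns")
  }
  m <- motion
  m[, 4:6] <- m[, 4:6] * headRadiusMm
  if (nrow(m) < 2) return(rep(0, nrow(m)))
  c(0, rowSums(abs(diff(m))))
}

#' Build a frame-censoring mask from an FD trace
#'
#' Frames with FD above `threshold` are censored. Surviving contiguous
#' segments shorter than `minSegment` frames are additionally censored. The
#' run is flagged for exclusion when fewer than `minRunUncensored` frames
#' survive.
#'
#' @param fd Numeric FD trace (mm).
#' @param threshold FD threshold in mm (default 0.25).
#' @param minSegment Minimum surviving contiguous segment length (default 5).
#' @param minRunUncensored Minimum uncensored frames for run inclusion
#'   (default 50).
#' @return A [CensorMask-class].
#' @export
buildCensorMask <- function(fd, threshold = 0.25, minSegment = 5L,
                            minRunUncensored = 50L) {
  keep <- fd <= threshold
  r <- rle(keep)
  r$values[r$values & r$lengths < minSegment] <- FALSE
  keep <- inverse.rle(r)
  new("CensorMask", keep = keep, fd = as.numeric(fd),
      fdThreshold = threshold, minSegment = as.integer(minSegment),
      minRunUncensored = as.integer(minRunUncensored),
      runIncluded = sum(keep) >= minRunUncensored)
}

#' Subject-level inclusion from censor masks
#'
#' A subject is included when the total uncensored time across their
#' included runs is at least `minUncensoredSeconds` (5 min by default).
#'
#' @param censorMasks A [CensorMask-class] or list of them (one per run).
#' @param trSeconds Repetition time in seconds.
#' @param minUncensoredSeconds Minimum total uncensored seconds (default 300).
#' @return Logical scalar.
#' @export
subjectInclusion <- function(censorMasks, trSeconds,
                             minUncensoredSeconds = 300) {
  if (is(censorMasks, "CensorMask")) censorMasks <- list(censorMasks)
  frames <- vapply(censorMasks, function(cm)
    if (cm@runIncluded) sum(cm@keep) else 0L, integer(1))
  sum(frames) * trSeconds >= minUncensoredSeconds
}

#' Volterra expansion of six realignment parameters
#'
#' Expands the raw parameters to 36 motion regressors: the 6 parameters,
#' their squares, the parameters at the previous one and two frames, and
#' those lagged parameters squared. Lag columns are zero-filled at the run
#' start.
#'
#' @param motion `t x 6` realignment matrix.
#' @return `t x 36` numeric matrix with descriptive column names.
#' @export
volterraExpand <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) {
    stop("validation error: motion must have exactly 6 columns")
  }
  t <- nrow(motion)
  lagM <- function(m, k) {
    out <- matrix(0, t, 6)
    if (t > k) out[(k + 1):t, ] <- m[1:(t - k), , drop = FALSE]
    out
  }
  l1 <- lagM(motion, 1L); l2 <- lagM(motion, 2L)
  out <- cbind(motion, motion^2, l1, l2, l1^2, l2^2)
  p <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(p, paste0(p, "_sq"),
                     paste0(p, "_lag1"), paste0(p, "_lag2"),
                     paste0(p, "_lag1_sq"), paste0(p, "_lag2_sq"))
  out
}

#' Build the full nuisance regressor matrix for a run
#'
#' 36 Volterra-expanded motion regressors, the mean signal within the CSF,
#' WM and whole-brain masks, the first derivative of each tissue regressor
#' (backward difference, zero at the first frame), and a constant: 43
#' columns in total.
#'
#' @param motion `t x 6` realignment matrix.
#' @param bold `t x V` BOLD matrix (frames in rows) or a [BoldRun-class].
#' @param masks Named list of logical 3D arrays `csf`, `wm`, `whole_brain`
#'   (ignored when `bold` is a `BoldRun`).
#' @return `t x 43` numeric matrix with column names.
#' @export
buildNuisanceMatrix <- function(motion, bold, masks = NULL) {
  if (is(bold, "BoldRun")) {
    masks <- bold@masks
    motion <- bold@motion
    bold <- boldMatrix(bold)
  }
  for (nm in c("csf", "wm", "whole_brain")) {
    if (!sum(masks[[nm]])) {
      stop("integrity error: tissue mask '", nm, "' is empty")
    }
  }
  mot <- volterraExpand(motion)
  tiss <- vapply(c("csf", "wm", "whole_brain"), function(nm)
    rowMeans(bold[, which(masks[[nm]]), drop = FALSE]), numeric(nrow(bold)))
  colnames(tiss) <- c("csf", "wm", "global")
  dtiss <- apply(tiss, 2, function(x) c(0, diff(x)))
  colnames(dtiss) <- paste0("d_", colnames(tiss))
  cbind(mot, tiss, dtiss, constant = 1)
}

#' Regress nuisance signals out of a BOLD matrix
#'
#' Coefficients are estimated by least squares on uncensored frames only;
#' residuals are then computed at all frames from those coefficients, so
#' censored-frame values never influence the fit.
#'
#' @param bold `t x V` BOLD matrix.
#' @param regressors `t x p` nuisance matrix.
#' @param keep Logical vector of uncensored frames.
#' @return `t x V` residual matrix.
#' @export
nuisanceRegress <- function(bold, regressors, keep) {
  X <- regressors[keep, , drop = FALSE]
  qrX <- qr(X)
  p <- ncol(X)
  if (qrX$rank < p) {
    bad <- colnames(regressors)[qrX$pivot[(qrX$rank + 1):p]]
    stop("numerical error: nuisance matrix is rank deficient on uncensored ",
         "frames; offending columns: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, bold[keep, , drop = FALSE])
  bold - regressors %*% beta
}

#' Reconstitute censored frames by least-squares spectral interpolation
#'
#' The frequency content of each voxel's series is estimated from the
#' uncensored frames only, by least-squares fitting of a sine/cosine
#' dictionary on an over-resolved frequency grid (spacing
#' `1 / (oversample * span)` up to the sampling Nyquist) in the spirit of
#' the Lomb-Scargle periodogram for non-uniformly sampled data. The grid is
#' deliberately over-complete, so the minimum-norm least-squares solution is
#' taken, computed in the dual (kernel) space with a small ridge for
#' numerical stability. The resulting harmonic reconstruction replaces the
#' censored frames; uncensored frames are returned unchanged, bit for bit.
#'
#' @param bold `t x V` matrix (or vector) of residual BOLD series.
#' @param keep Logical vector of uncensored frames.
#' @param trSeconds Repetition time in seconds.
#' @param oversample Frequency-grid oversampling factor (default 8).
#' @return Matrix (or vector) of the same shape with censored frames
#'   reconstituted.
#' @export
spectralInterpolate <- function(bold, keep, trSeconds, oversample = 8) {
  vec <- is.null(dim(bold))
  Y <- if (vec) matrix(bold, ncol = 1) else bold
  t <- nrow(Y)
  stopifnot(length(keep) == t)
  nObs <- sum(keep)
  if (nObs == 0) stop("unrecoverable run: all frames censored")
  if (nObs < 2) stop("unrecoverable run: fewer than 2 uncensored frames")
  if (nObs == t) return(bold)
  if (nObs / t < 0.3) {
    warning("fewer than 30% of frames are uncensored; ",
            "spectral reconstruction may be unreliable")
  }

  tAll <- (seq_len(t) - 1) * trSeconds
  tObs <- tAll[keep]
  mu <- colMeans(Y[keep, , drop = FALSE])
  D <- sweep(Y[keep, , drop = FALSE], 2, mu)

  span <- max(tObs) - min(tObs)
  dfreq <- 1 / (span * oversample)
  ## reconstruction band: a guard factor below the mean-rate Nyquist of the
  ## censored sampling (the Lomb-Scargle hifac = 1 limit). At the limit
  ## itself missing on-grid samples sit on the identifiability boundary and
  ## the fit degenerates; the 0.6 guard keeps the problem well posed under
  ## irregular gap patterns while still covering the 0.009-0.08 Hz analysis
  ## passband at typical censoring rates.
  fMax <- 0.6 * nObs / (2 * span)
  om <- 2 * pi * seq(dfreq, fMax, by = dfreq)

  aObs <- outer(tObs, om)
  cObs <- cos(aObs); sObs <- sin(aObs)
  G <- tcrossprod(cObs) + tcrossprod(sObs)     # nObs x nObs Gram matrix
  ## The band-limited dictionary restricted to the observed frames has
  ## numerical rank about 2 * fMax * span < nObs, so G is rank deficient.
  ## A truncated-eigenvalue pseudoinverse projects the data onto the
  ## supported band subspace; chasing the near-null directions would
  ## near-interpolate broadband noise and blow up inside censored gaps.
  eg <- eigen(G, symmetric = TRUE)
  pos <- eg$values > 1e-6 * eg$values[1]
  W <- eg$vectors[, pos, drop = FALSE] %*%
    (crossprod(eg$vectors[, pos, drop = FALSE], D) / eg$values[pos])

  cenIdx <- which(!keep)
  aCen <- outer(tAll[cenIdx], om)
  Kco <- tcrossprod(cos(aCen), cObs) + tcrossprod(sin(aCen), sObs)
  H <- Kco %*% W
  ## amplitude guard: the harmonic extension can overshoot inside long
  ## censored gaps when the data carry out-of-band power; reconstructed
  ## deviations are bounded by 1.5x the observed deviation range per voxel
  lim <- 1.5 * matrix(apply(abs(D), 2, max), nrow(H), ncol(H), byrow = TRUE)
  H <- pmin(pmax(H, -lim), lim)
  out <- Y
  out[cenIdx, ] <- sweep(H, 2, mu, "+")
  if (vec) out[, 1] else out
}

#' Zero-phase band-pass filter
#'
#' FFT-domain masking with a raised-cosine taper of width `taperHz` outside
#' the band edges. The DC component is removed exactly; the filter is
#' zero-phase by construction. Applied after interpolation, when the series
#' is uniformly sampled.
#'
#' @param bold `t x V` matrix (or vector).
#' @param trSeconds Repetition time in seconds.
#' @param fLo,fHi Passband edges in Hz (defaults 0.009 and 0.08).
#' @param taperHz Transition width (Hz) of the cosine taper.
#' @return Filtered matrix (or vector) of the same shape.
#' @export
bandpassFilter <- function(bold, trSeconds, fLo = 0.009, fHi = 0.08,
                           taperHz = 0.004) {
  nyq <- 1 / (2 * trSeconds)
  if (fHi >= nyq) {
    stop("configuration error: fHi must be below the Nyquist frequency ",
         signif(nyq, 4), " Hz")
  }
  vec <- is.null(dim(bold))
  Y <- if (vec) matrix(bold, ncol = 1) else bold
  t <- nrow(Y)
  f <- (0:(t - 1)) / (t * trSeconds)
  f <- pmin(f, 1 / trSeconds - f)
  g <- numeric(t)
  g[f >= fLo & f <= fHi] <- 1
  lo <- f > fLo - taperHz & f < fLo
  g[lo] <- 0.5 * (1 - cos(pi * (f[lo] - (fLo - taperHz)) / taperHz))
  hi <- f > fHi & f < fHi + taperHz
  g[hi] <- 0.5 * (1 + cos(pi * (f[hi] - fHi) / taperHz))
  g[f == 0] <- 0
  out <- Re(stats::mvfft(stats::mvfft(Y) * g, inverse = TRUE)) / t
  if (vec) out[, 1] else out
}

#' Voxels of a spherical seed
#'
#' Returns the linear indices of voxels whose world-space centres lie within
#' `radiusMm` of `centerMni` under the given affine.
#'
#' @param centerMni Length-3 world coordinate (mm).
#' @param radiusMm Sphere radius (mm).
#' @param affine 4x4 voxel-to-world map (1-based voxel indices).
#' @param gridShape Integer triple.
#' @return Integer vector of linear voxel indices.
#' @export
seedSphereVoxels <- function(centerMni, radiusMm, affine, gridShape) {
  v <- worldToVoxel(affine, matrix(centerMni, nrow = 1))
  if (any(v < 0.5) || any(v > gridShape + 0.5)) {
    stop("configuration error: seed centre lies outside the grid")
  }
  ijk <- gridIndices(gridShape)
  w <- voxelToWorld(affine, ijk)
  d2 <- (w[, 1] - centerMni[1])^2 + (w[, 2] - centerMni[2])^2 +
    (w[, 3] - centerMni[3])^2
  idx <- which(d2 <= radiusMm^2)
  if (!length(idx)) {
    stop("configuration error: seed sphere contains no voxel centres")
  }
  idx
}

# Frames-in-rows matrix view of a BoldRun.
boldMatrix <- function(run) {
  d <- dim(run@data)
  t(matrix(run@data, prod(d[1:3]), d[4]))
}

#' Seed connectivity map from a processed BOLD matrix
#'
#' Correlates the mean seed time course with every voxel, using uncensored
#' frames only, and Fisher-z transforms the result with r clipped to
#' +/-(1 - 1e-7). Zero-variance voxels receive z = 0 and are flagged; the
#' seed's own voxels are recorded as flagged self-correlations.
#'
#' @param bold `t x V` processed BOLD matrix.
#' @param seedVoxels Linear indices of the seed sphere.
#' @param keep Logical vector of uncensored frames.
#' @param gridShape Integer triple.
#' @param affine 4x4 voxel-to-world map.
#' @param subjectId Subject identifier.
#' @param seedCenterMni,seedRadiusMm Seed specification, recorded as metadata.
#' @return A [SeedMap-class].
#' @export
computeSeedMap <- function(bold, seedVoxels, keep, gridShape, affine,
                           subjectId = "subject",
                           seedCenterMni = c(NA_real_, NA_real_, NA_real_),
                           seedRadiusMm = NA_real_) {
  x <- rowMeans(bold[, seedVoxels, drop = FALSE])[keep]
  Yk <- bold[keep, , drop = FALSE]
  xc <- x - mean(x)
  Yc <- sweep(Yk, 2, colMeans(Yk))
  den <- sqrt(sum(xc^2) * colSums(Yc^2))
  r <- as.numeric(crossprod(xc, Yc))
  flagged <- which(den == 0)
  den[den == 0] <- 1
  r <- r / den
  r[flagged] <- 0
  r <- clamp(r, -(1 - 1e-7), 1 - 1e-7)
  z <- atanh(r)
  z[flagged] <- 0
  new("SeedMap", z = array(z, gridShape), subjectId = subjectId,
      nUncensoredFrames = as.integer(sum(keep)),
      seedCenterMni = as.numeric(seedCenterMni),
      seedRadiusMm = as.numeric(seedRadiusMm),
      seedVoxels = as.integer(seedVoxels),
      flaggedVoxels = as.integer(flagged), affine = affine)
}

#' Run the full per-subject denoising stream and compute the seed map
#'
#' Stage order is fixed: censor -> nuisance regression (uncensored frames
#' only) -> spectral interpolation -> band-pass filter -> correlation on
#' uncensored frames. The executed sequence is returned as a stage log.
#'
#' @param run A [BoldRun-class].
#' @param seedCenterMni Seed centre (mm), default the subgenual cingulate
#'   seed (0, 25, -10).
#' @param seedRadiusMm Seed radius (mm), default 4.
#' @param fdThreshold FD censoring threshold (mm), default 0.25.
#' @param minSegment,minRunUncensored,minUncensoredSeconds Censoring and
#'   inclusion rules (defaults 5 frames, 50 frames, 300 s).
#' @param fLo,fHi Band-pass edges (Hz), defaults 0.009 and 0.08.
#' @param oversample Lomb-Scargle oversampling factor.
#' @param subjectId Subject identifier for the output map.
#' @return List with `included` (logical), `reason` (character when
#'   excluded), `seedMap` ([SeedMap-class] or `NULL`), `censor`
#'   ([CensorMask-class]) and `stageLog` (character vector).
#' @export
subjectSeedMap <- function(run, seedCenterMni = c(0, 25, -10),
                           seedRadiusMm = 4, fdThreshold = 0.25,
                           minSegment = 5L, minRunUncensored = 50L,
                           minUncensoredSeconds = 300,
                           fLo = 0.009, fHi = 0.08, oversample = 8,
                           subjectId = "subject") {
  stageLog <- character(0)
  fd <- computeFD(run@motion)
  censor <- buildCensorMask(fd, fdThreshold, minSegment, minRunUncensored)
  stageLog <- c(stageLog, "censor")
  if (!censor@runIncluded) {
    return(list(included = FALSE, reason = "run has fewer than the minimum uncensored frames",
                seedMap = NULL, censor = censor, stageLog = stageLog))
  }
  if (!subjectInclusion(censor, run@trSeconds, minUncensoredSeconds)) {
    return(list(included = FALSE, reason = "less than the minimum uncensored time across runs",
                seedMap = NULL, censor = censor, stageLog = stageLog))
  }
  grid <- dim(run@data)[1:3]
  seedVox <- seedSphereVoxels(seedCenterMni, seedRadiusMm, run@affine, grid)
  Y <- boldMatrix(run)
  X <- buildNuisanceMatrix(run@motion, Y, run@masks)
  Y <- nuisanceRegress(Y, X, censor@keep)
  stageLog <- c(stageLog, "regress")
  Y <- spectralInterpolate(Y, censor@keep, run@trSeconds, oversample)
  stageLog <- c(stageLog, "interpolate")
  Y <- bandpassFilter(Y, run@trSeconds, fLo, fHi)
  stageLog <- c(stageLog, "bandpass")
  sm <- computeSeedMap(Y, seedVox, censor@keep, grid, run@affine,
                       subjectId = subjectId, seedCenterMni = seedCenterMni,
                       seedRadiusMm = seedRadiusMm)
  stageLog <- c(stageLog, "correlate")
  list(included = TRUE, reason = NA_character_, seedMap = sm,
       censor = censor, stageLog = stageLog)
}
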