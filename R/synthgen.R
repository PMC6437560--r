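# Two-cohort synthetic study generator: phone event streams, PHQ surveys and
# band-limited BOLD runs with known ground truth, so every downstream stage
# can be tested against planted parameters.

# Calendar origin of the synthetic clock. The clock is naive local time with
# no daylight-saving transitions; UTC is used purely as a fixed-offset store.
.streamOrigin <- function() as.POSIXct("2026-01-05 00:00:00", tz = "UTC")

#' Configuration for one synthetic cohort
#'
#' Holds the study-design parameters of one cohort: sample size, the phone
#' sampling regime (continuous screen-time sampling versus remote triggering
#' of a 1-min sampling window every 10 min, extended to at most 3 min when
#' conversation is detected), the planted across-subject correlation between
#' the behavioral covariate and seed-target connectivity, day-to-day
#' circadian consistency, and the imaging geometry.
#'
#' @param nSubjects Positive integer number of subjects.
#' @param samplingMode `"continuous"` or `"duty_cycled"`.
#' @param effectR Target across-subject correlation between the behavioral
#'   covariate and seed-target connectivity, in (-1, 1).
#' @param iccConsistency Day-to-day epoch-profile consistency in \[0, 1\];
#'   larger values yield larger realized circadian-similarity ICCs.
#' @param missingDayRate Probability per day of a sensor outage leaving
#'   under 16 h of coverage, in \[0, 1\].
#' @param motionSpikeRate Per-frame probability of a head-motion spike whose
#'   displacement exceeds the censoring threshold, in \[0, 1\].
#' @param nFrames Frames per BOLD run.
#' @param trSeconds Repetition time in seconds.
#' @param gridShape Integer triple of voxel grid dimensions (each >= 8).
#' @param voxelMm Isotropic voxel size in mm.
#' @param nDays Number of study days of phone data.
#' @param conversationRate Probability that a duty cycle's sampling window is
#'   extended by detected conversation, in \[0, 1\].
#' @param unlockNoiseSd Day-to-day SD (minutes) of the daily unlock total
#'   around its severity-determined mean.
#' @param targetMni,targetRadiusMm Centre (mm) and radius of the planted
#'   target region whose connectivity with the seed covaries with behavior.
#' @param seedMni,seedRadiusMm Centre (mm) and radius of the seed sphere.
#' @param rngSeed Integer seed; all cohort randomness derives from it.
#' @return A validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(nSubjects,
                         samplingMode = c("continuous", "duty_cycled"),
                         effectR = 0.5,
                         iccConsistency = 0.7,
                         missingDayRate = 0.1,
                         motionSpikeRate = 0.03,
                         nFrames = 240L,
                         trSeconds = 2.5,
                         gridShape = c(20L, 24L, 20L),
                         voxelMm = 3,
                         nDays = 35L,
                         conversationRate = 0.3,
                         unlockNoiseSd = 15,
                         targetMni = c(-12, 27, -9),
                         targetRadiusMm = 7.5,
                         seedMni = c(0, 25, -10),
                         seedRadiusMm = 4,
                         rngSeed = 1L) {
  samplingMode <- match.arg(samplingMode)
  if (!isCount(nSubjects)) stop("configuration error: nSubjects must be a positive integer")
  if (!isCount(nDays)) stop("configuration error: nDays must be a positive integer")
  if (!isCount(nFrames)) stop("configuration error: nFrames must be a positive integer")
  if (!(trSeconds > 0)) stop("configuration error: trSeconds must be > 0")
  rates <- c(iccConsistency = iccConsistency, missingDayRate = missingDayRate,
             motionSpikeRate = motionSpikeRate, conversationRate = conversationRate)
  bad <- rates < 0 | rates > 1
  if (any(bad)) {
    stop("configuration error: ", paste(names(rates)[bad], collapse = ", "),
         " must lie in [0, 1]")
  }
  if (!(abs(effectR) < 1)) stop("configuration error: effectR must be in (-1, 1)")
  if (length(gridShape) != 3 || any(gridShape < 8)) {
    stop("configuration error: gridShape must be an integer triple, each >= 8")
  }
  if (!(voxelMm > 0)) stop("configuration error: voxelMm must be > 0")
  structure(list(
    nSubjects = as.integer(nSubjects), samplingMode = samplingMode,
    effectR = effectR, iccConsistency = iccConsistency,
    missingDayRate = missingDayRate, motionSpikeRate = motionSpikeRate,
    nFrames = as.integer(nFrames), trSeconds = trSeconds,
    gridShape = as.integer(gridShape), voxelMm = voxelMm,
    nDays = as.integer(nDays), conversationRate = conversationRate,
    unlockNoiseSd = unlockNoiseSd,
    targetMni = targetMni, targetRadiusMm = targetRadiusMm,
    seedMni = seedMni, seedRadiusMm = seedRadiusMm,
    rngSeed = as.integer(rngSeed)
  ), class = "CohortConfig")
}

# Mean daily unlock minutes as a monotone (logistic) function of latent
# severity on the standard-normal scale.
unlockMeanMinutes <- function(severity) 90 + 150 * stats::plogis(1.2 * severity)

#' Draw per-subject latent parameters for a cohort
#'
#' Each subject receives a latent severity trait (standard normal), a
#' severity-determined mean daily unlock duration, per-subject circadian
#' epoch patterns, and a seed-target connectivity weight of the form
#' `w = a + b * behaviorZ + noise`, constructed so that the across-subject
#' correlation between the behavioral covariate and connectivity equals
#' `effectR` before measurement noise.
#'
#' @param config A [cohortConfig()].
#' @return A `data.frame`, one row per subject, with attributes `a`, `b`
#'   recording the planted linear model of the connectivity weight.
#' @export
simulateSubjectParams <- function(config) {
  n <- config$nSubjects
  withSeed(deriveSeed(config$rngSeed, "subjects"), {
    z <- stats::rnorm(n)
    mu <- unlockMeanMinutes(z)
    behaviorZ <- if (n > 1 && stats::sd(mu) > 0) as.numeric(scale(mu)) else rep(0, n)
    eta <- stats::rnorm(n)
    a <- 0.5; b <- 0.22
    w <- a + b * (config$effectR * behaviorZ +
                    sqrt(1 - config$effectR^2) * eta)
    w <- clamp(w, 0.05, 0.92)
    stillPattern <- matrix(stats::rnorm(3 * n), n, 3)
    locPattern <- matrix(stats::rnorm(3 * n), n, 3)
    out <- data.frame(
      subjectId = sprintf("sub-%03d", seq_len(n)),
      latentSeverity = z,
      meanDailyUnlock = mu,
      behaviorZ = behaviorZ,
      connectivityWeight = w,
      stringsAsFactors = FALSE
    )
    out$stillPattern <- stillPattern
    out$locPattern <- locPattern
    attr(out, "a") <- a
    attr(out, "b") <- b * config$effectR
    out
  })
}

# Half-hourly intensity profile of phone use across the day (48 slots).
.slotProfile <- function() {
  hourly <- c(rep(0.15, 7), rep(0.7, 2), rep(1.0, 9), rep(1.6, 5), 0.6)
  rep(hourly, each = 2)
}

# Duty-cycle observation windows for `nDays` days: a window at the start of
# every 10-min cycle, 60 s long, extended to 180 s when conversation is
# detected in the window.
.dutyCycleWindows <- function(nDays, conversationRate) {
  cyclesPerDay <- 144L
  starts <- rep((0:(nDays - 1)) * 86400, each = cyclesPerDay) +
    rep(600 * (0:(cyclesPerDay - 1)), nDays)
  conv <- stats::runif(length(starts)) < conversationRate
  data.frame(start = starts, end = starts + ifelse(conv, 180, 60))
}

# Intersect intervals (s, e) with a set of disjoint ordered windows.
.clipToWindows <- function(s, e, wStart, wEnd) {
  outS <- numeric(0); outE <- numeric(0); outI <- integer(0)
  for (i in seq_along(s)) {
    j <- which(wEnd > s[i] & wStart < e[i])
    if (length(j)) {
      cs <- pmax(s[i], wStart[j]); ce <- pmin(e[i], wEnd[j])
      keep <- ce > cs
      outS <- c(outS, cs[keep]); outE <- c(outE, ce[keep])
      outI <- c(outI, rep(i, sum(keep)))
    }
  }
  list(start = outS, end = outE, source = outI)
}

#' Generate one subject's phone event stream
#'
#' Produces chronologically ordered, non-overlapping unlock sessions, still
#' intervals and location observations over the configured number of days.
#' Daily unlock totals are a monotone (logistic) function of latent severity
#' plus day-level noise; still minutes and unique-location counts carry an
#' epoch-structured day-to-day consistency governed by `iccConsistency`.
#' Hourly location observations double as a sensor heartbeat from which
#' coverage hours are computed downstream. Under duty-cycled sampling the
#' unlock stream is restricted to the realized observation windows (1 min per
#' 10-min cycle, up to 3 min on detected conversation), which are returned in
#' the `windows` slot.
#'
#' @param subjectParams One row of [simulateSubjectParams()].
#' @param config The [cohortConfig()].
#' @return An [EventStream-class] object.
#' @export
generatePhoneStream <- function(subjectParams, config) {
  sid <- subjectParams$subjectId
  withSeed(deriveSeed(config$rngSeed, paste0("phone:", sid)), {
    nDays <- config$nDays
    icc <- config$iccConsistency
    prof <- .slotProfile()
    profW <- prof / sum(prof)
    epochStartH <- c(day = 9, evening = 18, night = 0)
    epochLenH <- c(day = 9, evening = 6, night = 9)

    stillPat <- as.numeric(subjectParams$stillPattern)
    locPat <- as.numeric(subjectParams$locPattern)
    # epoch-flat baselines: the epoch contrast comes only from the subject's
    # stable pattern, so icc_consistency = 0 really is the null
    stillBase <- c(150, 150, 150)
    locBase <- c(1.5, 1.5, 1.5)

    uS <- numeric(0); uE <- numeric(0)
    sS <- numeric(0); sE <- numeric(0)
    lT <- numeric(0); lLat <- numeric(0); lLon <- numeric(0)

    baseLat <- 43.70 + 0.01 * (deriveSeed(config$rngSeed, sid) %% 100) / 100
    baseLon <- -72.29

    outage <- stats::runif(nDays) < config$missingDayRate
    outageEnd <- 10 * 3600                  # outage days: no sensors 00-10h

    for (d in seq_len(nDays) - 1L) {
      day0 <- d * 86400

      ## unlock sessions
      total <- unlockMeanMinutes(subjectParams$latentSeverity) +
        stats::rnorm(1, 0, config$unlockNoiseSd)
      total <- clamp(total, 0, 400)
      alloc <- total * profW                # minutes per half-hour slot
      on <- alloc > 0.01
      ## jitter the session start inside its slot so that session onsets are
      ## not phase locked to the 10-min duty cycles
      slack <- pmax(0, 1800 - alloc[on] * 60)
      st <- day0 + (which(on) - 1) * 1800 + stats::runif(sum(on)) * slack
      en <- st + alloc[on] * 60
      uS <- c(uS, st); uE <- c(uE, en)

      ## still intervals: one per epoch, epoch-structured consistency
      dayEff <- stats::rnorm(1, 0, 15)        # shared day (rater) effect
      for (e in 1:3) {
        x <- stillBase[e] + 60 * sqrt(icc) * stillPat[e] + dayEff +
          60 * sqrt(1 - icc) * stats::rnorm(1)
        x <- clamp(x, 5, epochLenH[e] * 60 - 10)
        st <- day0 + epochStartH[e] * 3600 + 300
        sS <- c(sS, st); sE <- c(sE, st + x * 60)
      }

      ## hourly location observations (heartbeat + unique-location signal)
      for (e in 1:3) {
        k <- 1 + floor(clamp(locBase[e] + 1.5 * sqrt(icc) * locPat[e] +
                               1.5 * sqrt(1 - icc) * stats::rnorm(1), 0, 4))
        hrs <- epochStartH[e] + 0:(epochLenH[e] - 1)
        cells <- ((seq_along(hrs) - 1) %% k) + 1
        lT <- c(lT, day0 + hrs * 3600 + 1800)
        lLat <- c(lLat, rep(baseLat, length(hrs)))
        lLon <- c(lLon, baseLon + ((e - 1) * 10 + cells) * 0.003)
      }
    }

    ## sensor outages: drop/clip everything before the outage end
    clipOut <- function(s, e, dayIdx) {
      keepDay <- !outage[dayIdx]
      off <- s - (dayIdx - 1) * 86400
      inOut <- !keepDay & (off < outageEnd)
      s2 <- ifelse(inOut, (dayIdx - 1) * 86400 + outageEnd, s)
      ok <- e > s2
      list(start = s2[ok], end = e[ok])
    }
    dIdx <- function(s) floor(s / 86400) + 1L
    un <- clipOut(uS, uE, dIdx(uS)); uS <- un$start; uE <- un$end
    stl <- clipOut(sS, sE, dIdx(sS)); sS <- stl$start; sE <- stl$end
    lo <- outage[dIdx(lT)] & (lT - (dIdx(lT) - 1) * 86400) < outageEnd
    lT <- lT[!lo]; lLat <- lLat[!lo]; lLon <- lLon[!lo]

    ## duty cycling restricts the observed unlock stream
    windows <- data.frame(start = numeric(0), end = numeric(0))
    if (config$samplingMode == "duty_cycled") {
      windows <- .dutyCycleWindows(nDays, config$conversationRate)
      cl <- .clipToWindows(uS, uE, windows$start, windows$end)
      uS <- cl$start; uE <- cl$end
    }

    org <- .streamOrigin()
    events <- rbind(
      data.frame(event_type = "unlock_session", start = uS, end = uE,
                 latitude = NA_real_, longitude = NA_real_),
      data.frame(event_type = "still_interval", start = sS, end = sE,
                 latitude = NA_real_, longitude = NA_real_),
      data.frame(event_type = "location_obs", start = lT, end = NA_real_,
                 latitude = lLat, longitude = lLon)
    )
    events <- events[order(events$start, events$event_type), , drop = FALSE]
    rownames(events) <- NULL
    events$start <- org + events$start
    events$end <- org + events$end
    windows$start <- org + windows$start
    windows$end <- org + windows$end
    new("EventStream", subjectId = sid, events = events,
        samplingMode = config$samplingMode, windows = windows)
  })
}

#' Generate PHQ survey responses for one subject
#'
#' One pre-scan PHQ-8 administration plus weekly PHQ-4 prompts. Each item is
#' an ordinal 0-3 score obtained by thresholding the subject's latent
#' severity plus item noise at fixed standard-normal cutpoints, so item
#' distributions shift stochastically upward with severity. PHQ-4 items 1-2
#' are the depression (PHQ-2) items driven by the same severity trait; items
#' 3-4 are anxiety items driven by a correlated trait.
#'
#' @param subjectParams One row of [simulateSubjectParams()].
#' @param config The [cohortConfig()].
#' @param schedule List with `phq8Day` (scalar) and `phq4Days` (vector of
#'   study days); must contain at least one prompt.
#' @param itemNoiseSd SD of per-item latent noise.
#' @return A `data.frame` with columns `subject_id`, `instrument`,
#'   `item_index`, `score`, `timestamp`.
#' @export
generateSurveys <- function(subjectParams, config,
                            schedule = list(phq8Day = 0,
                                            phq4Days = seq(7, config$nDays, by = 7)),
                            itemNoiseSd = 0.6) {
  if (length(schedule$phq8Day) + length(schedule$phq4Days) < 1) {
    stop("configuration error: survey schedule must contain at least one prompt")
  }
  sid <- subjectParams$subjectId
  sev <- subjectParams$latentSeverity
  cuts <- stats::qnorm(c(0.70, 0.88, 0.97))
  itemScore <- function(latent, n) {
    z <- latent + stats::rnorm(n, 0, itemNoiseSd)
    findInterval(z, cuts)
  }
  withSeed(deriveSeed(config$rngSeed, paste0("survey:", sid)), {
    anx <- 0.6 * sev + 0.8 * stats::rnorm(1)
    org <- .streamOrigin()
    out <- list()
    for (d in schedule$phq8Day) {
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, instrument = "PHQ8", item_index = 1:8,
        score = itemScore(sev, 8),
        timestamp = org + d * 86400 + 10 * 3600)
    }
    for (d in schedule$phq4Days) {
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, instrument = "PHQ4", item_index = 1:4,
        score = c(itemScore(sev, 2), itemScore(anx, 2)),
        timestamp = org + d * 86400 + 19 * 3600)
    }
    do.call(rbind, out)
  })
}

# Band-limited unit-variance noise: white noise FFT-masked to [fLo, fHi].
# Returns an n x ncol matrix. The band sits inside the analysis passband so
# that band-pass filtering preserves planted structure.
bandLimitedNoise <- function(n, tr, ncol = 1, fLo = 0.01, fHi = 0.08) {
  x <- matrix(stats::rnorm(n * ncol), n, ncol)
  f <- (0:(n - 1)) / (n * tr)
  f <- pmin(f, 1 / tr - f)                      # fold to [0, Nyquist]
  pass <- f >= fLo & f <= fHi
  fx <- stats::mvfft(x)
  fx[!pass, ] <- 0
  x <- Re(stats::mvfft(fx, inverse = TRUE)) / n
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- 1
  sweep(x, 2, s, "/")
}

#' Generate one subject's synthetic BOLD run with ground truth
#'
#' Seed voxels share a band-limited (0.01-0.08 Hz) latent signal; target
#' voxels receive that signal scaled by the subject's connectivity weight
#' plus independent band-limited noise, so the voxelwise seed-target
#' correlation approximates the weight. All other voxels carry independent
#' noise; CSF and WM mask voxels share tissue signals. Realignment
#' parameters are a slow drift plus displacement spikes (occurring at
#' `motionSpikeRate` per frame) that exceed the 0.25 mm censoring threshold.
#'
#' @param subjectParams One row of [simulateSubjectParams()].
#' @param config The [cohortConfig()].
#' @return A list with elements `run` ([BoldRun-class]) and `truth` (list
#'   with `seedVoxels`, `targetVoxels`, `connectivityWeight`, `behaviorZ`).
#' @export
generateBoldRun <- function(subjectParams, config) {
  sid <- subjectParams$subjectId
  grid <- config$gridShape
  vox <- config$voxelMm
  affine <- buildAffine(grid, vox, centerWorld = c(0, 10, -5))
  seedVox <- tryCatch(
    seedSphereVoxels(config$seedMni, config$seedRadiusMm, affine, grid),
    error = function(e) stop("configuration error: grid too small to place the seed region"))
  targetVox <- tryCatch(
    seedSphereVoxels(config$targetMni, config$targetRadiusMm, affine, grid),
    error = function(e) stop("configuration error: grid too small to place the target region"))
  if (length(intersect(seedVox, targetVox))) {
    stop("configuration error: seed and target regions overlap on this grid")
  }

  t <- config$nFrames
  V <- prod(grid)
  withSeed(deriveSeed(config$rngSeed, paste0("bold:", sid)), {
    Y <- bandLimitedNoise(t, config$trSeconds, V)
    s <- bandLimitedNoise(t, config$trSeconds, 1)[, 1]
    Y[, seedVox] <- 0.9 * s + sqrt(1 - 0.81) * Y[, seedVox]
    w <- subjectParams$connectivityWeight
    Y[, targetVox] <- w * s + sqrt(1 - w^2) * Y[, targetVox]

    ## masks: ellipsoidal whole-brain, small CSF and WM blocks
    ijk <- gridIndices(grid)
    ctr <- (grid + 1) / 2
    rad <- 0.95 * (grid - 1) / 2
    brain <- array(rowSums(sweep(sweep(ijk, 2, ctr), 2, rad, "/")^2) <= 1, grid)
    csf <- array(FALSE, grid); wm <- array(FALSE, grid)
    cs <- pmax(2, round(ctr + c(0, -7, 0)) - 1)
    csf[cs[1]:(cs[1] + 2), cs[2]:(cs[2] + 2), cs[3]:(cs[3] + 2)] <- TRUE
    ws <- pmax(2, round(ctr + c(4, -3, 2)) - 1)
    wm[ws[1]:(ws[1] + 2), ws[2]:(ws[2] + 2), ws[3]:(ws[3] + 2)] <- TRUE
    csf <- csf & brain; wm <- wm & brain & !csf
    csfIdx <- which(csf); wmIdx <- which(wm)
    csfIdx <- setdiff(csfIdx, c(seedVox, targetVox))
    wmIdx <- setdiff(wmIdx, c(seedVox, targetVox))
    tsigC <- bandLimitedNoise(t, config$trSeconds, 1)[, 1]
    tsigW <- bandLimitedNoise(t, config$trSeconds, 1)[, 1]
    Y[, csfIdx] <- 0.8 * tsigC + 0.6 * Y[, csfIdx]
    Y[, wmIdx] <- 0.8 * tsigW + 0.6 * Y[, wmIdx]
    Y <- Y + matrix(stats::rnorm(t * V, 0, 0.2), t, V)

    ## motion: slow drift plus super-threshold spikes
    motion <- apply(matrix(stats::rnorm(t * 6), t, 6) *
                      rep(c(rep(0.004, 3), rep(8e-5, 3)), each = t), 2, cumsum)
    spikes <- which(stats::runif(t - 1) < config$motionSpikeRate) + 1L
    if (length(spikes) > 1) {                  # adjacent spikes would cancel
      spikes <- spikes[c(TRUE, diff(spikes) > 1)]
    }
    motion[spikes, 1] <- motion[spikes, 1] + 0.45

    run <- new("BoldRun",
               data = array(t(Y), c(grid, t)),
               trSeconds = config$trSeconds, voxelMm = vox,
               affine = affine, motion = motion,
               masks = list(csf = csf, wm = wm, whole_brain = brain))
    truth <- list(seedVoxels = seedVox, targetVoxels = targetVox,
                  connectivityWeight = w,
                  behaviorZ = subjectParams$behaviorZ,
                  spikeFrames = spikes)
    list(run = run, truth = truth)
  })
}

#' Simulate a stack of subject seed maps at the group level
#'
#' A scaled-down generative model used for group-statistics calibration and
#' power studies: each subject's Fisher-z seed map is spatially smooth
#' Gaussian noise (unit variance within the mask), and at the planted target
#' voxels the across-subject correlation with the behavioral covariate
#' equals `effectR` by construction. This skips the per-subject time-series
#' pipeline, isolating the group-level machinery.
#'
#' @param nSubjects Number of subjects.
#' @param gridShape Integer triple.
#' @param mask Logical 3D analysis mask (default: all voxels).
#' @param targetVoxels Linear indices of the planted region (may be empty).
#' @param effectR Planted across-subject correlation at the target voxels.
#' @param fwhmMm Smoothness of the subject maps, mm.
#' @param voxelMm Voxel size, mm.
#' @param rngSeed Integer seed.
#' @return List with `z` (voxels x subjects matrix), `covariate`,
#'   `mask`, `affine`.
#' @export
simulateSeedMapStack <- function(nSubjects, gridShape, mask = NULL,
                                 targetVoxels = integer(0), effectR = 0,
                                 fwhmMm = 6, voxelMm = 3, rngSeed = 1L) {
  V <- prod(gridShape)
  if (is.null(mask)) mask <- array(TRUE, gridShape)
  withSeed(rngSeed, {
    x <- stats::rnorm(nSubjects)
    Z <- matrix(0, V, nSubjects)
    for (i in seq_len(nSubjects)) {
      m <- array(stats::rnorm(V), gridShape)
      if (fwhmMm > 0) m <- gaussianSmooth3d(m, fwhmMm, voxelMm)
      m <- m / stats::sd(m[mask])
      if (length(targetVoxels)) {
        m[targetVoxels] <- effectR * x[i] +
          sqrt(1 - effectR^2) * m[targetVoxels]
      }
      Z[, i] <- as.numeric(m)
    }
    list(z = Z, covariate = x, mask = mask,
         affine = buildAffine(gridShape, voxelMm, centerWorld = c(0, 10, -5)))
  })
}

#' Simulate the phone and survey arm of one cohort
#'
#' @param config A [cohortConfig()].
#' @return List with `params` (subject table), `streams` (list of
#'   [EventStream-class]) and `surveys` (row-bound survey table).
#' @export
simulateCohortPhones <- function(config) {
  params <- simulateSubjectParams(config)
  streams <- lapply(seq_len(config$nSubjects), function(i)
    generatePhoneStream(params[i, , drop = FALSE], config))
  names(streams) <- params$subjectId
  surveys <- do.call(rbind, lapply(seq_len(config$nSubjects), function(i)
    generateSurveys(params[i, , drop = FALSE], config)))
  list(params = params, streams = streams, surveys = surveys)
}
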