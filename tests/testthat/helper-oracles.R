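# Shared oracles and fixture builders for the test suite.

# Independent ANOVA-table oracle for the two-way consistency ICC with
# epochs as targets (columns) and days as raters (rows), complete data.
anovaICCOracle <- function(mat) {
  df <- data.frame(value = as.numeric(mat),
                   epoch = factor(rep(seq_len(ncol(mat)), each = nrow(mat))),
                   day = factor(rep(seq_len(nrow(mat)), ncol(mat))))
  fit <- stats::aov(value ~ epoch + day, data = df)
  tab <- summary(fit)[[1]]
  msEpoch <- tab["epoch", "Mean Sq"]
  msErr <- tab["Residuals", "Mean Sq"]
  k <- nrow(mat)
  (msEpoch - msErr) / (msEpoch + (k - 1) * msErr)
}

# Minimal event stream assembled from explicit events (times in seconds
# from the synthetic-clock origin).
makeStream <- function(unlocks = NULL, stills = NULL, locations = NULL,
                       heartbeatDays = NULL, subjectId = "sub-t",
                       samplingMode = "continuous", windows = NULL) {
  org <- phenoconn:::.streamOrigin()
  rows <- list()
  addIv <- function(type, iv) {
    if (is.null(iv)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      event_type = type, start = iv[, 1], end = iv[, 2],
      latitude = NA_real_, longitude = NA_real_)
  }
  addIv("unlock_session", unlocks)
  addIv("still_interval", stills)
  if (!is.null(locations)) {
    rows[[length(rows) + 1L]] <- data.frame(
      event_type = "location_obs", start = locations[, 1], end = NA_real_,
      latitude = locations[, 2], longitude = locations[, 3])
  }
  if (!is.null(heartbeatDays)) {
    # one observation per hour so every listed day has 24 coverage hours
    hrs <- as.numeric(outer((0:23) * 3600 + 1800, heartbeatDays * 86400, "+"))
    rows[[length(rows) + 1L]] <- data.frame(
      event_type = "location_obs", start = hrs, end = NA_real_,
      latitude = 43.7, longitude = -72.29)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$start, ev$event_type), , drop = FALSE]
  ev$start <- org + ev$start
  ev$end <- org + ev$end
  win <- data.frame(start = org + numeric(0), end = org + numeric(0))
  if (!is.null(windows)) {
    win <- data.frame(start = org + windows[, 1], end = org + windows[, 2])
  }
  new("EventStream", subjectId = subjectId, events = ev,
      samplingMode = samplingMode, windows = win)
}

# Tiny BoldRun with controllable motion and planted voxel series.
makeBoldRun <- function(nFrames = 60, grid = c(10L, 10L, 10L), tr = 2.5,
                        motion = NULL, seed = 1) {
  set.seed(seed)
  V <- prod(grid)
  Y <- matrix(rnorm(nFrames * V), nFrames, V)
  if (is.null(motion)) motion <- matrix(rnorm(nFrames * 6, 0, 0.01), nFrames, 6)
  msk <- function(ix) { m <- array(FALSE, grid); m[ix] <- TRUE; m }
  brain <- array(TRUE, grid)
  new("BoldRun", data = array(t(Y), c(grid, nFrames)), trSeconds = tr,
      voxelMm = 3, affine = phenoconn:::buildAffine(grid, 3),
      motion = motion,
      masks = list(csf = msk(1:8), wm = msk(101:108), whole_brain = brain))
}
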