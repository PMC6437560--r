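# Daily and epoch-level features from phone event streams, with the
# data-quality inclusion rules (16 h coverage per day, 20 valid days per
# subject) applied downstream of feature extraction.

# Epoch windows, local time, half-open: day [09:00, 18:00),
# evening [18:00, 24:00), night [00:00, 09:00).
.epochDef <- function() {
  data.frame(epoch = c("night", "day", "evening"),
             startSec = c(0, 9, 18) * 3600,
             endSec = c(9, 18, 24) * 3600,
             stringsAsFactors = FALSE)
}

#' Epoch lengths in minutes
#' @return Named numeric vector (day = 540, evening = 360, night = 540).
#' @export
epochLengthsMinutes <- function() c(day = 540, evening = 360, night = 540)

# Seconds relative to the stream origin.
.relSeconds <- function(t) as.numeric(t) - as.numeric(.streamOrigin())

# Split intervals [s, e) (seconds from origin) across (day, epoch) cells by
# overlap. Returns a data.frame(day, epoch, seconds, source).
.splitByDayEpoch <- function(s, e) {
  if (!length(s)) {
    return(data.frame(day = integer(0), epoch = character(0),
                      seconds = numeric(0), source = integer(0)))
  }
  ep <- .epochDef()
  d0 <- floor(s / 86400); d1 <- floor((e - 1e-9) / 86400)
  nDaysEach <- pmax(d1 - d0 + 1, 1)
  src <- rep(seq_along(s), nDaysEach)
  day <- unlist(lapply(seq_along(s), function(i) d0[i]:d1[i]), use.names = FALSE)
  sE <- rep(s, nDaysEach); eE <- rep(e, nDaysEach)
  out <- do.call(rbind, lapply(seq_len(nrow(ep)), function(k) {
    ws <- day * 86400 + ep$startSec[k]
    we <- day * 86400 + ep$endSec[k]
    ov <- pmin(eE, we) - pmax(sE, ws)
    sel <- ov > 0
    data.frame(day = day[sel], epoch = rep(ep$epoch[k], sum(sel)),
               seconds = ov[sel], source = src[sel])
  }))
  out[order(out$day, out$source), , drop = FALSE]
}

# Hours of each day touched by any event (the "quality coverage" clock).
.coverageHours <- function(events) {
  s <- .relSeconds(events$start)
  e <- .relSeconds(events$end)
  e[is.na(e)] <- s[is.na(e)] + 1
  h0 <- floor(s / 3600); h1 <- floor((e - 1e-9) / 3600)
  n <- pmax(h1 - h0 + 1, 1)
  hrs <- unlist(lapply(seq_along(s), function(i) h0[i]:h1[i]), use.names = FALSE)
  hrs <- unique(hrs)
  data.frame(day = hrs %/% 24, hour = hrs %% 24)
}

#' Daily unlock duration with validity flags
#'
#' Sums unlock-session durations per calendar day, splitting sessions that
#' cross midnight at the boundary. A day is valid when it has at least
#' `minCoverageHours` hours in which any sensor event was observed.
#'
#' @param stream An [EventStream-class].
#' @param minCoverageHours Coverage-hours validity threshold (default 16).
#' @return `data.frame` with columns `day` (0-based study day),
#'   `unlock_minutes`, `coverage_hours`, `day_valid`.
#' @export
dailyUnlockDuration <- function(stream, minCoverageHours = 16) {
  ev <- stream@events
  if (!nrow(ev)) stop("validation error: event stream is empty")
  un <- ev[ev$event_type == "unlock_session", , drop = FALSE]
  s <- .relSeconds(un$start); e <- .relSeconds(un$end)
  if (nrow(un) > 1) {
    o <- order(s)
    lap <- which(s[o][-1] < e[o][-length(e)])
    if (length(lap)) {
      i <- o[lap[1]]; j <- o[lap[1] + 1]
      stop("input-integrity error: overlapping unlock sessions (",
           fmtIso8601(un$start[i]), " - ", fmtIso8601(un$end[i]), " and ",
           fmtIso8601(un$start[j]), " - ", fmtIso8601(un$end[j]), ")")
    }
  }
  cov <- .coverageHours(ev)
  covTab <- as.data.frame(table(day = cov$day), stringsAsFactors = FALSE)
  covTab$day <- as.integer(covTab$day)
  allDays <- seq(min(covTab$day), max(covTab$day))
  pieces <- .splitByDayEpoch(s, e)
  mins <- tapply(pieces$seconds, factor(pieces$day, levels = allDays),
                 sum, default = 0) / 60
  covH <- covTab$Freq[match(allDays, covTab$day)]
  covH[is.na(covH)] <- 0
  data.frame(day = allDays,
             unlock_minutes = as.numeric(mins),
             coverage_hours = covH,
             day_valid = covH >= minCoverageHours,
             row.names = NULL)
}

#' Subject mean daily unlock duration with the minimum-days rule
#'
#' @param daily Output of [dailyUnlockDuration()].
#' @param minDays Minimum number of valid days for inclusion (default 20).
#' @return List with `included` (logical), `meanUnlockMinutes` (`NA` when
#'   excluded) and `nValidDays`.
#' @export
subjectMeanUnlock <- function(daily, minDays = 20) {
  valid <- daily[daily$day_valid, , drop = FALSE]
  if (nrow(valid) < minDays) {
    list(included = FALSE, meanUnlockMinutes = NA_real_,
         nValidDays = nrow(valid))
  } else {
    list(included = TRUE, meanUnlockMinutes = mean(valid$unlock_minutes),
         nValidDays = nrow(valid))
  }
}

# 100 m square grid cell of a lat/lon observation (equirectangular).
.locationCell <- function(lat, lon, cellM = 100) {
  x <- lon * 111320 * cos(lat * pi / 180)
  y <- lat * 110540
  paste(floor(x / cellM), floor(y / cellM))
}

#' Epoch-level features from an event stream
#'
#' Interval features (`unlock`, `still`) are apportioned to the three daily
#' epochs by overlap; `locations` counts distinct 100 m grid cells per epoch
#' per day.
#'
#' @param stream An [EventStream-class].
#' @param feature One of `"unlock"`, `"still"`, `"locations"`.
#' @return `data.frame` with columns `day`, `epoch`, `value` (minutes for
#'   interval features, counts for locations), complete over the observed
#'   day span.
#' @export
epochPartition <- function(stream, feature = c("unlock", "still", "locations")) {
  feature <- match.arg(feature)
  ev <- stream@events
  if (!nrow(ev)) stop("validation error: event stream is empty")
  allDays <- range(floor(.relSeconds(ev$start) / 86400))
  allDays <- seq(allDays[1], allDays[2])
  epochs <- c("day", "evening", "night")
  grid <- expand.grid(day = allDays, epoch = epochs,
                      stringsAsFactors = FALSE)
  if (feature == "locations") {
    lo <- ev[ev$event_type == "location_obs", , drop = FALSE]
    s <- .relSeconds(lo$start)
    pieces <- .splitByDayEpoch(s, s + 1)
    pieces$cell <- .locationCell(lo$latitude[pieces$source],
                                 lo$longitude[pieces$source])
    key <- paste(pieces$day, pieces$epoch)
    val <- tapply(pieces$cell, key, function(x) length(unique(x)))
    grid$value <- as.numeric(val[paste(grid$day, grid$epoch)])
    grid$value[is.na(grid$value)] <- 0
  } else {
    type <- if (feature == "unlock") "unlock_session" else "still_interval"
    iv <- ev[ev$event_type == type, , drop = FALSE]
    pieces <- .splitByDayEpoch(.relSeconds(iv$start), .relSeconds(iv$end))
    key <- paste(pieces$day, pieces$epoch)
    val <- tapply(pieces$seconds, key, sum) / 60
    grid$value <- as.numeric(val[paste(grid$day, grid$epoch)])
    grid$value[is.na(grid$value)] <- 0
  }
  grid[order(grid$day, grid$epoch), c("day", "epoch", "value")]
}

#' Build the full day x epoch feature table for one subject
#'
#' @param stream An [EventStream-class].
#' @param minCoverageHours Coverage validity threshold (default 16).
#' @param upscale Apply [coverageUpscale()] to the unlock feature for
#'   duty-cycled streams (default `TRUE`).
#' @return `data.frame` with columns `subject_id`, `day`, `epoch`,
#'   `unlock_minutes`, `still_minutes`, `unique_locations`,
#'   `coverage_hours`, `day_valid`.
#' @export
buildDailyEpochTable <- function(stream, minCoverageHours = 16,
                                 upscale = TRUE) {
  un <- epochPartition(stream, "unlock")
  if (upscale && stream@samplingMode == "duty_cycled") {
    un <- coverageUpscale(un, stream@windows)
  }
  st <- epochPartition(stream, "still")
  lo <- epochPartition(stream, "locations")
  daily <- dailyUnlockDuration(stream, minCoverageHours)
  out <- un
  names(out)[names(out) == "value"] <- "unlock_minutes"
  out$still_minutes <- st$value[match(paste(out$day, out$epoch),
                                      paste(st$day, st$epoch))]
  out$unique_locations <- lo$value[match(paste(out$day, out$epoch),
                                         paste(lo$day, lo$epoch))]
  m <- match(out$day, daily$day)
  out$coverage_hours <- daily$coverage_hours[m]
  out$day_valid <- daily$day_valid[m]
  cbind(subject_id = stream@subjectId, out)
}

#' Upscale duty-cycled epoch observations to estimated totals
#'
#' Continuous schedules are returned unchanged. For duty-cycled schedules
#' the observed minutes in each (day, epoch) cell are divided by that cell's
#' realized window-coverage fraction.
#'
#' @param observed `data.frame` with columns `day`, `epoch`, `value`
#'   (observed minutes).
#' @param windows `data.frame` of observation windows (`start`, `end`,
#'   `POSIXct`), or `NULL`/zero rows for continuous sampling.
#' @return `observed` with `value` replaced by the coverage-corrected
#'   estimate (`NA` where a cell had zero coverage and zero observation).
#' @export
coverageUpscale <- function(observed, windows = NULL) {
  if (is.null(windows) || !nrow(windows)) return(observed)
  ws <- .relSeconds(windows$start); we <- .relSeconds(windows$end)
  pieces <- .splitByDayEpoch(ws, we)
  key <- paste(pieces$day, pieces$epoch)
  covSec <- tapply(pieces$seconds, key, sum)
  epLen <- epochLengthsMinutes() * 60
  k <- paste(observed$day, observed$epoch)
  cov <- as.numeric(covSec[k])
  cov[is.na(cov)] <- 0
  frac <- cov / epLen[observed$epoch]
  bad <- frac == 0 & observed$value > 0
  if (any(bad)) {
    stop("integrity error: nonzero observation in a cell with zero ",
         "window coverage (day ", observed$day[which(bad)[1]], ", ",
         observed$epoch[which(bad)[1]], ")")
  }
  est <- ifelse(frac > 0, observed$value / frac,
                ifelse(observed$value == 0, NA_real_, NA_real_))
  out <- observed
  out$value <- est
  out
}
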