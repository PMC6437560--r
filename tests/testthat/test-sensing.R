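# Daily and epoch-level phone features: midnight splitting, coverage
# validity, inclusion rules, epoch apportionment and duty-cycle upscaling.

h <- 3600

test_that("a single session is summed into its calendar day", {
  st <- makeStream(unlocks = cbind(9 * h, 9.5 * h), heartbeatDays = 0)
  d <- dailyUnlockDuration(st)
  expect_equal(d$unlock_minutes[d$day == 0], 30)
})

test_that("sessions crossing midnight are split at the boundary", {
  st <- makeStream(unlocks = cbind(23 * h + 50 * 60, 24 * h + 20 * 60),
                   heartbeatDays = 0:1)
  d <- dailyUnlockDuration(st)
  expect_equal(d$unlock_minutes[d$day == 0], 10)
  expect_equal(d$unlock_minutes[d$day == 1], 20)
})

test_that("days under 16 coverage hours are flagged invalid", {
  # heartbeats only during 15 distinct hours
  loc <- cbind((0:14) * h + 1800, 43.7, -72.29)
  st <- makeStream(unlocks = cbind(10 * h, 11 * h), locations = loc)
  d <- dailyUnlockDuration(st)
  expect_identical(d$coverage_hours[1], 15)
  expect_false(d$day_valid[1])
  loc16 <- cbind((0:15) * h + 1800, 43.7, -72.29)
  d16 <- dailyUnlockDuration(makeStream(unlocks = cbind(10 * h, 11 * h),
                                        locations = loc16))
  expect_true(d16$day_valid[1])
})

test_that("overlapping unlock sessions raise an integrity error naming the pair", {
  # class validity already rejects overlap at construction
  expect_error(makeStream(unlocks = cbind(c(10 * h, 10.5 * h),
                                          c(11 * h, 11.2 * h))),
               "non-overlapping")
  # bypass class validity to exercise the feature-level guard
  st2 <- makeStream(unlocks = cbind(10 * h, 11 * h), heartbeatDays = 0)
  org <- phenoconn:::.streamOrigin()
  bad <- rbind(st2@events,
               data.frame(event_type = "unlock_session",
                          start = org + 10.5 * h, end = org + 11.5 * h,
                          latitude = NA_real_, longitude = NA_real_))
  bad <- bad[order(bad$start), ]
  slot(st2, "events", check = FALSE) <- bad
  expect_error(dailyUnlockDuration(st2), "input-integrity")
})

test_that("the 20-valid-day rule gates the subject mean", {
  mk <- function(nValid) {
    data.frame(day = seq_len(25) - 1,
               unlock_minutes = 60,
               coverage_hours = c(rep(24, nValid), rep(10, 25 - nValid)),
               day_valid = c(rep(TRUE, nValid), rep(FALSE, 25 - nValid)))
  }
  expect_false(subjectMeanUnlock(mk(19))$included)
  r <- subjectMeanUnlock(mk(20))
  expect_true(r$included)
  expect_equal(r$meanUnlockMinutes, 60)
  # monotonicity: raising minDays never re-includes an excluded subject
  for (md in c(21, 25, 30)) {
    expect_false(subjectMeanUnlock(mk(19), minDays = md)$included)
  }
})

test_that("subject mean matches an independent event-level summation", {
  cc <- cohortConfig(1, nDays = 25, missingDayRate = 0, rngSeed = 19L)
  p <- simulateSubjectParams(cc)
  st <- generatePhoneStream(p[1, , drop = FALSE], cc)
  got <- subjectMeanUnlock(dailyUnlockDuration(st))$meanUnlockMinutes
  # brute force: split each session at midnight by hand, then average days
  ev <- streamEvents(st)
  un <- ev[ev$event_type == "unlock_session", ]
  s <- phenoconn:::.relSeconds(un$start); e <- phenoconn:::.relSeconds(un$end)
  perDay <- numeric(25)
  for (i in seq_along(s)) {
    for (d in floor(s[i] / 86400):floor((e[i] - 1e-9) / 86400)) {
      perDay[d + 1] <- perDay[d + 1] +
        (min(e[i], (d + 1) * 86400) - max(s[i], d * 86400)) / 60
    }
  }
  expect_equal(got, mean(perDay), tolerance = 1e-9)
})

test_that("interval features are apportioned to epochs by overlap", {
  st <- makeStream(stills = cbind(17.5 * h, 18.5 * h), heartbeatDays = 0)
  ep <- epochPartition(st, "still")
  expect_equal(ep$value[ep$epoch == "day"], 30)
  expect_equal(ep$value[ep$epoch == "evening"], 30)
  expect_equal(ep$value[ep$epoch == "night"], 0)
  # phone still the whole day: epoch lengths force 540 / 360 / 540
  stFull <- makeStream(stills = cbind(0, 24 * h), heartbeatDays = 0)
  epF <- epochPartition(stFull, "still")
  expect_equal(epF$value[match(c("day", "evening", "night"), epF$epoch)],
               c(540, 360, 540))
})

test_that("locations within one 100 m cell count once per epoch", {
  base <- c(43.7, -72.29)
  loc <- cbind(10 * h + (1:5) * 60, base[1], base[2] + (1:5) * 1e-6)
  st <- makeStream(locations = loc)
  ep <- epochPartition(st, "locations")
  expect_equal(ep$value[ep$epoch == "day"], 1)
  locFar <- cbind(10 * h + (1:3) * 60, base[1], base[2] + (0:2) * 0.005)
  epFar <- epochPartition(makeStream(locations = locFar), "locations")
  expect_equal(epFar$value[epFar$epoch == "day"], 3)
})

test_that("epoch values sum to the daily total for every interval feature", {
  cc <- cohortConfig(1, nDays = 15, rngSeed = 23L)
  p <- simulateSubjectParams(cc)
  st <- generatePhoneStream(p[1, , drop = FALSE], cc)
  for (feat in c("unlock", "still")) {
    ep <- epochPartition(st, feat)
    byDay <- tapply(ep$value, ep$day, sum)
    type <- if (feat == "unlock") "unlock_session" else "still_interval"
    ev <- streamEvents(st)
    iv <- ev[ev$event_type == type, ]
    tot <- sum(as.numeric(iv$end) - as.numeric(iv$start)) / 60
    expect_equal(sum(byDay), tot, tolerance = 1e-9)
  }
})

test_that("daily unlock totals are invariant to event-order shuffling", {
  cc <- cohortConfig(1, nDays = 10, rngSeed = 29L)
  p <- simulateSubjectParams(cc)
  st <- generatePhoneStream(p[1, , drop = FALSE], cc)
  d1 <- dailyUnlockDuration(st)
  set.seed(4)
  sh <- st
  perm <- sample(nrow(sh@events))
  sh@events <- sh@events[perm, ]
  sh@events <- sh@events[order(sh@events$start, sh@events$event_type), ]
  expect_equal(dailyUnlockDuration(sh), d1)
})

test_that("coverage upscaling is the identity for continuous schedules", {
  obs <- data.frame(day = 0, epoch = c("day", "evening", "night"),
                    value = c(30, 20, 5))
  expect_identical(coverageUpscale(obs, NULL), obs)
})

test_that("coverage upscaling divides by the realized window fraction", {
  org <- phenoconn:::.streamOrigin()
  # windows covering 10% of the day epoch only: 54 min within 09:00-18:00
  starts <- 9 * h + (0:53) * 600
  win <- data.frame(start = org + starts, end = org + starts + 60)
  obs <- data.frame(day = 0, epoch = "day", value = 6)
  up <- coverageUpscale(obs, win)
  expect_equal(up$value, 60)
  bad <- data.frame(day = 0, epoch = "night", value = 2)
  expect_error(coverageUpscale(bad, win), "integrity error")
})

test_that("duty-cycled upscaled estimates track the continuous twin", {
  ccC <- cohortConfig(4, "continuous", nDays = 25, missingDayRate = 0,
                      rngSeed = 37L)
  ccD <- cohortConfig(4, "duty_cycled", nDays = 25, missingDayRate = 0,
                      rngSeed = 37L)
  p <- simulateSubjectParams(ccC)
  rel <- numeric(0)
  for (i in 1:4) {
    stC <- generatePhoneStream(p[i, , drop = FALSE], ccC)
    stD <- generatePhoneStream(p[i, , drop = FALSE], ccD)
    epC <- epochPartition(stC, "unlock")
    epD <- coverageUpscale(epochPartition(stD, "unlock"), stD@windows)
    dC <- tapply(epC$value, epC$day, sum)
    dD <- tapply(epD$value, epD$day, sum)
    rel <- c(rel, (dD - dC) / pmax(dC, 1))
  }
  expect_lt(sqrt(mean(rel^2)), 0.2)
})
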