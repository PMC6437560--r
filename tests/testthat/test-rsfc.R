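# Denoising stream: FD arithmetic, censoring rules, Volterra design,
# regression on uncensored frames, spectral interpolation, band-pass
# response, seed geometry and seed-map correlation.

test_that("framewise displacement follows the differentiated-parameter sum", {
  m <- matrix(1, 10, 6)
  expect_equal(computeFD(m), rep(0, 10))
  m2 <- matrix(0, 5, 6); m2[3, 1] <- 0.1
  expect_equal(computeFD(m2), c(0, 0, 0.1, 0.1, 0))
  # 0.01 rad pitch change on a 50 mm sphere is 0.5 mm of arc
  m3 <- matrix(0, 4, 6); m3[3:4, 4] <- 0.01
  expect_equal(computeFD(m3), c(0, 0, 0.5, 0))
  expect_error(computeFD(matrix(0, 5, 5)), "6 columns")
})

test_that("censoring applies the threshold and the short-segment rule", {
  expect_true(all(censorKeep(buildCensorMask(rep(0, 80)))))
  expect_true(runIncluded(buildCensorMask(rep(0, 80))))
  # spikes leaving a 4-frame island: the island is censored too
  fd <- rep(0, 60)
  fd[c(20, 25)] <- 0.4                 # island of frames 21:24
  cm <- buildCensorMask(fd)
  expect_false(any(censorKeep(cm)[20:25]))
  expect_true(all(censorKeep(cm)[1:19]))
  expect_true(all(censorKeep(cm)[26:60]))
  # a 5-frame island survives
  fd5 <- rep(0, 60); fd5[c(20, 26)] <- 0.4
  expect_true(all(censorKeep(buildCensorMask(fd5))[21:25]))
  # boundary: fd exactly at the threshold is kept
  expect_true(all(censorKeep(buildCensorMask(c(0, rep(0.25, 59))))))
})

test_that("run and subject inclusion boundaries are exact", {
  fd49 <- c(rep(0, 49), rep(1, 31))
  expect_false(runIncluded(buildCensorMask(fd49)))
  fd50 <- c(rep(0, 50), rep(1, 30))
  expect_true(runIncluded(buildCensorMask(fd50)))
  mk <- function(nKeep, t = 200) buildCensorMask(c(rep(0, nKeep), rep(1, t - nKeep)))
  expect_true(subjectInclusion(mk(120), 2.5))        # exactly 300 s
  expect_false(subjectInclusion(mk(119), 2.5))
  expect_false(subjectInclusion(mk(250, 400), 1.19)) # 297.5 s
  expect_true(subjectInclusion(mk(253, 400), 1.19))  # 301.07 s
  # excluded runs contribute no frames
  expect_false(subjectInclusion(list(mk(49), mk(60)), 2.5))
})

test_that("raising the FD threshold never discards kept frames", {
  set.seed(8)
  fd <- c(0, abs(rnorm(199, 0.2, 0.15)))
  kept <- vapply(c(0.1, 0.2, 0.25, 0.4, 0.8), function(th)
    sum(censorKeep(buildCensorMask(fd, threshold = th))), integer(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("the Volterra expansion has 36 columns with exact lag structure", {
  set.seed(2)
  m <- matrix(rnorm(120), 20, 6)
  v <- volterraExpand(m)
  expect_identical(ncol(v), 36L)
  expect_equal(v[, 1:6], m, ignore_attr = TRUE)
  expect_equal(v[, 7:12], m^2, ignore_attr = TRUE)
  # unit impulse at frame k appears in the lag columns at k+1 and k+2 only
  imp <- matrix(0, 12, 6); imp[5, 3] <- 1
  vi <- volterraExpand(imp)
  lag1 <- vi[, "tz_lag1"]; lag2 <- vi[, "tz_lag2"]
  expect_equal(which(lag1 != 0), 6L)
  expect_equal(which(lag2 != 0), 7L)
  expect_equal(which(vi[, "tz_lag1_sq"] != 0), 6L)
  # zero motion gives an all-zero motion block
  expect_true(all(volterraExpand(matrix(0, 10, 6)) == 0))
})

test_that("the nuisance matrix has 43 named columns and tissue derivatives", {
  run <- makeBoldRun(nFrames = 60)
  X <- buildNuisanceMatrix(run@motion, run)
  expect_identical(dim(X), c(60L, 43L))
  expect_true(all(c("csf", "wm", "global", "d_csf", "constant") %in% colnames(X)))
  expect_equal(X[, "d_csf"], c(0, diff(X[, "csf"])), ignore_attr = TRUE)
  run@masks$csf[] <- FALSE
  expect_error(buildNuisanceMatrix(run@motion, phenoconn:::boldMatrix(run),
                                   run@masks), "integrity error")
})

test_that("nuisance regression projects on uncensored frames only", {
  set.seed(5)
  t <- 40
  X <- cbind(rnorm(t), rnorm(t), constant = 1)
  keep <- rep(TRUE, t); keep[c(3, 17, 30)] <- FALSE
  # a voxel equal to a regressor is annihilated at uncensored frames
  Y <- cbind(X[, 1], rnorm(t))
  R <- nuisanceRegress(Y, X, keep)
  expect_lt(max(abs(R[keep, 1])), 1e-8)
  # censored-frame values cannot influence the fit
  Y2 <- Y; Y2[!keep, ] <- Y2[!keep, ] + 100
  R2 <- nuisanceRegress(Y2, X, keep)
  expect_equal(R[keep, ], R2[keep, ], tolerance = 1e-10)
  # exactly orthogonal regressors leave the signal minus its mean untouched
  tg <- 0:9
  Xo <- cbind(cos(2 * pi * tg / 10), constant = 1)
  yo <- sin(2 * pi * tg / 10)
  Ro <- nuisanceRegress(matrix(yo), Xo, rep(TRUE, 10))
  expect_equal(Ro[, 1], yo - mean(yo), tolerance = 1e-10)
  # rank deficiency names the offending columns
  Xr <- cbind(a = X[, 1], b = X[, 1], constant = 1)
  expect_error(nuisanceRegress(Y, Xr, keep), "rank deficient")
})

test_that("spectral interpolation reconstructs an in-band sinusoid", {
  tr <- 2.5; n <- 150
  tt <- (0:(n - 1)) * tr
  x <- sin(2 * pi * 0.03 * tt + 0.7)
  set.seed(1)
  keep <- rep(TRUE, n); keep[sample(n, 30)] <- FALSE
  xr <- spectralInterpolate(x, keep, tr)
  expect_identical(xr[keep], x[keep])
  rms <- sqrt(mean((xr[!keep] - x[!keep])^2)) / sqrt(mean(x[!keep]^2))
  expect_lt(rms, 0.10)
  # no censoring: identity
  expect_identical(spectralInterpolate(x, rep(TRUE, n), tr), x)
  # uncensored frames of arbitrary series are untouched bit for bit
  set.seed(2)
  w <- rnorm(n)
  wr <- spectralInterpolate(w, keep, tr)
  expect_identical(wr[keep], w[keep])
  expect_error(spectralInterpolate(x, rep(FALSE, n), tr), "all frames censored")
})

test_that("the band-pass filter rejects DC and out-of-band frequencies", {
  n <- 400; tr <- 2.5
  tt <- (0:(n - 1)) * tr
  expect_lt(max(abs(bandpassFilter(rep(7, n), tr))), 1e-6 * 7)
  gain <- function(f, tr, n) {
    tt <- (0:(n - 1)) * tr
    x <- sin(2 * pi * f * tt)
    sqrt(mean(bandpassFilter(x, tr)^2)) / sqrt(mean(x^2))
  }
  expect_gt(gain(0.04, 2.5, 400), 0.9)
  expect_lt(gain(0.2, 1.19, 600), 0.05)
  expect_error(bandpassFilter(rnorm(100), 10), "Nyquist")
})

test_that("seed sphere selection follows world-space geometry", {
  grid <- c(15L, 15L, 15L)
  aff <- phenoconn:::buildAffine(grid, 3, c(0, 0, 0))
  ctr <- as.numeric(phenoconn:::voxelToWorld(aff, matrix(c(8, 8, 8), 1)))
  expect_identical(length(seedSphereVoxels(ctr, 0.1, aff, grid)), 1L)
  # 4 mm radius on a 3 mm grid at a voxel centre: centre + 6 face neighbors
  v <- seedSphereVoxels(ctr, 4, aff, grid)
  expect_identical(length(v), 7L)
  # brute-force enumeration oracle
  ijk <- phenoconn:::gridIndices(grid)
  w <- phenoconn:::voxelToWorld(aff, ijk)
  oracle <- which(colSums((t(w) - ctr)^2) <= 16)
  expect_identical(sort(v), sort(oracle))
  # translation invariance of relative indices
  aff2 <- aff; aff2[1:3, 4] <- aff2[1:3, 4] + c(30, -12, 9)
  v2 <- seedSphereVoxels(ctr + c(30, -12, 9), 4, aff2, grid)
  expect_identical(sort(v), sort(v2))
  expect_error(seedSphereVoxels(c(500, 0, 0), 4, aff, grid), "outside the grid")
})

test_that("seed-map correlations behave at the analytic anchors", {
  grid <- c(8L, 8L, 8L)
  aff <- phenoconn:::buildAffine(grid, 3)
  n <- 200
  set.seed(6)
  s <- rnorm(n)
  V <- prod(grid)
  Y <- matrix(rnorm(n * V), n, V)
  Y[, 1] <- s
  Y[, 2] <- s                 # identical to the seed mean
  Y[, 3] <- -s                # negated
  Y[, 4] <- 0                 # zero variance
  keep <- rep(TRUE, n)
  sm <- computeSeedMap(Y, 1L, keep, grid, aff)
  z <- zMap(sm)
  expect_equal(z[2], atanh(1 - 1e-7))
  expect_equal(z[3], -atanh(1 - 1e-7))
  expect_identical(z[4], 0)
  expect_true(4L %in% sm@flaggedVoxels)
  expect_true(all(is.finite(z)))
  # signal + equal-variance noise: r concentrates near 1/sqrt(2)
  rs <- vapply(1:100, function(i) {
    y <- s + rnorm(n)
    cor(s, y)
  }, numeric(1))
  expect_true(mean(rs) > 0.6 && mean(rs) < 0.8)
})

test_that("the full stream is deterministic and scale invariant", {
  cc <- cohortConfig(2, nFrames = 150, rngSeed = 55L)
  p <- simulateSubjectParams(cc)
  gen <- generateBoldRun(p[1, , drop = FALSE], cc)
  r1 <- subjectSeedMap(gen$run)
  r2 <- subjectSeedMap(gen$run)
  expect_true(r1$included)
  expect_identical(zMap(r1$seedMap), zMap(r2$seedMap))
  expect_identical(r1$stageLog,
                   c("censor", "regress", "interpolate", "bandpass", "correlate"))
  # rescaling the whole 4D array leaves the seed map unchanged
  run2 <- gen$run
  slot(run2, "data", check = FALSE) <- gen$run@data * 3.14
  r3 <- subjectSeedMap(run2)
  expect_equal(zMap(r3$seedMap), zMap(r1$seedMap), tolerance = 1e-9)
})
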