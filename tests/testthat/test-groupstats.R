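# Group statistics: correlation maps and their invariants, smoothness
# estimation, Monte-Carlo cluster calibration, cluster labeling, masked
# replication and overlap accounting.

test_that("group correlation enforces its contracts and antisymmetry", {
  grid <- c(10L, 10L, 8L)
  st <- simulateSeedMapStack(20, grid, fwhmMm = 0, rngSeed = 2L)
  g <- voxelwiseCorrelate(st$z, st$covariate, st$mask, st$affine, 3)
  expect_identical(g@df, 18L)
  m <- g@analysisMask
  r <- rMap(g)[m]; tt <- tMap(g)[m]
  expect_equal(tt, r * sqrt(18) / sqrt(1 - r^2), tolerance = 1e-8)
  gn <- voxelwiseCorrelate(st$z, -st$covariate, st$mask, st$affine, 3)
  expect_equal(rMap(gn)[m], -r, tolerance = 1e-12)
  expect_equal(tMap(gn)[m], -tt, tolerance = 1e-12)
  expect_error(voxelwiseCorrelate(st$z, rep(1, 20), st$mask, st$affine, 3),
               "constant")
  expect_error(voxelwiseCorrelate(st$z[, 1:2], st$covariate[1:2], st$mask,
                                  st$affine, 3), "at least 3")
})

test_that("a permuted covariate yields the nominal voxelwise false-positive rate", {
  grid <- c(20L, 24L, 20L)
  st <- simulateSeedMapStack(40, grid, fwhmMm = 0, rngSeed = 5L)
  set.seed(11)
  g <- voxelwiseCorrelate(st$z, sample(st$covariate), st$mask, st$affine, 3)
  frac <- mean(pMap(g)[st$mask] < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})

test_that("smoothness estimation recovers a known kernel and scales correctly", {
  grid <- c(20L, 24L, 20L)
  set.seed(3)
  maps6 <- lapply(1:4, function(i)
    phenoconn:::gaussianSmooth3d(array(rnorm(prod(grid)), grid), 6, 3))
  est <- estimateFWHM(maps6, 3)
  expect_gt(est, 6 * 0.8); expect_lt(est, 6 * 1.2)
  # unsmoothed white noise stays near the voxel scale
  mapsW <- lapply(1:4, function(i) array(rnorm(prod(grid)), grid))
  expect_lt(estimateFWHM(mapsW, 3), 1.2 * 3)
  # invariance to global rescaling
  expect_equal(estimateFWHM(lapply(maps6, function(m) m * 42), 3), est,
               tolerance = 1e-10)
  expect_error(estimateFWHM(array(0, c(8, 8, 8)), 3), "zero spatial variance")
})

test_that("cluster labeling distinguishes face, edge and corner adjacency", {
  b <- array(FALSE, c(6, 6, 6))
  b[2, 2, 2] <- TRUE; b[3, 3, 2] <- TRUE      # touch along an edge
  expect_identical(length(labelClusters(b, "face")$sizes), 2L)
  expect_identical(length(labelClusters(b, "edge")$sizes), 1L)
  b2 <- array(FALSE, c(6, 6, 6))
  b2[2, 2, 2] <- TRUE; b2[3, 3, 3] <- TRUE    # touch at a corner only
  expect_identical(length(labelClusters(b2, "face")$sizes), 2L)
  expect_identical(length(labelClusters(b2, "edge")$sizes), 2L)
  expect_identical(length(labelClusters(b2, "corner")$sizes), 1L)
  expect_identical(labelClusters(array(FALSE, c(4, 4, 4)))$sizes, integer(0))
})

test_that("cluster tables report extent, volume and peaks correctly", {
  grid <- c(12L, 12L, 10L)
  tm <- array(0, grid)
  tm[4, 4, 4] <- 6                            # singleton cluster
  tm[7:9, 7:8, 5] <- 5; tm[8, 7, 5] <- 7      # 6-voxel block, known peak
  n <- 52L
  r <- tanh(1)  # placeholder; rebuild consistent maps from t
  df <- n - 2L
  rm <- tm / sqrt(tm^2 + df)
  pm <- 2 * pt(-abs(tm), df)
  gr <- new("GroupResult", rMap = rm, tMap = tm, pMap = pm,
            nSubjects = n, df = df, covariateName = "x",
            analysisMask = array(TRUE, grid), voxelMm = 3,
            affine = phenoconn:::buildAffine(grid, 3))
  cl <- findClusters(gr, 0.01)
  expect_identical(nrow(cl), 2L)
  expect_identical(cl$extent_voxels, c(6L, 1L))         # sorted descending
  expect_equal(cl$volume_mm3, c(6, 1) * 27)
  expect_equal(cl$peak_t[1], 7)
  pk <- phenoconn:::voxelToWorld(gr@affine, matrix(c(8, 7, 5), 1))
  expect_equal(c(cl$peak_x[1], cl$peak_y[1], cl$peak_z[1]), as.numeric(pk))
  # a 584-voxel cluster at 3 mm isotropic occupies 15768 mm^3
  tm2 <- array(0, c(12L, 12L, 10L))
  tm2[seq_len(584)] <- 6                      # x-fastest fill is connected
  gr2 <- new("GroupResult", rMap = tm2 / sqrt(tm2^2 + df), tMap = tm2,
             pMap = 2 * pt(-abs(tm2), df), nSubjects = n, df = df,
             covariateName = "x", analysisMask = array(TRUE, c(12L, 12L, 10L)),
             voxelMm = 3, affine = phenoconn:::buildAffine(c(12L, 12L, 10L), 3))
  cl2 <- findClusters(gr2, 0.01)
  expect_identical(cl2$extent_voxels[1], 584L)
  expect_equal(cl2$volume_mm3[1], 15768)
})

test_that("two independent Monte-Carlo calibrations agree", {
  mask <- array(TRUE, c(20L, 20L, 20L))
  c1 <- clusterExtentThreshold(mask, 0, 0.01, 0.05, 800L, rngSeed = 1L)
  c2 <- clusterExtentThreshold(mask, 0, 0.01, 0.05, 800L, rngSeed = 999L)
  expect_lte(abs(extentThreshold(c1) - extentThreshold(c2)), 1L)
  # determinism under a fixed seed
  c3 <- clusterExtentThreshold(mask, 0, 0.01, 0.05, 800L, rngSeed = 1L)
  expect_identical(c1@nullMaxima, c3@nullMaxima)
})

test_that("the extent threshold is non-decreasing in smoothness", {
  mask <- array(TRUE, c(16L, 16L, 16L))
  th <- vapply(c(0, 4, 8), function(fw)
    extentThreshold(clusterExtentThreshold(mask, fw, 0.01, 0.05, 400L,
                                           rngSeed = 7L)), integer(1))
  expect_true(all(diff(th) >= 0))
})

test_that("masked replication reduces to unmasked analysis on the full mask", {
  grid <- c(12L, 12L, 10L)
  tg <- seq_len(30)
  st <- simulateSeedMapStack(40, grid, targetVoxels = tg, effectR = 0.6,
                             fwhmMm = 4, rngSeed = 9L)
  g <- voxelwiseCorrelate(st$z, st$covariate, st$mask, st$affine, 3)
  full <- array(TRUE, grid)
  rep1 <- maskReplicate(g, full, 0.01, fwhmMm = 4, nIterations = 400L,
                        rngSeed = 3L)
  cl <- findClusters(g, 0.01, rep1$calibration, signs = "positive")
  expect_equal(rep1$clusters$extent_voxels, cl$extent_voxels)
  # an off-effect mask yields an empty table
  offMask <- array(FALSE, grid); offMask[prod(grid) - (0:40)] <- TRUE
  rep2 <- maskReplicate(g, offMask, 0.01, fwhmMm = 4, nIterations = 400L,
                        rngSeed = 3L)
  expect_identical(nrow(rep2$clusters), 0L)
  expect_error(maskReplicate(g, array(FALSE, grid), 0.01, 4), "empty")
})

test_that("overlap accounting satisfies the set identities", {
  grid <- c(8L, 8L, 8L)
  A <- array(FALSE, grid); A[1:20] <- TRUE
  B <- array(FALSE, grid); B[1:50] <- TRUE
  C <- array(FALSE, grid); C[200:210] <- TRUE
  ov <- overlapReport(list(a = A, b = B, c = C))
  pw <- ov$pairwise
  expect_identical(pw$n_overlap[pw$a == "a" & pw$b == "b"], 20L)  # A subset B
  expect_identical(pw$n_overlap[pw$a == "a" & pw$b == "c"], 0L)   # disjoint
  expect_identical(overlapReport(list(x = A, y = A))$pairwise$n_overlap, 20L)
  expect_true(all(pw$n_overlap <= pmin(pw$n_a, pw$n_b)))
  expect_identical(ov$kway$n, 0L)
})

test_that("group result invariants are enforced by the class validity", {
  grid <- c(6L, 6L, 6L)
  st <- simulateSeedMapStack(10, grid, fwhmMm = 0, rngSeed = 4L)
  g <- voxelwiseCorrelate(st$z, st$covariate, st$mask, st$affine, 3)
  bad <- g
  expect_error({slot(bad, "df") <- 5L; validObject(bad)}, "df must equal")
})
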