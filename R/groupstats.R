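# Group-level machinery: voxelwise across-subject correlation of seed maps
# with a behavioral covariate, Gaussian-smoothness Monte-Carlo cluster-extent
# correction, cohort-mask replication and overlap reporting.

#' Voxelwise across-subject correlation of seed maps with a covariate
#'
#' For every voxel inside the mask, the Pearson correlation across subjects
#' between the Fisher-z seed-map values and the covariate. Degrees of
#' freedom are N - 2; `t = r * sqrt(df) / sqrt(1 - r^2)` and p is two-tailed.
#'
#' @param zStack Voxels x subjects matrix of Fisher-z values, or a list of
#'   [SeedMap-class] objects (stacked with [stackSeedMaps()]).
#' @param covariate Numeric vector, one value per subject.
#' @param mask Logical 3D analysis mask.
#' @param affine 4x4 voxel-to-world map (taken from the maps when a list is
#'   given).
#' @param voxelMm Voxel size in mm.
#' @param covariateName Label recorded in the result.
#' @return A [GroupResult-class].
#' @export
voxelwiseCorrelate <- function(zStack, covariate, mask, affine = NULL,
                               voxelMm = 3, covariateName = "covariate") {
  if (is.list(zStack)) {
    st <- stackSeedMaps(zStack)
    if (is.null(affine)) affine <- st$affine
    zStack <- st$z
  }
  n <- ncol(zStack)
  if (n < 3) stop("validation error: at least 3 subjects are required")
  if (length(covariate) != n) {
    stop("validation error: covariate length must equal the number of subjects")
  }
  if (any(!is.finite(covariate))) {
    stop("validation error: covariate must be finite")
  }
  if (stats::sd(covariate) == 0) {
    stop("validation error: covariate is constant")
  }
  if (is.null(affine)) affine <- buildAffine(dim(mask), voxelMm)
  df <- n - 2L
  cc <- covariate - mean(covariate)
  zm <- rowMeans(zStack)
  num <- as.numeric(zStack %*% cc) - sum(cc) * zm   # sum(cc) == 0
  den <- sqrt(pmax(rowSums(zStack^2) - length(cc) * zm^2, 0) * sum(cc^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  r <- clamp(r, -1, 1)
  rt <- clamp(r, -(1 - 1e-12), 1 - 1e-12)
  tt <- rt * sqrt(df) / sqrt(1 - rt^2)
  pp <- 2 * stats::pt(-abs(tt), df)
  dimn <- dim(mask)
  shape <- function(x) { x[!mask] <- NA_real_; array(x, dimn) }
  new("GroupResult",
      rMap = shape(r), tMap = shape(tt), pMap = shape(pp),
      nSubjects = as.integer(n), df = df,
      covariateName = covariateName,
      analysisMask = mask & array(is.finite(r), dimn),
      voxelMm = voxelMm, affine = affine)
}

#' Stack a list of seed maps into a voxels x subjects matrix
#'
#' @param seedMaps List of [SeedMap-class] objects on a common grid.
#' @return List with `z` (matrix), `affine`, `gridShape`, `subjectIds`.
#' @export
stackSeedMaps <- function(seedMaps) {
  stopifnot(length(seedMaps) >= 1)
  grid <- dim(seedMaps[[1]]@z)
  z <- vapply(seedMaps, function(sm) {
    stopifnot(identical(dim(sm@z), grid))
    as.numeric(sm@z)
  }, numeric(prod(grid)))
  list(z = z, affine = seedMaps[[1]]@affine, gridShape = grid,
       subjectIds = vapply(seedMaps, function(sm) sm@subjectId, character(1)))
}

# Separable Gaussian smoothing of a 3D array. Kernel rows are renormalized
# at the edges so the filter preserves a constant field.
gaussianSmooth3d <- function(arr, fwhmMm, voxelMm) {
  if (fwhmMm <= 0) return(arr)
  sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / voxelMm
  d <- dim(arr)
  kmat <- function(n) {
    K <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
    K / rowSums(K)
  }
  m <- kmat(d[1]) %*% matrix(arr, d[1], d[2] * d[3])
  arr <- array(m, d)
  arr <- aperm(arr, c(2, 1, 3))
  m <- kmat(d[2]) %*% matrix(arr, d[2], d[1] * d[3])
  arr <- aperm(array(m, d[c(2, 1, 3)]), c(2, 1, 3))
  arr <- aperm(arr, c(3, 2, 1))
  m <- kmat(d[3]) %*% matrix(arr, d[3], d[2] * d[1])
  aperm(array(m, d[c(3, 2, 1)]), c(3, 2, 1))
}

#' Estimate the Gaussian-equivalent spatial smoothness of maps
#'
#' Estimates the full width at half maximum of the equivalent Gaussian
#' autocorrelation from the variance of spatial first differences relative
#' to the total variance: for a Gaussian random field,
#' `FWHM = voxel * sqrt(-2 log(2) / log(1 - vd / (2 v)))` where `vd` is the
#' variance of adjacent-voxel differences and `v` the field variance. The
#' estimate is averaged over the three axes and over maps, and is invariant
#' to global rescaling.
#'
#' @param maps A 3D array, a list of 3D arrays, or a voxels x maps matrix
#'   (with `gridShape` supplied).
#' @param voxelMm Voxel size in mm.
#' @param mask Optional logical 3D mask; differences use voxel pairs fully
#'   inside the mask.
#' @param gridShape Required when `maps` is a matrix.
#' @return FWHM in mm.
#' @export
estimateFWHM <- function(maps, voxelMm, mask = NULL, gridShape = NULL) {
  if (is.matrix(maps) && !is.null(gridShape)) {
    maps <- lapply(seq_len(ncol(maps)), function(i) array(maps[, i], gridShape))
  } else if (!is.list(maps)) {
    maps <- list(maps)
  }
  if (length(maps) < 1) stop("validation error: at least one map required")
  est <- unlist(lapply(maps, function(m) {
    d <- dim(m)
    if (is.null(mask)) mask <- array(TRUE, d)
    v <- stats::var(m[mask])
    if (!is.finite(v) || v == 0) {
      stop("validation error: map has zero spatial variance")
    }
    vapply(1:3, function(ax) {
      i1 <- slice.index(m, ax) < d[ax]
      mShift <- aperm(m, c(ax, setdiff(1:3, ax)))
      mskShift <- aperm(mask, c(ax, setdiff(1:3, ax)))
      a <- mShift[-d[ax], , , drop = FALSE]; b <- mShift[-1, , , drop = FALSE]
      ma <- mskShift[-d[ax], , , drop = FALSE]; mb <- mskShift[-1, , , drop = FALSE]
      dd <- (b - a)[ma & mb]
      if (length(dd) < 2) return(NA_real_)
      ratio <- stats::var(dd) / (2 * v)
      ratio <- clamp(ratio, 1e-6, 1 - 1e-6)
      voxelMm * sqrt(-2 * log(2) / log(1 - ratio))
    }, numeric(1))
  }))
  mean(est, na.rm = TRUE)
}

# Neighbor offsets for a connectivity level (half-space, no duplicates).
.connOffsets <- function(connectivity = c("face", "edge", "corner")) {
  connectivity <- match.arg(connectivity)
  face <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  edge <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))
  corner <- rbind(c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  switch(connectivity, face = face, edge = rbind(face, edge),
         corner = rbind(face, edge, corner))
}

#' Label connected clusters in a binary 3D array
#'
#' Groups `TRUE` voxels into connected components under the requested
#' adjacency (face = 6-neighbor default; edge = 18; corner = 26).
#'
#' @param bin Logical 3D array.
#' @param connectivity `"face"`, `"edge"` or `"corner"`.
#' @return List with `labels` (integer 3D array, 0 = background) and
#'   `sizes` (integer vector of cluster extents, by label).
#' @export
labelClusters <- function(bin, connectivity = "face") {
  d <- dim(bin)
  idx <- which(bin)
  if (!length(idx)) {
    return(list(labels = array(0L, d), sizes = integer(0)))
  }
  vmap <- integer(prod(d))
  vmap[idx] <- seq_along(idx)
  AI <- array(seq_len(prod(d)), d)
  offs <- .connOffsets(connectivity)
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    r1 <- lapply(1:3, function(i) {
      if (o[i] >= 0) seq_len(d[i] - o[i]) else seq(1 - o[i], d[i])
    })
    r2 <- lapply(1:3, function(i) r1[[i]] + o[i])
    A1 <- do.call(`[`, c(list(AI), r1, list(drop = FALSE)))
    A2 <- do.call(`[`, c(list(AI), r2, list(drop = FALSE)))
    sel <- bin[A1] & bin[A2]
    if (any(sel)) edges <- rbind(edges, cbind(vmap[A1[sel]], vmap[A2[sel]]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  labels <- array(0L, d)
  labels[idx] <- as.integer(comp)
  list(labels = labels, sizes = as.integer(tabulate(comp)))
}

# Internal: maximum suprathreshold cluster extent of one simulated smooth
# Gaussian null volume within a mask.
.nullMaxExtent <- function(dimn, mask, fwhmMm, voxelMm, zCrit, connectivity) {
  vol <- array(stats::rnorm(prod(dimn)), dimn)
  if (fwhmMm > 0) vol <- gaussianSmooth3d(vol, fwhmMm, voxelMm)
  s <- stats::sd(vol[mask])
  supra <- (abs(vol) > zCrit * s) & mask
  cl <- labelClusters(supra, connectivity)
  if (length(cl$sizes)) max(cl$sizes) else 0L
}

#' Monte-Carlo cluster-extent threshold for smooth Gaussian null volumes
#'
#' Simulates `nIterations` white-noise volumes smoothed to `fwhmMm`,
#' standardizes within the mask, thresholds at the two-tailed voxelwise p,
#' and records the maximum cluster extent of each. The extent threshold is
#' the smallest cluster size whose null exceedance probability is at most
#' `correctedAlpha`.
#'
#' @param mask Logical 3D analysis mask (non-empty).
#' @param fwhmMm Gaussian-equivalent smoothness of the null (mm).
#' @param voxelP Voxelwise two-tailed threshold, in (0,1).
#' @param correctedAlpha Corrected cluster false-positive rate, in (0,1).
#' @param nIterations Number of null volumes (>= 1000 recommended for
#'   reported thresholds).
#' @param rngSeed Integer seed for the simulation.
#' @param voxelMm Voxel size (mm).
#' @param connectivity Cluster adjacency (default `"face"`).
#' @return A [NullCalibration-class].
#' @export
clusterExtentThreshold <- function(mask, fwhmMm, voxelP,
                                   correctedAlpha = 0.05,
                                   nIterations = 1000L, rngSeed = 1L,
                                   voxelMm = 3, connectivity = "face") {
  if (!sum(mask)) stop("validation error: mask is empty")
  if (voxelP <= 0 || voxelP >= 1 || correctedAlpha <= 0 || correctedAlpha >= 1) {
    stop("validation error: voxelP and correctedAlpha must lie in (0,1)")
  }
  if (nIterations < 100) {
    stop("validation error: at least 100 iterations are required")
  }
  dimn <- dim(mask)
  zCrit <- stats::qnorm(1 - voxelP / 2)
  maxima <- withSeed(rngSeed, {
    vapply(seq_len(nIterations), function(i)
      .nullMaxExtent(dimn, mask, fwhmMm, voxelMm, zCrit, connectivity),
      integer(1))
  })
  k <- 1L
  while (mean(maxima >= k) > correctedAlpha) k <- k + 1L
  new("NullCalibration", fwhmMm = fwhmMm, voxelP = voxelP,
      nIterations = as.integer(nIterations), extentThreshold = k,
      correctedAlpha = correctedAlpha, rngSeed = as.integer(rngSeed),
      nullMaxima = as.integer(maxima))
}

#' Cluster table of a group result
#'
#' Thresholds the t map at the two-tailed voxelwise p, groups suprathreshold
#' voxels by the requested adjacency (positive and negative clusters
#' separately), and reports peaks, extents and volumes. When a
#' [NullCalibration-class] is supplied, `passed_correction` marks clusters
#' at or above the extent threshold.
#'
#' @param result A [GroupResult-class].
#' @param voxelP Voxelwise two-tailed threshold.
#' @param calibration Optional [NullCalibration-class].
#' @param connectivity Cluster adjacency (default `"face"`).
#' @param signs `"both"`, `"positive"` or `"negative"`.
#' @param mask Optional logical 3D array restricting the analysis.
#' @return `data.frame` with columns `label`, `sign`, `peak_x`, `peak_y`,
#'   `peak_z` (world mm), `peak_t`, `extent_voxels`, `volume_mm3`,
#'   `passed_correction`, sorted by extent descending. Zero rows when no
#'   voxel is suprathreshold.
#' @export
findClusters <- function(result, voxelP, calibration = NULL,
                         connectivity = "face",
                         signs = c("both", "positive", "negative"),
                         mask = NULL) {
  signs <- match.arg(signs)
  tcrit <- stats::qt(1 - voxelP / 2, result@df)
  amask <- result@analysisMask
  if (!is.null(mask)) amask <- amask & mask
  tm <- result@tMap
  rows <- list()
  wanted <- switch(signs, both = c(1, -1), positive = 1, negative = -1)
  for (sgn in wanted) {
    supra <- !is.na(tm) & (sgn * tm > tcrit) & amask
    cl <- labelClusters(supra, connectivity)
    for (lab in seq_along(cl$sizes)) {
      vox <- which(cl$labels == lab)
      pk <- vox[which.max(abs(tm[vox]))]
      pw <- voxelToWorld(result@affine,
                         matrix(arrayInd(pk, dim(tm)), nrow = 1))
      rows[[length(rows) + 1L]] <- data.frame(
        sign = if (sgn > 0) "positive" else "negative",
        peak_x = pw[1], peak_y = pw[2], peak_z = pw[3],
        peak_t = tm[pk],
        extent_voxels = cl$sizes[lab],
        volume_mm3 = cl$sizes[lab] * result@voxelMm^3,
        passed_correction = if (is.null(calibration)) NA else
          cl$sizes[lab] >= calibration@extentThreshold,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$voxels <- I(list(vox))
    }
  }
  if (!length(rows)) {
    return(data.frame(label = integer(0), sign = character(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0), peak_t = numeric(0),
                      extent_voxels = integer(0), volume_mm3 = numeric(0),
                      passed_correction = logical(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$extent_voxels), , drop = FALSE]
  out <- cbind(label = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Replicate an analysis within another cohort's cluster mask
#'
#' Thresholds `resultB` only within `clusterMaskA` (e.g. the union of
#' volume-corrected cluster voxels from the discovery cohort), with the
#' cluster-extent correction re-calibrated within the mask volume. By
#' default only positive clusters are reported, matching a directed
#' replication of a positive relationship; set `positiveOnly = FALSE` for
#' both signs.
#'
#' @param resultB A [GroupResult-class] from the replication cohort.
#' @param clusterMaskA Logical 3D mask from the discovery cohort.
#' @param voxelP Voxelwise two-tailed threshold.
#' @param fwhmMm Smoothness for the within-mask null calibration.
#' @param correctedAlpha Corrected alpha (default 0.05).
#' @param nIterations Monte-Carlo iterations (default 1000).
#' @param rngSeed Seed for the calibration.
#' @param positiveOnly Report positive clusters only (default `TRUE`).
#' @param connectivity Cluster adjacency.
#' @return List with `clusters` (cluster table) and `calibration`
#'   ([NullCalibration-class]).
#' @export
maskReplicate <- function(resultB, clusterMaskA, voxelP, fwhmMm,
                          correctedAlpha = 0.05, nIterations = 1000L,
                          rngSeed = 1L, positiveOnly = TRUE,
                          connectivity = "face") {
  if (!identical(dim(clusterMaskA), dim(resultB@tMap))) {
    stop("validation error: mask shape does not match the result maps")
  }
  m <- clusterMaskA & resultB@analysisMask
  if (!sum(m)) stop("validation error: replication mask is empty")
  cal <- clusterExtentThreshold(m, fwhmMm, voxelP, correctedAlpha,
                                nIterations, rngSeed, resultB@voxelMm,
                                connectivity)
  cl <- findClusters(resultB, voxelP, cal, connectivity,
                     signs = if (positiveOnly) "positive" else "both",
                     mask = m)
  list(clusters = cl, calibration = cal)
}

#' Voxel overlap report across cluster masks
#'
#' Pairwise and k-way voxel intersections of two or more binary masks, with
#' the world coordinate of the intersection peak when a statistic map is
#' supplied.
#'
#' @param masks Named list of logical 3D arrays on a common grid.
#' @param statMap Optional 3D statistic map used to locate intersection
#'   peaks (by absolute value).
#' @param affine 4x4 voxel-to-world map for peak coordinates.
#' @return List with `pairwise` (`data.frame`: `a`, `b`, `n_a`, `n_b`,
#'   `n_overlap`) and `kway` (list: `n`, `peak_xyz` or `NULL`).
#' @export
overlapReport <- function(masks, statMap = NULL, affine = NULL) {
  stopifnot(length(masks) >= 2)
  d <- dim(masks[[1]])
  for (m in masks) stopifnot(identical(dim(m), d))
  nm <- names(masks)
  if (is.null(nm)) nm <- paste0("mask", seq_along(masks))
  cmb <- utils::combn(length(masks), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
    i1 <- cmb[1, j]; i2 <- cmb[2, j]
    data.frame(a = nm[i1], b = nm[i2],
               n_a = sum(masks[[i1]]), n_b = sum(masks[[i2]]),
               n_overlap = sum(masks[[i1]] & masks[[i2]]),
               stringsAsFactors = FALSE)
  }))
  inter <- Reduce(`&`, masks)
  peak <- NULL
  if (sum(inter) && !is.null(statMap) && !is.null(affine)) {
    vox <- which(inter)
    pk <- vox[which.max(abs(statMap[vox]))]
    peak <- as.numeric(voxelToWorld(affine,
                                    matrix(arrayInd(pk, d), nrow = 1)))
  }
  list(pairwise = pairwise, kway = list(n = sum(inter), peak_xyz = peak))
}

#' Binary mask of the voxels in corrected (or all) clusters
#'
#' @param clusters Cluster table from [findClusters()].
#' @param gridShape Integer triple.
#' @param passedOnly Keep only clusters with `passed_correction` (default
#'   `TRUE`; tables built without a calibration have `NA` there and are
#'   kept only when `passedOnly = FALSE`).
#' @return Logical 3D array.
#' @export
clusterMask <- function(clusters, gridShape, passedOnly = TRUE) {
  m <- array(FALSE, gridShape)
  if (!nrow(clusters)) return(m)
  sel <- if (passedOnly) which(clusters$passed_correction %in% TRUE)
         else seq_len(nrow(clusters))
  for (i in sel) m[clusters$voxels[[i]]] <- TRUE
  m
}
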