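# Internal helpers shared across modules.

#' Derive a stage-specific RNG seed from a master seed
#'
#' Sub-seeds are derived from a master integer seed by hashing a stable
#' text label, so that adding or reordering pipeline stages never perturbs
#' the random draws of other stages. The result is always a non-negative
#' integer below 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param label Character scalar naming the consumer (e.g. `"bold:sub-001"`).
#' @return A single integer seed.
#' @export
deriveSeed <- function(master, label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  # one multiplicative scramble so nearby labels diverge
  as.integer((h * 48271) %% m)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# World coordinates (mm) of voxel centres for a grid under an affine.
# ijk is an n x 3 matrix of 1-based voxel indices.
voxelToWorld <- function(affine, ijk) {
  ijk <- rbind(t(ijk), 1)
  t(affine %*% ijk)[, 1:3, drop = FALSE]
}

worldToVoxel <- function(affine, xyz) {
  xyz <- rbind(t(xyz), 1)
  t(solve(affine) %*% xyz)[, 1:3, drop = FALSE]
}

# Axis-aligned affine for a grid whose centre sits at `centerWorld`.
buildAffine <- function(gridShape, voxelMm, centerWorld = c(0, 0, 0)) {
  a <- diag(c(rep(voxelMm, 3), 1))
  a[1:3, 4] <- centerWorld - voxelMm * (gridShape + 1) / 2
  a
}

# All voxel indices of a grid as an n x 3 integer matrix (x fastest).
gridIndices <- function(gridShape) {
  arrayInd(seq_len(prod(gridShape)), .dim = gridShape)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)

fmtIso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")

parseIso8601 <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
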