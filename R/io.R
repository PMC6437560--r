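# File interfaces: TSV event/survey/feature tables, NIfTI-1 volumes with a
# JSON sidecar for seed maps, 6-column motion text and cluster tables.

# NIfTI sform uses 0-based voxel indices; the package affine is 1-based.
.affineToSform <- function(affine) {
  s <- affine
  s[1:3, 4] <- affine[1:3, 4] + rowSums(affine[1:3, 1:3, drop = FALSE])
  s
}

.sformToAffine <- function(s) {
  a <- s
  a[1:3, 4] <- s[1:3, 4] - rowSums(s[1:3, 1:3, drop = FALSE])
  a
}

#' Write an event stream as TSV
#'
#' Columns: `subject_id`, `event_type`, `start_iso8601`, `end_iso8601`,
#' `latitude`, `longitude`. Duty-cycle observation windows, when present,
#' are written alongside as `<path>.windows.tsv`.
#'
#' @param stream An [EventStream-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeEventStream <- function(stream, path) {
  ev <- stream@events
  out <- data.frame(subject_id = stream@subjectId,
                    event_type = ev$event_type,
                    start_iso8601 = fmtIso8601(ev$start),
                    end_iso8601 = ifelse(is.na(ev$end), "",
                                         fmtIso8601(ev$end)),
                    latitude = ev$latitude, longitude = ev$longitude)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (nrow(stream@windows)) {
    win <- data.frame(start_iso8601 = fmtIso8601(stream@windows$start),
                      end_iso8601 = fmtIso8601(stream@windows$end))
    utils::write.table(win, paste0(path, ".windows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an event stream from TSV
#'
#' @param path TSV path written by [writeEventStream()].
#' @param samplingMode Sampling mode to record; inferred as `duty_cycled`
#'   when a `.windows.tsv` companion exists.
#' @return An [EventStream-class].
#' @export
readEventStream <- function(path, samplingMode = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "")
  winPath <- paste0(path, ".windows.tsv")
  windows <- data.frame(start = parseIso8601(character(0)),
                        end = parseIso8601(character(0)))
  if (file.exists(winPath)) {
    w <- utils::read.table(winPath, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    windows <- data.frame(start = parseIso8601(w$start_iso8601),
                          end = parseIso8601(w$end_iso8601))
  }
  if (is.null(samplingMode)) {
    samplingMode <- if (nrow(windows)) "duty_cycled" else "continuous"
  }
  events <- data.frame(event_type = tab$event_type,
                       start = parseIso8601(tab$start_iso8601),
                       end = parseIso8601(ifelse(is.na(tab$end_iso8601) |
                                                   tab$end_iso8601 == "",
                                                 NA, tab$end_iso8601)),
                       latitude = tab$latitude, longitude = tab$longitude)
  new("EventStream", subjectId = tab$subject_id[1], events = events,
      samplingMode = samplingMode, windows = windows)
}

#' Write a survey response table as TSV
#' @param surveys Long survey table ([generateSurveys()] schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSurveyTable <- function(surveys, path) {
  surveys$timestamp <- fmtIso8601(surveys$timestamp)
  utils::write.table(surveys, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a survey response table from TSV
#' @param path TSV path.
#' @return Long survey `data.frame`.
#' @export
readSurveyTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tab$timestamp <- parseIso8601(tab$timestamp)
  tab
}

#' Write a 3D/4D volume as NIfTI-1
#'
#' @param arr Numeric array (logical arrays are stored as 0/1).
#' @param path Output `.nii` or `.nii.gz` path.
#' @param affine 4x4 voxel-to-world map (1-based voxel indices).
#' @param voxelMm Voxel size (mm).
#' @param trSeconds Repetition time, written to `pixdim[4]` for 4D data.
#' @return `path`, invisibly.
#' @export
writeNiftiVolume <- function(arr, path, affine, voxelMm = 3,
                             trSeconds = NULL) {
  img <- RNifti::asNifti(array(as.numeric(arr), dim(arr)))
  nd <- length(dim(arr))
  pd <- rep(voxelMm, 3)
  if (nd == 4) pd <- c(pd, if (is.null(trSeconds)) 1 else trSeconds)
  img <- RNifti::`pixdim<-`(img, pd)
  img <- RNifti::`sform<-`(img, structure(.affineToSform(affine), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume and its affine
#' @param path NIfTI path.
#' @return List with `data` (array), `affine` (1-based voxel-to-world),
#'   `voxelMm`, `trSeconds` (4D only).
#' @export
readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(data = array(as.numeric(img), dim(img)),
       affine = .sformToAffine(unclass(RNifti::xform(img))[1:4, 1:4]),
       voxelMm = pd[1],
       trSeconds = if (length(dim(img)) == 4) pd[4] else NA_real_)
}

#' Assemble a BoldRun from NIfTI + motion text + mask files
#'
#' @param boldPath 4D NIfTI path.
#' @param motionPath 6-column whitespace-delimited realignment text file.
#' @param maskPaths Named list/character vector with entries `csf`, `wm`,
#'   `whole_brain` (3D 0/1 NIfTI paths).
#' @param trSeconds Repetition time; default taken from `pixdim[4]`.
#' @return A [BoldRun-class].
#' @export
readBoldRun <- function(boldPath, motionPath, maskPaths, trSeconds = NULL) {
  vol <- readNiftiVolume(boldPath)
  motion <- as.matrix(utils::read.table(motionPath))
  dimnames(motion) <- NULL
  masks <- lapply(maskPaths[c("csf", "wm", "whole_brain")], function(p) {
    m <- readNiftiVolume(p)$data
    array(m != 0, dim(m))
  })
  new("BoldRun", data = vol$data,
      trSeconds = if (is.null(trSeconds)) vol$trSeconds else trSeconds,
      voxelMm = vol$voxelMm, affine = vol$affine,
      motion = motion, masks = masks)
}

#' Write realignment parameters as 6-column text
#' @param motion `t x 6` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMotionParams <- function(motion, path) {
  utils::write.table(format(motion, digits = 10), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a seed map as NIfTI with a JSON sidecar
#'
#' The sidecar records the subject id, uncensored frame count, seed
#' specification and the executed stage sequence.
#'
#' @param seedMap A [SeedMap-class].
#' @param path Output `.nii` path (sidecar at `<path>.json`).
#' @param stageLog Character vector of executed stages.
#' @return `path`, invisibly.
#' @export
writeSeedMap <- function(seedMap, path, stageLog = character(0)) {
  writeNiftiVolume(seedMap@z, path, seedMap@affine,
                   voxelMm = abs(seedMap@affine[1, 1]))
  side <- list(subject_id = seedMap@subjectId,
               n_uncensored = seedMap@nUncensoredFrames,
               seed_center_mni = seedMap@seedCenterMni,
               seed_radius_mm = seedMap@seedRadiusMm,
               stage_log = stageLog)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a cluster table as TSV and JSON
#' @param clusters Cluster table from [findClusters()].
#' @param path Base path; writes `<path>.tsv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeClusterTable <- function(clusters, path) {
  out <- clusters[, setdiff(names(clusters), "voxels"), drop = FALSE]
  utils::write.table(out, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(out, paste0(path, ".json"), digits = NA,
                       dataframe = "rows")
  invisible(path)
}
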