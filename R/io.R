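## Delimited-text serialization of cohort data. Every container round-trips
## through plain TSV (plus a small YAML sidecar for scalar attributes), so a
## generated cohort can be written to disk and re-analyzed identically in
## file mode.

#' @importFrom data.table fread fwrite
NULL

writeMeta <- function(meta, path) yaml::write_yaml(meta, path)
readMeta <- function(path) yaml::read_yaml(path)

#' Read and write cohort components as delimited text
#'
#' Trial tables and lick trains are plain TSV; neural sessions are a TSV
#' matrix (first column `roi_id`, one column per frame) with a `.meta.yaml`
#' sidecar holding the frame rate, mouse id and epoch; keypoint tracks are
#' wide TSV (`frame`, then `<node>.x`, `<node>.y`, `<node>.conf` per node)
#' with fps and calibration in the sidecar.
#'
#' @param trials,licks,session,track The objects to serialize.
#' @param path Output file path (`.tsv`; the sidecar adds `.meta.yaml`).
#' @return Readers return the deserialized object; writers return the path,
#'   invisibly.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
writeTrials <- function(trials, path) {
  fwrite(trials, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname cohort-io
#' @export
readTrials <- function(path) {
  as.data.frame(fread(path, sep = "\t", na.strings = "NA"))
}

#' @rdname cohort-io
#' @export
writeLicks <- function(licks, path) {
  fwrite(data.table::data.table(timestamp_s = licks), path, sep = "\t")
  invisible(path)
}

#' @rdname cohort-io
#' @export
readLicks <- function(path) {
  as.data.frame(fread(path, sep = "\t"))$timestamp_s %||% numeric()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname cohort-io
#' @export
writeNeural <- function(session, path) {
  dt <- data.table::data.table(roi_id = roiIds(session))
  dt <- cbind(dt, data.table::as.data.table(activityMatrix(session)))
  fwrite(dt, path, sep = "\t")
  writeMeta(list(frame_rate = frameRate(session), mouse_id = mouseId(session),
                 epoch = epochOf(session)), paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname cohort-io
#' @export
readNeural <- function(path) {
  dt <- fread(path, sep = "\t")
  meta <- readMeta(paste0(path, ".meta.yaml"))
  neuralSession(as.matrix(dt[, -1]), frameRate = meta$frame_rate,
                roiIds = dt$roi_id, mouseId = meta$mouse_id,
                epoch = meta$epoch)
}

#' @rdname cohort-io
#' @export
writeKeypoints <- function(track, path) {
  co <- track@coords
  cols <- list(frame = seq_len(dim(co)[1]))
  for (i in seq_along(track@nodes)) {
    nd <- track@nodes[i]
    cols[[paste0(nd, ".x")]] <- co[, i, 1]
    cols[[paste0(nd, ".y")]] <- co[, i, 2]
    cols[[paste0(nd, ".conf")]] <- co[, i, 3]
  }
  fwrite(data.table::as.data.table(cols), path, sep = "\t")
  writeMeta(list(fps = track@fps,
                 px_per_cm = if (is.na(track@pxPerCm)) NULL else track@pxPerCm,
                 nodes = as.list(track@nodes)), paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname cohort-io
#' @export
readKeypoints <- function(path) {
  dt <- fread(path, sep = "\t")
  meta <- readMeta(paste0(path, ".meta.yaml"))
  nodes <- unlist(meta$nodes)
  co <- array(NA_real_, c(nrow(dt), length(nodes), 3))
  for (i in seq_along(nodes)) {
    co[, i, 1] <- dt[[paste0(nodes[i], ".x")]]
    co[, i, 2] <- dt[[paste0(nodes[i], ".y")]]
    co[, i, 3] <- dt[[paste0(nodes[i], ".conf")]]
  }
  keypointTrack(co, nodes = nodes, fps = meta$fps,
                pxPerCm = meta$px_per_cm %||% NA_real_)
}

#' Write a synthetic cohort to a directory
#'
#' Materializes and serializes the requested epochs of every mouse:
#' `mice.tsv`, `behavior.tsv`, `roi_match.tsv` (all pairs of written
#' epochs), and per session `<mouse>_<epoch>.{trials,licks,neural,keypoints}.tsv`.
#' The resulting directory can be analyzed in file mode via
#' [runFullAnalysis()] and reproduces the in-memory results.
#'
#' @param cohort A [generateCohort()] result.
#' @param dir Output directory (created if needed).
#' @param epochs Epochs to materialize (default: all in the cohort config).
#' @param withNeural,withKeypoints Toggle the heavy components.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, epochs = cohort@config@epochs,
                        withNeural = TRUE, withKeypoints = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(cohortMice(cohort), file.path(dir, "mice.tsv"), sep = "\t")
  fwrite(cohortBehavior(cohort), file.path(dir, "behavior.tsv"), sep = "\t")
  if (length(epochs) > 1L) {
    pairs <- utils::combn(epochs, 2)
    match <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j)
      cohortRoiMatch(cohort, pairs[1, j], pairs[2, j])))
    fwrite(match, file.path(dir, "roi_match.tsv"), sep = "\t")
  }
  for (m in cohortMice(cohort)$mouse_id) {
    for (ep in epochs) {
      s <- cohortSession(cohort, m, ep, withNeural = withNeural,
                         withKeypoints = withKeypoints)
      stem <- file.path(dir, paste0(m, "_", ep))
      writeTrials(s$trials, paste0(stem, ".trials.tsv"))
      writeLicks(s$licks, paste0(stem, ".licks.tsv"))
      if (!is.null(s$neural)) writeNeural(s$neural, paste0(stem, ".neural.tsv"))
      if (!is.null(s$keypoints))
        writeKeypoints(s$keypoints, paste0(stem, ".keypoints.tsv"))
    }
  }
  writeMeta(list(epochs = as.list(epochs)), file.path(dir, "cohort.meta.yaml"))
  invisible(dir)
}

#' Read one serialized session back from a cohort directory
#'
#' @param dir Cohort directory written by [writeCohort()].
#' @param mouseId,epoch Which session.
#' @return A list like [generateSession()]'s (`trials`, `licks`, `neural`,
#'   `keypoints`; missing components are `NULL`).
#' @rdname writeCohort
#' @export
readCohortSession <- function(dir, mouseId, epoch) {
  stem <- file.path(dir, paste0(mouseId, "_", epoch))
  if (!file.exists(paste0(stem, ".trials.tsv")))
    stopf("missing session file: %s.trials.tsv", stem)
  list(trials = readTrials(paste0(stem, ".trials.tsv")),
       licks = readLicks(paste0(stem, ".licks.tsv")),
       neural = if (file.exists(paste0(stem, ".neural.tsv")))
         readNeural(paste0(stem, ".neural.tsv")) else NULL,
       keypoints = if (file.exists(paste0(stem, ".keypoints.tsv")))
         readKeypoints(paste0(stem, ".keypoints.tsv")) else NULL)
}
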