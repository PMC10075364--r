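# Session container I/O: raw little-endian float32 LFP + JSON sidecar,
# tracking CSV + JSON sidecar, ground-truth JSON, key-value (YAML) config.

#' Write an LFP recording to disk
#'
#' Writes \code{<path>.bin}: channel-major little-endian float32 samples,
#' and \code{<path>.json}: a sidecar with \code{n_channels},
#' \code{n_samples}, \code{fs}, \code{channel_labels}, \code{ttl_s},
#' \code{dtype} and \code{order}.
#'
#' @param lfp an [LfpRecording-class].
#' @param path file stem (no extension).
#' @return invisibly, the two file paths.
#' @export
writeLfpRecording <- function(lfp, path) {
  stopifnot(is(lfp, "LfpRecording"))
  bin <- paste0(path, ".bin")
  side <- paste0(path, ".json")
  con <- file(bin, "wb")
  on.exit(close(con))
  # channel-major: each channel's samples contiguous
  writeBin(as.numeric(t(lfpData(lfp))), con, size = 4, endian = "little")
  meta <- list(
    n_channels = nChannels(lfp),
    n_samples = ncol(lfpData(lfp)),
    fs = samplingRate(lfp),
    channel_labels = channelLabels(lfp),
    ttl_s = ttlTimes(lfp),
    dtype = "float32le",
    order = "channel_major"
  )
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(bin = bin, sidecar = side))
}

#' Read an LFP recording written by [writeLfpRecording()]
#'
#' @param path file stem (no extension).
#' @return an [LfpRecording-class].
#' @export
readLfpRecording <- function(path) {
  side <- paste0(path, ".json")
  bin <- paste0(path, ".bin")
  if (!file.exists(side) || !file.exists(bin)) {
    stop("missing LFP container file(s): ", path, ".{bin,json}")
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  con <- file(bin, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = meta$n_channels * meta$n_samples,
                  size = 4, endian = "little")
  data <- matrix(vals, nrow = meta$n_channels, byrow = TRUE)
  LfpRecording(data, meta$fs, channelLabels = meta$channel_labels,
               ttl = as.numeric(meta$ttl_s))
}

#' Write a tracking trace to CSV (+ JSON sidecar)
#'
#' CSV columns: \code{frame}, \code{t_s}, \code{x_m}, \code{y_m}; sidecar
#' records frame rate, arena side and camera-clock TTL times.
#'
#' @param tracking a [TrackingTrace-class].
#' @param path file stem (no extension).
#' @return invisibly, the two file paths.
#' @export
writeTrackingCsv <- function(tracking, path) {
  stopifnot(is(tracking, "TrackingTrace"))
  csv <- paste0(path, ".csv")
  side <- paste0(path, ".json")
  utils::write.csv(
    data.frame(frame = tracking@frame, t_s = tracking@t,
               x_m = tracking@x, y_m = tracking@y),
    csv, row.names = FALSE)
  jsonlite::write_json(
    list(frame_rate = tracking@frameRate, arena_side_m = tracking@arenaSide,
         ttl_s = tracking@ttl),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, sidecar = side))
}

#' Read a tracking trace written by [writeTrackingCsv()]
#'
#' @param path file stem (no extension).
#' @return a [TrackingTrace-class].
#' @export
readTrackingCsv <- function(path) {
  csv <- paste0(path, ".csv")
  side <- paste0(path, ".json")
  if (!file.exists(csv)) stop("missing tracking file: ", csv)
  d <- utils::read.csv(csv)
  meta <- if (file.exists(side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    list(frame_rate = 1 / stats::median(diff(d$t_s)), arena_side_m = NA,
         ttl_s = numeric())
  }
  TrackingTrace(t = d$t_s, x = d$x_m, y = d$y_m,
                frameRate = meta$frame_rate, arenaSide = meta$arena_side_m,
                ttl = as.numeric(meta$ttl_s), frame = d$frame)
}

#' Write synthetic-session ground truth to JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path output file path.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  jsonlite::write_json(
    list(swr_events = truth@swrEvents,
         frame_state = truth@frameState,
         pac_depth_by_state = as.list(truth@pacDepthByState),
         theta_amp_by_state = as.list(truth@thetaAmpByState),
         state_schedule = truth@stateSchedule),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pipeline/simulation config from a key-value (YAML) file
#'
#' @param path YAML file path.
#' @return named list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  yaml::read_yaml(path)
}
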