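# End-to-end orchestration: simulate or load a session, segment behavior,
# run the spectral / PAC / SWR stages, and write diff-friendly CSV/JSON
# outputs with a provenance manifest.

.defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    simulate = list(),          # sessionConfig() overrides; NULL = load
    lfp_path = NULL,            # file stems for loading a recorded session
    tracking_path = NULL,
    behavior = list(exploration_min = 0.05, zero_tol = 1e-3, min_dur = 1),
    pac = list(
      channel = NULL,           # default: pyramidal-labeled channel
      band_pairs = list(
        list(state = "exploration", phase = c(6.5, 10), amp = c(55, 90)),
        list(state = "exploration", phase = c(6.5, 9), amp = c(35, 45)),
        list(state = "wake_immobility", phase = c(6.5, 9), amp = c(60, 90))
      ),
      comodulogram = FALSE      # expensive; off by default in the pipeline
    ),
    swr = list(core = 3, edge = 2, min_dur_ms = 30, min_psf_hz = 140,
               sw_thresh = 2.5, sw_dur_ms = c(20, 400),
               slow_gamma_band = c(30, 45)),
    openfield = list(inner_fraction = 0.5, window_s = 300)
  )
}

# recursively overlay user config onto defaults
.mergeConfig <- function(defaults, override) {
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], override[[nm]])
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}

#' Simulate a session and write its files
#'
#' @param config a [SessionConfig-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file stems/paths.
#' @export
simulateToFiles <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ses <- simSession(config)
  p1 <- writeLfpRecording(ses$lfp, file.path(dir, "lfp"))
  p2 <- writeTrackingCsv(ses$tracking, file.path(dir, "tracking"))
  p3 <- writeGroundTruth(ses$truth, file.path(dir, "ground_truth.json"))
  invisible(list(lfp = p1, tracking = p2, truth = p3))
}

#' Run the full analysis pipeline
#'
#' Executes simulate-or-load, behavioral segmentation, band power, tPAC
#' (and optionally a comodulogram), SWR detection and the open-field
#' metrics, writing per-stage CSV/JSON outputs plus a provenance manifest
#' to \code{outDir}. Deterministic: rerunning with the same config produces
#' byte-identical tables.
#'
#' @param config named list (see package vignette), e.g. from
#'   [readPipelineConfig()]; missing entries take the package defaults.
#' @param outDir output directory.
#' @return invisibly, a list of the in-memory stage results.
#' @export
runPipeline <- function(config = list(), outDir) {
  cfg <- .mergeConfig(.defaultPipelineConfig(), config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$simulate)) {
    simCfg <- do.call(sessionConfig,
                      c(cfg$simulate, list(seed = as.integer(cfg$seed))))
    ses <- simSession(simCfg)
    lfp <- ses$lfp
    tracking <- ses$tracking
    writeGroundTruth(ses$truth, file.path(outDir, "ground_truth.json"))
  } else {
    if (is.null(cfg$lfp_path) || is.null(cfg$tracking_path)) {
      stop("config must provide lfp_path and tracking_path when not simulating")
    }
    lfp <- readLfpRecording(cfg$lfp_path)
    tracking <- readTrackingCsv(cfg$tracking_path)
  }

  # --- behavior ---
  epochs <- segmentSession(tracking, lfp,
                           explorationMin = cfg$behavior$exploration_min,
                           zeroTol = cfg$behavior$zero_tol,
                           minDur = cfg$behavior$min_dur)
  utils::write.csv(epochs, file.path(outDir, "epochs.csv"),
                   row.names = FALSE)

  # --- spectral ---
  power <- bandPowerTable(lfp, epochs)
  utils::write.csv(power, file.path(outDir, "band_power.csv"),
                   row.names = FALSE)
  kTop <- min(3, nChannels(lfp))
  summaries <- do.call(rbind, lapply(canonicalBands()$name, function(b) {
    s <- topChannelSummary(power, b, k = kTop)
    s$band <- b
    s
  }))
  utils::write.csv(summaries, file.path(outDir, "band_power_top3.csv"),
                   row.names = FALSE)

  # --- PAC ---
  pacCh <- cfg$pac$channel
  if (is.null(pacCh)) pacCh <- which(channelLabels(lfp) == "pyramidal")[1]
  if (is.na(pacCh)) pacCh <- 1L
  x <- lfpData(lfp)[pacCh, ]
  fs <- samplingRate(lfp)
  tpacRows <- list()
  for (bp in cfg$pac$band_pairs) {
    eps <- epochs[epochs$state == bp$state, , drop = FALSE]
    if (!nrow(eps)) next
    series <- tryCatch(
      tpac(x, fs, eps, phaseBand = bp$phase, ampBand = bp$amp),
      error = function(e) NULL)
    if (is.null(series)) next
    tpacRows[[length(tpacRows) + 1L]] <- data.frame(
      state = bp$state,
      phase_lo = bp$phase[1], phase_hi = bp$phase[2],
      amp_lo = bp$amp[1], amp_hi = bp$amp[2],
      n_windows = length(miValues(series)),
      mean_mi = subjectMean(series))
  }
  tpacTab <- if (length(tpacRows)) do.call(rbind, tpacRows) else
    data.frame(state = character(), phase_lo = numeric(),
               phase_hi = numeric(), amp_lo = numeric(),
               amp_hi = numeric(), n_windows = integer(),
               mean_mi = numeric())
  utils::write.csv(tpacTab, file.path(outDir, "tpac.csv"),
                   row.names = FALSE)
  comod <- NULL
  if (isTRUE(cfg$pac$comodulogram)) {
    comod <- computeComodulogram(x, fs, epochs)
    cm <- miMatrix(comod)
    dimnames(cm) <- list(phase_hz = comod@phaseFreqs,
                         amp_hz = comod@ampFreqs)
    utils::write.csv(cm, file.path(outDir, "comodulogram.csv"))
  }

  # --- SWR ---
  events <- tryCatch(
    detectSwr(lfp, epochs,
              core = cfg$swr$core, edge = cfg$swr$edge,
              minDurMs = cfg$swr$min_dur_ms, minPsfHz = cfg$swr$min_psf_hz,
              swThresh = cfg$swr$sw_thresh, swDurMs = cfg$swr$sw_dur_ms,
              slowGammaBand = cfg$swr$slow_gamma_band),
    error = function(e) {
      message("SWR stage failed: ", conditionMessage(e))
      NULL
    })
  if (!is.null(events)) {
    utils::write.csv(events, file.path(outDir, "swr_events.csv"),
                     row.names = FALSE)
  }
  ratio <- tryCatch(
    suppressWarnings(swrOccurrenceRatio(events, epochs)),
    error = function(e) NA_real_)

  # --- open field ---
  ofm <- openFieldMetrics(tracking,
                          innerFraction = cfg$openfield$inner_fraction,
                          windowS = cfg$openfield$window_s)
  utils::write.csv(ofm$per_epoch, file.path(outDir, "openfield_windows.csv"),
                   row.names = FALSE)

  metrics <- list(
    n_epochs = nrow(epochs),
    epoch_seconds_by_state = as.list(tapply(
      epochs$end_s - epochs$start_s, epochs$state, sum)),
    n_swr_events = if (is.null(events)) NA else nrow(events),
    swr_occurrence_ratio = ratio,
    total_distance_m = ofm$total_distance_m,
    inner_time_s = ofm$inner_time_s,
    inner_distance_m = ofm$inner_distance_m,
    inner_entries = ofm$inner_entries
  )
  jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(cfg, cfgPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    package = "hippolfp",
    version = as.character(utils::packageVersion("hippolfp")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfgPath))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = cfg, epochs = epochs, power = power,
                 tpac = tpacTab, comodulogram = comod, events = events,
                 occurrence_ratio = ratio, openfield = ofm))
}
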