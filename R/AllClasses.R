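#' @import methods
NULL

.STATES <- c("exploration", "grooming", "wake_immobility")

#' Multichannel LFP recording
#'
#' Container for a laminar local field potential recording: a channels x
#' samples matrix in microvolts, the sampling rate, per-channel layer labels
#' and TTL synchronization pulse times on the recording clock.
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector, one label per channel (e.g.
#'   \code{"pyramidal"}, \code{"radiatum"}, \code{"other"}).
#' @slot ttl numeric vector of TTL pulse times in seconds (LFP clock).
#'
#' @seealso [LfpRecording()] for the constructor, [simSession()] for the
#'   synthetic generator.
#' @export
setClass("LfpRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    ttl = "numeric"
  )
)

setValidity("LfpRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) {
    msg <- c(msg, "data must be a numeric matrix")
  }
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (nrow(object@data) != length(object@channelLabels)) {
    msg <- c(msg, "channelLabels must have one entry per channel (row)")
  }
  dur <- ncol(object@data) / object@fs
  if (length(object@ttl) && (any(object@ttl < 0) || any(object@ttl > dur))) {
    msg <- c(msg, "ttl times must lie within the recording")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an LfpRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param channelLabels character vector of per-channel layer labels;
#'   defaults to \code{"other"} for every channel.
#' @param ttl TTL pulse times in seconds on the LFP clock.
#' @return an [LfpRecording-class] object.
#' @export
LfpRecording <- function(data, fs, channelLabels = NULL, ttl = numeric()) {
  data <- as.matrix(data)
  if (is.null(channelLabels)) channelLabels <- rep("other", nrow(data))
  new("LfpRecording", data = data, fs = as.numeric(fs),
      channelLabels = as.character(channelLabels), ttl = as.numeric(ttl))
}

#' Animal tracking trace
#'
#' Center-of-body positions from overhead video tracking of an open-field
#' trial, on the camera clock, together with the TTL pulse times seen by the
#' camera system (used to align tracking to LFP time).
#'
#' @slot frame integer frame indices (0-based).
#' @slot t frame times in seconds (camera clock), strictly increasing.
#' @slot x,y positions in meters.
#' @slot frameRate nominal frame rate, Hz.
#' @slot arenaSide side length of the square arena, meters.
#' @slot ttl TTL pulse times in seconds (camera clock).
#' @export
setClass("TrackingTrace",
  representation(
    frame = "integer",
    t = "numeric",
    x = "numeric",
    y = "numeric",
    frameRate = "numeric",
    arenaSide = "numeric",
    ttl = "numeric"
  )
)

setValidity("TrackingTrace", function(object) {
  msg <- character()
  n <- length(object@t)
  if (length(object@x) != n || length(object@y) != n ||
      length(object@frame) != n) {
    msg <- c(msg, "frame, t, x, y must have equal length")
  }
  if (n > 1 && any(diff(object@t) <= 0)) {
    msg <- c(msg, "t must be strictly increasing")
  }
  if (length(object@arenaSide) != 1L || object@arenaSide <= 0) {
    msg <- c(msg, "arenaSide must be a single positive number")
  }
  tol <- 1e-9
  if (n && (min(object@x, object@y) < -tol ||
            max(object@x, object@y) > object@arenaSide + tol)) {
    msg <- c(msg, "positions must lie within [0, arenaSide]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TrackingTrace
#'
#' @param t frame times (s, camera clock).
#' @param x,y positions (m).
#' @param frameRate frames per second.
#' @param arenaSide arena side length (m).
#' @param ttl TTL times (s, camera clock).
#' @param frame frame indices (0-based); derived from \code{t} if missing.
#' @return a [TrackingTrace-class] object.
#' @export
TrackingTrace <- function(t, x, y, frameRate, arenaSide, ttl = numeric(),
                          frame = NULL) {
  if (is.null(frame)) frame <- seq_along(t) - 1L
  new("TrackingTrace", frame = as.integer(frame), t = as.numeric(t),
      x = as.numeric(x), y = as.numeric(y), frameRate = as.numeric(frameRate),
      arenaSide = as.numeric(arenaSide), ttl = as.numeric(ttl))
}

#' Synthetic session configuration
#'
#' Parameters of one synthetic CA1 session: a laminar 16-channel LFP built
#' from 1/f background noise, state-gated theta, theta-phase-modulated gamma
#' and injected sharp wave-ripple events, plus a tracking trace following a
#' scheduled sequence of behavioral bouts.
#'
#' @slot stateSchedule data.frame with columns \code{state} and
#'   \code{duration} (s); states run back to back in order.
#' @slot fs LFP sampling rate, Hz.
#' @slot nChannels number of channels on the laminar probe.
#' @slot pyramidalChannel,radiatumChannel 1-based indices of the pyramidal
#'   layer channel (ripples, PAC) and stratum radiatum channel (sharp waves).
#' @slot noiseExponent spectral slope alpha of the 1/f^alpha background.
#' @slot noiseAmp background noise standard deviation, microvolts.
#' @slot thetaFreq theta frequency, Hz.
#' @slot thetaAmpByState named numeric: theta amplitude (microvolts) per
#'   behavioral state.
#' @slot gammaFreq,gammaAmp gamma carrier frequency (Hz) and base amplitude
#'   (microvolts).
#' @slot pacDepthByState named numeric in [0,1]: depth of theta-phase
#'   modulation of the gamma envelope per state.
#' @slot swrRateByState named numeric: SWR event rate (events/s) per state.
#' @slot rippleFreq,rippleDurMs,rippleAmp ripple burst frequency (Hz),
#'   duration (ms) and amplitude (microvolts).
#' @slot swAmp,swDurMs sharp-wave deflection amplitude (microvolts) and
#'   width (ms).
#' @slot thetaChannelGains per-channel gain applied to theta and gamma;
#'   length \code{nChannels}.
#' @slot frameRate tracking frame rate, Hz.
#' @slot arenaSide arena side, meters.
#' @slot speedByState named numeric: locomotion speed (m/s) used for the
#'   tracking trace in each state.
#' @slot cameraClockOffset,cameraClockDrift camera clock model: camera time
#'   = offset + (1 + drift) * LFP time.
#' @slot seed integer RNG seed.
#' @export
setClass("SessionConfig",
  representation(
    stateSchedule = "data.frame",
    fs = "numeric",
    nChannels = "integer",
    pyramidalChannel = "integer",
    radiatumChannel = "integer",
    noiseExponent = "numeric",
    noiseAmp = "numeric",
    thetaFreq = "numeric",
    thetaAmpByState = "numeric",
    gammaFreq = "numeric",
    gammaAmp = "numeric",
    pacDepthByState = "numeric",
    swrRateByState = "numeric",
    rippleFreq = "numeric",
    rippleDurMs = "numeric",
    rippleAmp = "numeric",
    swAmp = "numeric",
    swDurMs = "numeric",
    thetaChannelGains = "numeric",
    frameRate = "numeric",
    arenaSide = "numeric",
    speedByState = "numeric",
    cameraClockOffset = "numeric",
    cameraClockDrift = "numeric",
    seed = "integer"
  )
)

setValidity("SessionConfig", function(object) {
  msg <- character()
  sched <- object@stateSchedule
  if (!all(c("state", "duration") %in% names(sched)) || nrow(sched) == 0) {
    msg <- c(msg, "stateSchedule needs columns state, duration and >= 1 row")
  } else {
    if (!all(sched$state %in% .STATES)) {
      msg <- c(msg, sprintf("states must be one of: %s",
                            paste(.STATES, collapse = ", ")))
    }
    if (any(sched$duration <= 0)) msg <- c(msg, "bout durations must be > 0")
  }
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (any(object@pacDepthByState < 0) || any(object@pacDepthByState > 1)) {
    msg <- c(msg, "pacDepthByState values must lie in [0, 1]")
  }
  if (any(object@swrRateByState < 0)) {
    msg <- c(msg, "swrRateByState values must be >= 0")
  }
  fmax <- max(object@thetaFreq, object@gammaFreq, object@rippleFreq)
  if (object@fs <= 2 * fmax) {
    msg <- c(msg, "fs must exceed twice the highest generated frequency")
  }
  if (object@pyramidalChannel < 1L ||
      object@pyramidalChannel > object@nChannels ||
      object@radiatumChannel < 1L ||
      object@radiatumChannel > object@nChannels) {
    msg <- c(msg, "pyramidal/radiatum channel indices out of range")
  }
  if (length(object@thetaChannelGains) != object@nChannels) {
    msg <- c(msg, "thetaChannelGains must have one entry per channel")
  }
  if (object@rippleDurMs <= 0) msg <- c(msg, "rippleDurMs must be > 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth for a synthetic session
#'
#' @slot swrEvents data.frame of injected events: \code{start_s},
#'   \code{end_s}, \code{state}, \code{kind} (\code{"joint"},
#'   \code{"ripple_only"} or \code{"sw_only"}).
#' @slot frameState character vector: true behavioral state of every
#'   tracking frame.
#' @slot pacDepthByState named numeric, the generating modulation depths.
#' @slot thetaAmpByState named numeric, the generating theta amplitudes.
#' @slot stateSchedule the generating bout schedule.
#' @export
setClass("GroundTruth",
  representation(
    swrEvents = "data.frame",
    frameState = "character",
    pacDepthByState = "numeric",
    thetaAmpByState = "numeric",
    stateSchedule = "data.frame"
  )
)

#' Power spectral density
#'
#' One-sided Welch power spectral density, density-scaled so that the
#' rectangle-rule integral over frequency equals the signal's mean power
#' (Parseval).
#'
#' @slot freq frequency grid, Hz.
#' @slot density power spectral density, microvolts^2 / Hz.
#' @slot fs sampling rate of the analyzed signal, Hz.
#' @slot nSegments number of Welch segments averaged.
#' @slot segPower mean power (microvolts^2) of the detrended analysis
#'   segments; the reference quantity for Parseval checks (slow drift
#'   below the window resolution is removed by the per-segment detrend and
#'   cannot appear in the spectrum).
#' @export
setClass("PowerSpectrum",
  representation(
    freq = "numeric",
    density = "numeric",
    fs = "numeric",
    nSegments = "integer",
    segPower = "numeric"
  ),
  prototype(segPower = NA_real_)
)

setValidity("PowerSpectrum", function(object) {
  if (length(object@freq) != length(object@density)) {
    "freq and density must have equal length"
  } else if (any(object@density < 0)) {
    "density must be non-negative"
  } else TRUE
})

#' Phase-amplitude comodulogram
#'
#' Modulation index over a grid of 1-Hz phase-frequency and
#' amplitude-frequency bins, averaged across behavioral epochs.
#'
#' @slot mi matrix of modulation indices, phase bins x amplitude bins.
#' @slot phaseFreqs,ampFreqs bin center frequencies, Hz.
#' @slot nEpochs number of epochs averaged.
#' @export
setClass("Comodulogram",
  representation(
    mi = "matrix",
    phaseFreqs = "numeric",
    ampFreqs = "numeric",
    nEpochs = "integer"
  )
)

setValidity("Comodulogram", function(object) {
  msg <- character()
  if (nrow(object@mi) != length(object@phaseFreqs) ||
      ncol(object@mi) != length(object@ampFreqs)) {
    msg <- c(msg, "mi matrix shape must be phaseFreqs x ampFreqs")
  }
  if (any(object@mi < 0, na.rm = TRUE)) msg <- c(msg, "mi must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Time-resolved PAC series
#'
#' Modulation index per consecutive 1-s window for one phase/amplitude band
#' pair; the subject-level summary is the arithmetic mean over windows.
#'
#' @slot mi modulation index per window.
#' @slot phaseBand,ampBand frequency bands, Hz (length-2).
#' @slot epochLen window length, seconds.
#' @export
setClass("TPacSeries",
  representation(
    mi = "numeric",
    phaseBand = "numeric",
    ampBand = "numeric",
    epochLen = "numeric"
  )
)

#' Ripple power signal
#'
#' The 120-250 Hz band-passed pyramidal-layer signal resampled to 1200 Hz,
#' z-scored per behavioral segment, rectified, and smoothed with an 8-ms
#' rectangular window. Samples outside analyzed segments are NA.
#'
#' @slot power smoothed rectified z-scored signal (z-units), NA outside
#'   segments.
#' @slot filtered band-passed signal at the working rate (microvolts).
#' @slot fs working sampling rate, Hz (1200).
#' @slot segments data.frame of analyzed segments: \code{start_sample},
#'   \code{end_sample} (0-based half-open at \code{fs}), \code{state},
#'   \code{degenerate} (constant input flag).
#' @export
setClass("RipplePower",
  representation(
    power = "numeric",
    filtered = "numeric",
    fs = "numeric",
    segments = "data.frame"
  )
)
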