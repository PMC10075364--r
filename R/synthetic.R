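# Synthetic CA1 session generator. Every downstream stage of the pipeline
# is validated against the ground truth these functions emit: state labels
# per tracking frame, injected SWR intervals, and the generating coupling
# depths and band amplitudes.

#' 1/f^alpha Gaussian background noise
#'
#' Generates a zero-mean Gaussian trace whose power spectrum follows
#' 1/f^alpha, by spectral shaping of white noise (amplitude scaled by
#' f^(-alpha/2), DC removed). alpha = 0 gives white noise; alpha = 1 the
#' conventional LFP background approximation.
#'
#' @param durationS duration, seconds.
#' @param fs sampling rate, Hz.
#' @param exponent spectral slope alpha (>= 0).
#' @param amp target standard deviation, microvolts.
#' @param seed optional integer seed; fixed seed gives an identical trace.
#' @return numeric trace of \code{round(durationS * fs)} samples.
#' @export
simBackgroundNoise <- function(durationS, fs, exponent = 1, amp = 1,
                               seed = NULL) {
  if (durationS <= 0 || fs <= 0) {
    stop("durationS and fs must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(durationS * fs)
  w <- stats::rnorm(n)
  if (exponent != 0) {
    W <- stats::fft(w)
    k <- 0:(n - 1)
    f <- pmin(k, n - k) * fs / n  # two-sided frequency magnitude
    g <- numeric(n)
    g[f > 0] <- f[f > 0]^(-exponent / 2)
    w <- Re(stats::fft(W * g, inverse = TRUE)) / n
  }
  w <- w - mean(w)
  s <- stats::sd(w)
  if (s > 0) w <- w * (amp / s)
  w
}

#' Phase-amplitude-coupled two-rhythm signal
#'
#' A slow rhythm plus a fast rhythm whose envelope is modulated by the slow
#' rhythm's phase:
#' \deqn{x(t) = a_p \cos(2\pi f_p t) + A(t) \cos(2\pi f_a t),}
#' \deqn{A(t) = a_g [1 - d + d (1 + \cos(2\pi f_p t)) / 2],}
#' so the fast envelope is maximal at phase 0 of the slow rhythm and, at
#' depth \eqn{d = 1}, reaches exactly 0 at the trough.
#'
#' @param fPhase,fAmp slow and fast frequencies, Hz (\code{fAmp > fPhase}).
#' @param pacDepth modulation depth d in [0, 1].
#' @param ampPhase,ampGamma slow-rhythm amplitude and fast-rhythm base
#'   amplitude, microvolts.
#' @param durationS,fs duration (s) and sampling rate (Hz).
#' @param noiseSd standard deviation of additive white noise (default 0).
#' @param seed optional seed for the noise.
#' @return list with \code{trace}, the true fast-rhythm \code{envelope}
#'   A(t), and the time axis \code{t}.
#' @export
simPacSignal <- function(fPhase, fAmp, pacDepth, ampPhase = 1, ampGamma = 1,
                         durationS = 10, fs = 1000, noiseSd = 0,
                         seed = NULL) {
  if (pacDepth < 0 || pacDepth > 1) stop("pacDepth must lie in [0, 1]")
  if (fAmp <= fPhase) stop("fAmp must exceed fPhase")
  if (!is.null(seed)) set.seed(seed)
  n <- round(durationS * fs)
  t <- (0:(n - 1)) / fs
  slowPhase <- 2 * pi * fPhase * t
  env <- ampGamma * (1 - pacDepth + pacDepth * (1 + cos(slowPhase)) / 2)
  trace <- ampPhase * cos(slowPhase) + env * cos(2 * pi * fAmp * t)
  if (noiseSd > 0) trace <- trace + stats::rnorm(n, sd = noiseSd)
  list(trace = trace, envelope = env, t = t)
}

# bout boundaries (start/end seconds) from a schedule data.frame
.scheduleBouts <- function(stateSchedule) {
  ends <- cumsum(stateSchedule$duration)
  data.frame(state = stateSchedule$state,
             start = c(0, ends[-length(ends)]),
             end = ends, stringsAsFactors = FALSE)
}

# Tapered-cosine (Tukey) ripple burst waveform: flat core with cosine
# ramps, so the injected nominal duration matches the span a threshold
# detector sees (a fully Hann-shaped envelope would keep only ~half the
# nominal duration above an edge threshold)
.rippleWaveform <- function(freqHz, durMs, amp, fs, taper = 0.25) {
  n <- max(4L, round(durMs / 1000 * fs))
  t <- (0:(n - 1)) / fs
  frac <- (0:(n - 1)) / (n - 1)
  env <- rep(1, n)
  ramp <- frac < taper / 2
  env[ramp] <- 0.5 * (1 - cos(2 * pi * frac[ramp] / taper))
  ramp <- frac > 1 - taper / 2
  env[ramp] <- 0.5 * (1 - cos(2 * pi * (1 - frac[ramp]) / taper))
  amp * env * sin(2 * pi * freqHz * t)
}

# negative Gaussian sharp-wave deflection; sigma = width/6 so the visible
# deflection spans ~durMs
.sharpWaveWaveform <- function(durMs, amp, fs) {
  n <- max(4L, round(durMs / 1000 * fs * 2))  # 2x width of padding
  t <- (0:(n - 1)) / fs
  t0 <- (n - 1) / (2 * fs)
  sigma <- durMs / 1000 / 6
  -amp * exp(-(t - t0)^2 / (2 * sigma^2))
}

# draw nEvents non-overlapping event center times within [lo, hi],
# resampling on collision (margin seconds between centers)
.drawEventTimes <- function(nEvents, lo, hi, margin, existing = numeric()) {
  times <- numeric(0)
  tries <- 0
  while (length(times) < nEvents && tries < 10000 * max(1, nEvents)) {
    cand <- stats::runif(1, lo, hi)
    if (!length(c(times, existing)) ||
        min(abs(c(times, existing) - cand)) > margin) {
      times <- c(times, cand)
    }
    tries <- tries + 1
  }
  if (length(times) < nEvents) {
    stop("could not place non-overlapping events; lower the rate")
  }
  sort(times)
}

#' Injected sharp wave-ripple event train
#'
#' Draws SWR events as a Poisson process per behavioral state (at that
#' state's rate) and injects, for each event, a tapered-cosine-windowed
#' sinusoidal ripple burst on the pyramidal-layer trace co-centered with a
#' negative sharp-wave deflection on the stratum radiatum trace. Optional distractor
#' events carry only one of the two components, for exercising the
#' co-occurrence filter. Events never overlap (start times are resampled on
#' collision).
#'
#' @param stateSchedule data.frame of \code{state}, \code{duration} (s).
#' @param rateByState named numeric, events/s per state (states absent from
#'   the map get rate 0).
#' @param rippleFreq,rippleDurMs,rippleAmp ripple burst parameters.
#' @param swAmp,swDurMs sharp-wave amplitude (microvolts) and width (ms).
#' @param fs sampling rate, Hz.
#' @param seed optional seed.
#' @param nEventsByState named integer; when given, exact per-state event
#'   counts override the Poisson draw.
#' @param nRippleOnly,nSwOnly numbers of distractor events carrying only a
#'   ripple or only a sharp wave, placed uniformly over the session.
#' @return list with \code{pyr} and \code{rad} additive traces and
#'   \code{events}: data.frame of \code{start_s}, \code{end_s},
#'   \code{state}, \code{kind} (joint / ripple_only / sw_only).
#' @export
simSwrTrain <- function(stateSchedule, rateByState, rippleFreq = 180,
                        rippleDurMs = 60, rippleAmp = 40, swAmp = 80,
                        swDurMs = 80, fs = 2500, seed = NULL,
                        nEventsByState = NULL, nRippleOnly = 0, nSwOnly = 0) {
  if (is.null(stateSchedule) || nrow(stateSchedule) == 0) {
    stop("stateSchedule must contain at least one bout")
  }
  if (any(rateByState < 0)) stop("event rates must be >= 0")
  if (rippleDurMs <= 0) stop("rippleDurMs must be positive")
  if (!is.null(seed)) set.seed(seed)
  bouts <- .scheduleBouts(stateSchedule)
  total <- max(bouts$end)
  n <- round(total * fs)
  pyr <- numeric(n)
  rad <- numeric(n)
  margin <- (max(rippleDurMs, swDurMs * 2) / 1000) * 1.5
  halfDur <- rippleDurMs / 2000

  centers <- numeric(0)
  states <- character(0)
  kinds <- character(0)
  for (i in seq_len(nrow(bouts))) {
    st <- bouts$state[i]
    if (!is.null(nEventsByState) && st %in% names(nEventsByState)) {
      # exact count split across this state's bouts proportionally to length
      stBouts <- bouts[bouts$state == st, ]
      frac <- (bouts$end[i] - bouts$start[i]) / sum(stBouts$end - stBouts$start)
      k <- round(nEventsByState[[st]] * frac)
    } else {
      rate <- if (st %in% names(rateByState)) rateByState[[st]] else 0
      k <- stats::rpois(1, rate * (bouts$end[i] - bouts$start[i]))
    }
    if (k == 0) next
    tms <- .drawEventTimes(k, bouts$start[i] + margin, bouts$end[i] - margin,
                           margin, existing = centers)
    centers <- c(centers, tms)
    states <- c(states, rep(st, k))
    kinds <- c(kinds, rep("joint", k))
  }
  for (spec in list(c("ripple_only", nRippleOnly), c("sw_only", nSwOnly))) {
    k <- as.integer(spec[2])
    if (k > 0) {
      tms <- .drawEventTimes(k, margin, total - margin, margin,
                             existing = centers)
      centers <- c(centers, tms)
      states <- c(states, vapply(tms, function(tt) {
        bouts$state[which(tt >= bouts$start & tt < bouts$end)[1]]
      }, character(1)))
      kinds <- c(kinds, rep(spec[1], k))
    }
  }

  ripWave <- .rippleWaveform(rippleFreq, rippleDurMs, rippleAmp, fs)
  swWave <- .sharpWaveWaveform(swDurMs, swAmp, fs)
  for (j in seq_along(centers)) {
    c0 <- round(centers[j] * fs)
    if (kinds[j] != "sw_only") {
      idx <- c0 - floor(length(ripWave) / 2) + seq_along(ripWave)
      ok <- idx >= 1 & idx <= n
      pyr[idx[ok]] <- pyr[idx[ok]] + ripWave[ok]
    }
    if (kinds[j] != "ripple_only") {
      idx <- c0 - floor(length(swWave) / 2) + seq_along(swWave)
      ok <- idx >= 1 & idx <= n
      rad[idx[ok]] <- rad[idx[ok]] + swWave[ok]
    }
  }
  ord <- order(centers)
  events <- data.frame(
    start_s = centers[ord] - halfDur,
    end_s = centers[ord] + halfDur,
    state = states[ord],
    kind = kinds[ord],
    stringsAsFactors = FALSE
  )
  list(pyr = pyr, rad = rad, events = events)
}

#' Scheduled open-field tracking trace
#'
#' Generates a smooth random-turning path whose frame-to-frame speed is
#' constant within each scheduled bout: above the exploration threshold in
#' exploration, strictly between zero and the threshold in grooming, and
#' exactly zero in wake immobility. The path reflects off the arena walls.
#'
#' @param stateSchedule data.frame of \code{state}, \code{duration} (s).
#' @param frameRate frames per second (default 30).
#' @param arenaSide arena side length, m.
#' @param speedByState named numeric, m/s per state.
#' @param seed optional seed.
#' @param ttl TTL pulse times to stamp on the trace (camera clock), seconds.
#' @return list with \code{tracking} (a [TrackingTrace-class]) and
#'   \code{labels}: the true state of every frame.
#' @export
simTracking <- function(stateSchedule, frameRate = 30, arenaSide = 1,
                        speedByState = c(exploration = 0.2, grooming = 0.03,
                                         wake_immobility = 0),
                        seed = NULL, ttl = numeric()) {
  if (arenaSide <= 0) stop("arenaSide must be positive")
  if (frameRate <= 0) stop("frameRate must be positive")
  if (!is.null(seed)) set.seed(seed)
  bouts <- .scheduleBouts(stateSchedule)
  total <- max(bouts$end)
  nFrames <- round(total * frameRate)
  t <- (0:(nFrames - 1)) / frameRate
  labels <- character(nFrames)
  for (i in seq_len(nrow(bouts))) {
    labels[t >= bouts$start[i] - 1e-9 & t < bouts$end[i] - 1e-9] <-
      bouts$state[i]
  }
  labels[labels == ""] <- bouts$state[nrow(bouts)]

  x <- numeric(nFrames)
  y <- numeric(nFrames)
  x[1] <- arenaSide / 2
  y[1] <- arenaSide / 2
  heading <- stats::runif(1, 0, 2 * pi)
  for (i in seq_len(nFrames)[-1]) {
    sp <- speedByState[[labels[i]]]
    step <- sp / frameRate
    if (step == 0) {
      x[i] <- x[i - 1]
      y[i] <- y[i - 1]
      next
    }
    heading <- heading + stats::rnorm(1, sd = 0.4)
    for (tries in 1:50) {
      nx <- x[i - 1] + step * cos(heading)
      ny <- y[i - 1] + step * sin(heading)
      if (nx >= 0 && nx <= arenaSide && ny >= 0 && ny <= arenaSide) break
      heading <- stats::runif(1, 0, 2 * pi)  # bounce off the wall
    }
    # clamp pathological corner cases while preserving the step length
    x[i] <- min(max(nx, 0), arenaSide)
    y[i] <- min(max(ny, 0), arenaSide)
  }
  trk <- TrackingTrace(t = t, x = x, y = y, frameRate = frameRate,
                       arenaSide = arenaSide, ttl = ttl)
  list(tracking = trk, labels = labels)
}

#' Default synthetic session configuration
#'
#' Constructs a [SessionConfig-class] with defaults emulating a 16-channel
#' laminar CA1 recording: 1/f background, state-gated theta, theta-phase
#' modulated gamma concentrated on the channels flanking the pyramidal
#' layer, and SWR events concentrated in wake immobility. Any field can be
#' overridden by name.
#'
#' @param ... named overrides of any slot (see [SessionConfig-class]).
#' @return a validated [SessionConfig-class].
#' @export
sessionConfig <- function(...) {
  defaults <- list(
    stateSchedule = data.frame(
      state = c("exploration", "grooming", "wake_immobility"),
      duration = c(120, 20, 120), stringsAsFactors = FALSE),
    fs = 2500,
    nChannels = 16L,
    pyramidalChannel = 4L,
    radiatumChannel = 9L,
    noiseExponent = 1,
    noiseAmp = 20,
    thetaFreq = 8,
    thetaAmpByState = c(exploration = 50, grooming = 30,
                        wake_immobility = 15),
    gammaFreq = 70,
    gammaAmp = 15,
    pacDepthByState = c(exploration = 0.8, grooming = 0.4,
                        wake_immobility = 0.3),
    swrRateByState = c(exploration = 0.05, grooming = 0,
                       wake_immobility = 0.3),
    rippleFreq = 180,
    rippleDurMs = 60,
    rippleAmp = 40,
    swAmp = 80,
    swDurMs = 80,
    thetaChannelGains = numeric(0),
    frameRate = 30,
    arenaSide = 1,
    speedByState = c(exploration = 0.2, grooming = 0.03,
                     wake_immobility = 0),
    cameraClockOffset = 0,
    cameraClockDrift = 0,
    seed = 1L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop("unknown SessionConfig field(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(override)] <- override
  if (!length(defaults$thetaChannelGains)) {
    g <- rep(0.25, defaults$nChannels)
    pc <- defaults$pyramidalChannel
    g[intersect(c(pc - 1L, pc, pc + 1L), seq_len(defaults$nChannels))] <- 1
    defaults$thetaChannelGains <- g
  }
  defaults$nChannels <- as.integer(defaults$nChannels)
  defaults$pyramidalChannel <- as.integer(defaults$pyramidalChannel)
  defaults$radiatumChannel <- as.integer(defaults$radiatumChannel)
  defaults$seed <- as.integer(defaults$seed)
  do.call(new, c(list("SessionConfig"), defaults))
}

#' Generate a complete synthetic session
#'
#' Builds the multichannel LFP (background + state-gated theta + PAC gamma +
#' SWR train), a tracking trace following the same bout schedule, and the
#' ground truth for every downstream stage. TTL pulses are emitted at the
#' session start and end on both clocks; the camera clock may carry a
#' configured offset and drift. Fully reproducible from the config seed.
#'
#' @param config a [SessionConfig-class], e.g. from [sessionConfig()].
#' @return list with \code{lfp} ([LfpRecording-class]), \code{tracking}
#'   ([TrackingTrace-class]) and \code{truth} ([GroundTruth-class]).
#' @export
simSession <- function(config) {
  stopifnot(is(config, "SessionConfig"))
  validObject(config)
  set.seed(config@seed)
  bouts <- .scheduleBouts(config@stateSchedule)
  total <- max(bouts$end)
  fs <- config@fs
  n <- round(total * fs)
  t <- (0:(n - 1)) / fs

  # per-sample state-driven amplitude/depth envelopes
  stateAt <- character(n)
  for (i in seq_len(nrow(bouts))) {
    stateAt[t >= bouts$start[i] - 1e-12 & t < bouts$end[i] - 1e-12] <-
      bouts$state[i]
  }
  stateAt[stateAt == ""] <- bouts$state[nrow(bouts)]
  thetaAmp <- unname(config@thetaAmpByState[stateAt])
  pacDepth <- unname(config@pacDepthByState[stateAt])

  slowPhase <- 2 * pi * config@thetaFreq * t
  theta <- thetaAmp * cos(slowPhase)
  gammaEnv <- config@gammaAmp *
    (1 - pacDepth + pacDepth * (1 + cos(slowPhase)) / 2)
  gamma <- gammaEnv * cos(2 * pi * config@gammaFreq * t)

  swr <- simSwrTrain(
    config@stateSchedule, config@swrRateByState,
    rippleFreq = config@rippleFreq, rippleDurMs = config@rippleDurMs,
    rippleAmp = config@rippleAmp, swAmp = config@swAmp,
    swDurMs = config@swDurMs, fs = fs)

  data <- matrix(0, nrow = config@nChannels, ncol = n)
  for (ch in seq_len(config@nChannels)) {
    bg <- simBackgroundNoise(total, fs, config@noiseExponent,
                             config@noiseAmp)
    data[ch, ] <- bg + config@thetaChannelGains[ch] * (theta + gamma)
  }
  data[config@pyramidalChannel, ] <- data[config@pyramidalChannel, ] + swr$pyr
  data[config@radiatumChannel, ] <- data[config@radiatumChannel, ] + swr$rad

  labels <- rep("other", config@nChannels)
  labels[config@pyramidalChannel] <- "pyramidal"
  labels[config@radiatumChannel] <- "radiatum"
  ttlLfp <- c(0, (n - 1) / fs)
  lfp <- LfpRecording(data, fs, channelLabels = labels, ttl = ttlLfp)

  ttlCam <- config@cameraClockOffset + (1 + config@cameraClockDrift) * ttlLfp
  trkGen <- simTracking(config@stateSchedule, config@frameRate,
                        config@arenaSide, config@speedByState, ttl = ttlCam)
  trk <- trkGen$tracking
  # express frame times on the (possibly offset/drifting) camera clock
  camT <- config@cameraClockOffset +
    (1 + config@cameraClockDrift) * trk@t
  trk <- TrackingTrace(t = camT, x = trk@x, y = trk@y,
                       frameRate = config@frameRate,
                       arenaSide = config@arenaSide, ttl = ttlCam)

  truth <- new("GroundTruth",
               swrEvents = swr$events,
               frameState = trkGen$labels,
               pacDepthByState = config@pacDepthByState,
               thetaAmpByState = config@thetaAmpByState,
               stateSchedule = config@stateSchedule)
  list(lfp = lfp, tracking = trk, truth = truth)
}

#' Two-channel SWR detector benchmark session
#'
#' A pyramidal + radiatum channel pair of 1/f background with a known set of
#' injected events: joint ripple+sharp-wave events, ripple-only distractors
#' and sharp-wave-only distractors. Ripple amplitude is set relative to the
#' measured 120-250 Hz in-band standard deviation of the background so the
#' in-band SNR is controlled.
#'
#' @param seed integer seed.
#' @param nJoint,nRippleOnly,nSwOnly event counts.
#' @param snr ripple amplitude as a multiple of the background's 120-250 Hz
#'   in-band SD (default 5).
#' @param durationS session length, s (single wake-immobility bout).
#' @param fs sampling rate, Hz.
#' @param rippleFreq,rippleDurMs ripple burst parameters.
#' @return list with \code{lfp} (2-channel [LfpRecording-class]: pyramidal,
#'   radiatum), \code{events} (ground-truth data.frame) and \code{epochs}
#'   (a single wake-immobility behavior epoch covering the session).
#' @export
simSwrBenchmarkSession <- function(seed = 1, nJoint = 100, nRippleOnly = 20,
                                   nSwOnly = 20, snr = 5, durationS = 360,
                                   fs = 2500, rippleFreq = 180,
                                   rippleDurMs = 60) {
  set.seed(seed)
  sched <- data.frame(state = "wake_immobility", duration = durationS,
                      stringsAsFactors = FALSE)
  bgPyr <- simBackgroundNoise(durationS, fs, exponent = 1, amp = 20)
  bgRad <- simBackgroundNoise(durationS, fs, exponent = 1, amp = 20)
  inBandSd <- stats::sd(bandpassFilter(bgPyr, fs, c(120, 250)))
  swBandSd <- stats::sd(cascadeBandpass(bgRad, fs, c(0.5, 40)))
  swr <- simSwrTrain(sched, c(wake_immobility = 0),
                     rippleFreq = rippleFreq, rippleDurMs = rippleDurMs,
                     rippleAmp = snr * inBandSd, swAmp = 8 * swBandSd,
                     swDurMs = 80, fs = fs,
                     nEventsByState = c(wake_immobility = nJoint),
                     nRippleOnly = nRippleOnly, nSwOnly = nSwOnly)
  data <- rbind(bgPyr + swr$pyr, bgRad + swr$rad)
  lfp <- LfpRecording(data, fs, channelLabels = c("pyramidal", "radiatum"),
                      ttl = 0)
  epochs <- data.frame(state = "wake_immobility", start_s = 0,
                       end_s = durationS,
                       start_sample = 0L, end_sample = round(durationS * fs),
                       stringsAsFactors = FALSE)
  list(lfp = lfp, events = swr$events, epochs = epochs)
}
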