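# Sharp wave-ripple detection: ripple-band power signal, dual-threshold
# event detection with 2-SD expansion, sharp-wave co-detection on the
# stratum radiatum channel, event features, and occurrence-rate ratios.

#' Ripple power signal
#'
#' Band-passes the pyramidal-layer signal between 120 and 250 Hz
#' (zero-phase Butterworth), resamples to the 1200 Hz working rate, then per
#' behavioral segment: z-scores, rectifies (absolute value) and smooths
#' with a centered 8-ms rectangular window. Segments shorter than 30 ms are
#' skipped; constant segments are flagged degenerate and left at zero.
#'
#' @param x raw single-channel signal (microvolts).
#' @param fsIn input sampling rate, Hz (>= 2400 so the 250 Hz edge is
#'   representable before resampling).
#' @param epochs optional epoch data.frame (0-based half-open sample
#'   indices at \code{fsIn}, column \code{state}); when NULL the whole
#'   signal is one segment.
#' @param band ripple band, Hz (default c(120, 250)).
#' @param targetFs working rate, Hz (default 1200).
#' @param smoothMs rectangular smoothing window, ms (default 8).
#' @return a [RipplePower-class].
#' @export
ripplePowerSignal <- function(x, fsIn, epochs = NULL, band = c(120, 250),
                              targetFs = 1200, smoothMs = 8) {
  if (fsIn < 2 * band[2]) {
    stop("input sampling rate too low for the ripple band")
  }
  filt <- bandpassFilter(x, fsIn, band)
  y <- resampleSignal(as.numeric(filt), fsIn, targetFs)
  n <- length(y)
  if (is.null(epochs)) {
    segs <- data.frame(start_sample = 0L, end_sample = n,
                       state = "all", stringsAsFactors = FALSE)
  } else {
    scale <- targetFs / fsIn
    segs <- data.frame(
      start_sample = pmin(n, as.integer(round(epochs$start_sample * scale))),
      end_sample = pmin(n, as.integer(round(epochs$end_sample * scale))),
      state = epochs$state, stringsAsFactors = FALSE)
  }
  minLen <- as.integer(round(0.03 * targetFs))
  segs$degenerate <- FALSE
  power <- rep(NA_real_, n)
  kSmooth <- round(smoothMs / 1000 * targetFs)
  keep <- logical(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    i0 <- segs$start_sample[i] + 1L
    i1 <- segs$end_sample[i]
    if (i1 - i0 + 1L < minLen) {
      message(sprintf("ripplePowerSignal: skipping %.0f ms segment at sample %d",
                      (i1 - i0 + 1L) / targetFs * 1000, i0 - 1L))
      next
    }
    keep[i] <- TRUE
    seg <- y[i0:i1]
    s <- stats::sd(seg)
    # degeneracy is judged on the raw input segment: a constant input
    # leaves only filter edge transients after band-passing
    j0 <- min(length(x), as.integer(round((i0 - 1L) * fsIn / targetFs)) + 1L)
    j1 <- min(length(x), as.integer(round(i1 * fsIn / targetFs)))
    if (s == 0 || stats::sd(x[j0:j1]) == 0) {
      segs$degenerate[i] <- TRUE
      power[i0:i1] <- 0
      next
    }
    z <- (seg - mean(seg)) / s
    power[i0:i1] <- movingAverage(abs(z), kSmooth)
  }
  new("RipplePower", power = power, filtered = y, fs = targetFs,
      segments = segs[keep, , drop = FALSE])
}

#' Detect candidate ripple events
#'
#' Scans each behavioral segment of the ripple power signal for maximal
#' runs containing at least one sample above the core threshold, expands
#' them bidirectionally to the last contiguous sample above the edge
#' threshold (runs whose expanded spans touch are merged), and discards
#' events shorter than the minimum duration or with a peak spectral
#' frequency below the cutoff. Thresholds sit at \code{mean + k * SD} of
#' the power signal: per segment, or pooled across a state's segments when
#' a segment is shorter than \code{poolBelowS}.
#'
#' @param rp a [RipplePower-class].
#' @param core core threshold, SD units (default 3).
#' @param edge expansion threshold, SD units (default 2).
#' @param minDurMs minimum event duration, ms (default 30).
#' @param minPsfHz minimum peak spectral frequency, Hz (default 140).
#' @param psfBand band searched for the peak frequency (default
#'   c(120, 250) Hz).
#' @param poolBelowS segments shorter than this (s) use the state-pooled SD
#'   (default 5).
#' @return data.frame of events: \code{start_s}, \code{end_s} (half-open,
#'   working-rate clock), \code{duration_ms}, \code{psf_hz},
#'   \code{band_power} (mean squared band-passed amplitude, microvolts^2),
#'   \code{peak_power} (power-signal maximum, SD units), \code{state}.
#' @export
detectRipples <- function(rp, core = 3, edge = 2, minDurMs = 30,
                          minPsfHz = 140, psfBand = c(120, 250),
                          poolBelowS = 5) {
  stopifnot(is(rp, "RipplePower"))
  fs <- rp@fs
  segs <- rp@segments
  pooledStats <- lapply(stats::setNames(nm = unique(segs$state)),
                        function(st) {
    idx <- unlist(lapply(which(segs$state == st), function(i) {
      (segs$start_sample[i] + 1L):segs$end_sample[i]
    }))
    c(m = mean(rp@power[idx], na.rm = TRUE),
      s = stats::sd(rp@power[idx], na.rm = TRUE))
  })
  events <- list()
  for (i in seq_len(nrow(segs))) {
    i0 <- segs$start_sample[i] + 1L
    i1 <- segs$end_sample[i]
    p <- rp@power[i0:i1]
    segLen <- (i1 - i0 + 1L) / fs
    ms <- if (segLen < poolBelowS) pooledStats[[segs$state[i]]] else
      c(m = mean(p), s = stats::sd(p))
    if (!is.finite(ms["s"]) || ms["s"] == 0) next
    above <- p > ms["m"] + edge * ms["s"]
    if (!any(above)) next
    r <- rle(above)
    runEnd <- cumsum(r$lengths)
    runStart <- c(1L, runEnd[-length(runEnd)] + 1L)
    for (j in which(r$values)) {
      a <- runStart[j]
      b <- runEnd[j]
      if (!any(p[a:b] > ms["m"] + core * ms["s"])) next
      events[[length(events) + 1L]] <- data.frame(
        startIdx = i0 + a - 1L, endIdx = i0 + b,  # half-open
        peak_power = (max(p[a:b]) - ms[["m"]]) / ms[["s"]],
        state = segs$state[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(events)) return(.emptyRippleTable())
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$startIdx), , drop = FALSE]
  # merge runs whose expanded spans touch or overlap
  merged <- ev[1, , drop = FALSE]
  for (j in seq_len(nrow(ev))[-1]) {
    last <- nrow(merged)
    if (ev$startIdx[j] <= merged$endIdx[last]) {
      merged$endIdx[last] <- max(merged$endIdx[last], ev$endIdx[j])
      merged$peak_power[last] <- max(merged$peak_power[last],
                                     ev$peak_power[j])
    } else {
      merged <- rbind(merged, ev[j, , drop = FALSE])
    }
  }
  ev <- merged
  ev$duration_ms <- (ev$endIdx - ev$startIdx) / fs * 1000
  ev <- ev[ev$duration_ms >= minDurMs, , drop = FALSE]
  if (!nrow(ev)) return(.emptyRippleTable())
  feats <- lapply(seq_len(nrow(ev)), function(j) {
    tr <- rp@filtered[ev$startIdx[j]:(ev$endIdx[j] - 1L)]
    psf <- periodogramPeak(tr, fs, psfBand)
    c(psf = as.numeric(psf), bp = mean(tr^2))
  })
  ev$psf_hz <- vapply(feats, `[[`, numeric(1), "psf")
  ev$band_power <- vapply(feats, `[[`, numeric(1), "bp")
  ev <- ev[ev$psf_hz >= minPsfHz, , drop = FALSE]
  if (!nrow(ev)) return(.emptyRippleTable())
  data.frame(start_s = (ev$startIdx - 1L) / fs, end_s = (ev$endIdx - 1L) / fs,
             duration_ms = ev$duration_ms, psf_hz = ev$psf_hz,
             band_power = ev$band_power, peak_power = ev$peak_power,
             state = ev$state, stringsAsFactors = FALSE, row.names = NULL)
}

.emptyRippleTable <- function() {
  data.frame(start_s = numeric(), end_s = numeric(),
             duration_ms = numeric(), psf_hz = numeric(),
             band_power = numeric(), peak_power = numeric(),
             state = character(), stringsAsFactors = FALSE)
}

#' Peak spectral frequency of an event trace
#'
#' Periodogram peak of a band-passed event snippet within the ripple band,
#' zero-padded to at least 1 Hz resolution.
#'
#' @param x band-passed event trace (>= 30 ms of samples).
#' @param fs sampling rate, Hz.
#' @param band search band, Hz (default c(120, 250)).
#' @return peak frequency, Hz.
#' @export
eventPeakFrequency <- function(x, fs, band = c(120, 250)) {
  if (length(x) < 0.03 * fs) stop("event shorter than 30 ms")
  as.numeric(periodogramPeak(x, fs, band))
}

#' Detect sharp waves on the stratum radiatum channel
#'
#' Band-passes the signal between 0.5 and 40 Hz (zero-phase), thresholds
#' the magnitude of the filtered signal at a multiple of its standard
#' deviation (polarity-agnostic, since electrode referencing can flip the
#' conventional negative deflection), and keeps events lasting between 20
#' and 400 ms.
#'
#' @param x raw radiatum-channel signal (microvolts).
#' @param fs sampling rate, Hz.
#' @param band sharp-wave band, Hz (default c(0.5, 40)).
#' @param thresh threshold, SD units (default 2.5).
#' @param durMs length-2 admissible duration range, ms (default
#'   c(20, 400)).
#' @return data.frame with \code{start_s}, \code{end_s},
#'   \code{duration_ms}, \code{peak_uV}.
#' @export
detectSharpWaves <- function(x, fs, band = c(0.5, 40), thresh = 2.5,
                             durMs = c(20, 400)) {
  filt <- as.numeric(cascadeBandpass(x, fs, band))
  s <- stats::sd(filt)
  if (s == 0) {
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      duration_ms = numeric(), peak_uV = numeric()))
  }
  above <- abs(filt) > thresh * s
  if (!any(above)) {
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      duration_ms = numeric(), peak_uV = numeric()))
  }
  r <- rle(above)
  runEnd <- cumsum(r$lengths)
  runStart <- c(1L, runEnd[-length(runEnd)] + 1L)
  keep <- which(r$values)
  out <- data.frame(
    start_s = (runStart[keep] - 1L) / fs,
    end_s = runEnd[keep] / fs,
    duration_ms = r$lengths[keep] / fs * 1000,
    peak_uV = vapply(keep, function(j) {
      max(abs(filt[runStart[j]:runEnd[j]]))
    }, numeric(1))
  )
  out <- out[out$duration_ms >= durMs[1] & out$duration_ms <= durMs[2], ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair ripples with co-occurring sharp waves
#'
#' A ripple is retained iff its interval has a nonempty intersection with
#' any sharp-wave interval (half-open interval overlap, no tolerance
#' window). Retained events carry \code{paired_sw = TRUE}.
#'
#' @param ripples data.frame from [detectRipples()].
#' @param sharpWaves data.frame from [detectSharpWaves()].
#' @return the retained subset of \code{ripples} with a \code{paired_sw}
#'   column.
#' @export
pairSwrEvents <- function(ripples, sharpWaves) {
  if (!nrow(ripples)) {
    ripples$paired_sw <- logical(0)
    return(ripples)
  }
  overlaps <- vapply(seq_len(nrow(ripples)), function(i) {
    any(sharpWaves$start_s < ripples$end_s[i] &
        ripples$start_s[i] < sharpWaves$end_s)
  }, logical(1))
  out <- ripples[overlaps, , drop = FALSE]
  out$paired_sw <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Slow-gamma features during an event
#'
#' Band power and periodogram peak frequency in the slow-gamma band over
#' the event window; windows shorter than 100 ms are extended symmetrically
#' to 100 ms (flagged) so the band is spectrally resolvable.
#'
#' @param x raw signal at rate \code{fs}.
#' @param fs sampling rate, Hz.
#' @param event list or one-row data.frame with \code{start_s},
#'   \code{end_s}.
#' @param band slow-gamma band, Hz (default c(30, 45); c(25, 55) is the
#'   broader variant sometimes used).
#' @return list with \code{power} (microvolts^2), \code{psf_hz} and
#'   \code{extended} (window-extension flag).
#' @export
slowGammaFeatures <- function(x, fs, event, band = c(30, 45)) {
  start <- event$start_s
  end <- event$end_s
  extended <- FALSE
  if (end - start < 0.1) {
    mid <- (start + end) / 2
    start <- mid - 0.05
    end <- mid + 0.05
    extended <- TRUE
  }
  i0 <- max(1L, as.integer(round(start * fs)) + 1L)
  i1 <- min(length(x), as.integer(round(end * fs)))
  seg <- x[i0:i1]
  psf <- periodogramPeak(seg, fs, band)
  list(power = attr(psf, "power"), psf_hz = as.numeric(psf),
       extended = extended)
}

#' SWR occurrence-rate ratio between states
#'
#' (events per second of exploration) / (events per second of wake
#' immobility). Dividing rates limits the bias from electrode placement
#' and impedance, which scale both rates together.
#'
#' @param events event data.frame with a \code{state} column.
#' @param epochs epoch data.frame with \code{state}, \code{start_s},
#'   \code{end_s} (durations define the per-state exposure).
#' @param num,den numerator and denominator states.
#' @return the ratio; \code{Inf} (with a warning) when the denominator
#'   state has events = 0, an error when it has zero total duration.
#' @export
swrOccurrenceRatio <- function(events, epochs, num = "exploration",
                               den = "wake_immobility") {
  durFor <- function(st) {
    sel <- epochs$state == st
    sum(epochs$end_s[sel] - epochs$start_s[sel])
  }
  dNum <- durFor(num)
  dDen <- durFor(den)
  if (dNum <= 0 || dDen <= 0) {
    stop("degenerate input: a state has zero total duration")
  }
  rNum <- sum(events$state == num) / dNum
  rDen <- sum(events$state == den) / dDen
  if (rDen == 0) {
    warning("no events in the denominator state; ratio is infinite")
    return(Inf)
  }
  rNum / rDen
}

#' Full SWR detection pass over a session
#'
#' Runs the ripple power signal, dual-threshold ripple detection,
#' sharp-wave detection, co-occurrence pairing and slow-gamma feature
#' extraction for one session.
#'
#' @param lfp an [LfpRecording-class].
#' @param epochs LFP-aligned epoch data.frame.
#' @param pyramidalChannel,radiatumChannel channel indices; default to the
#'   channels labeled \code{"pyramidal"} / \code{"radiatum"}.
#' @param core,edge,minDurMs,minPsfHz see [detectRipples()].
#' @param swThresh,swDurMs see [detectSharpWaves()].
#' @param slowGammaBand see [slowGammaFeatures()].
#' @return data.frame of retained SWR events with all features.
#' @export
detectSwr <- function(lfp, epochs, pyramidalChannel = NULL,
                      radiatumChannel = NULL, core = 3, edge = 2,
                      minDurMs = 30, minPsfHz = 140, swThresh = 2.5,
                      swDurMs = c(20, 400), slowGammaBand = c(30, 45)) {
  stopifnot(is(lfp, "LfpRecording"))
  if (is.null(pyramidalChannel)) {
    pyramidalChannel <- which(channelLabels(lfp) == "pyramidal")[1]
  }
  if (is.null(radiatumChannel)) {
    radiatumChannel <- which(channelLabels(lfp) == "radiatum")[1]
  }
  if (is.na(pyramidalChannel) || is.na(radiatumChannel)) {
    stop("pyramidal and radiatum channels must be identified")
  }
  fs <- samplingRate(lfp)
  rp <- ripplePowerSignal(lfpData(lfp)[pyramidalChannel, ], fs,
                          epochs = epochs)
  ripples <- detectRipples(rp, core = core, edge = edge,
                           minDurMs = minDurMs, minPsfHz = minPsfHz)
  sws <- detectSharpWaves(lfpData(lfp)[radiatumChannel, ], fs,
                          thresh = swThresh, durMs = swDurMs)
  ev <- pairSwrEvents(ripples, sws)
  if (nrow(ev)) {
    sg <- lapply(seq_len(nrow(ev)), function(i) {
      slowGammaFeatures(lfpData(lfp)[pyramidalChannel, ], fs,
                        ev[i, ], band = slowGammaBand)
    })
    ev$slow_gamma_power <- vapply(sg, `[[`, numeric(1), "power")
    ev$slow_gamma_psf_hz <- vapply(sg, `[[`, numeric(1), "psf_hz")
  } else {
    ev$slow_gamma_power <- numeric(0)
    ev$slow_gamma_psf_hz <- numeric(0)
  }
  ev
}
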