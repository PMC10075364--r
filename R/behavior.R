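# Behavioral-state segmentation from tracking speed, TTL alignment of
# epochs into LFP sample indices, and open-field trial metrics.
#
# Conventions: states are "exploration", "grooming", "wake_immobility";
# intervals are half-open [start, end); sample indices are 0-based.

#' Frame-to-frame speed from a tracking trace
#'
#' speed[i] = ||pos[i] - pos[i-1]|| * frameRate; the first frame copies the
#' second so every frame has a defined speed.
#'
#' @param tracking a [TrackingTrace-class].
#' @param smoothWindow moving-median window in frames (0 = off).
#' @return numeric vector of speeds, m/s, one per frame.
#' @export
trackingSpeed <- function(tracking, smoothWindow = 0) {
  stopifnot(is(tracking, "TrackingTrace"))
  n <- length(tracking@t)
  if (n < 2) stop("need at least two frames to compute speed")
  dx <- diff(tracking@x)
  dy <- diff(tracking@y)
  dt <- diff(tracking@t)
  sp <- c(NA_real_, sqrt(dx^2 + dy^2) / dt)
  sp[1] <- sp[2]
  if (smoothWindow > 1) {
    sp <- stats::runmed(sp, k = smoothWindow + (smoothWindow %% 2 == 0))
  }
  sp
}

#' Classify frames into behavioral states by speed
#'
#' Exploration is speed above the locomotion threshold, wake immobility is
#' speed at (numerical) zero, grooming is everything in between. A
#' zero-tolerance parameter defines "zero" because tracker jitter makes
#' exact zeros rare in real data.
#'
#' @param speed numeric vector of frame speeds, m/s (>= 0).
#' @param explorationMin locomotion threshold, m/s (default 0.05).
#' @param zeroTol immobility tolerance, m/s (default 1e-3).
#' @return character vector of state labels, one per frame.
#' @export
classifyFrames <- function(speed, explorationMin = 0.05, zeroTol = 1e-3) {
  if (any(speed < 0, na.rm = TRUE)) stop("speeds must be non-negative")
  out <- rep("grooming", length(speed))
  out[speed > explorationMin] <- "exploration"
  out[speed <= zeroTol] <- "wake_immobility"
  out
}

#' Collapse per-frame labels into behavioral epochs
#'
#' Maximal runs of identical labels become epochs (half-open [start, end) in
#' camera time). Epochs of dropped states and epochs shorter than the
#' minimum duration are removed; surviving epochs keep their original
#' boundaries (no merging across removed gaps).
#'
#' @param labels character vector, one state per frame.
#' @param t frame times, seconds (same length as \code{labels}).
#' @param minDur minimum epoch duration, s (default 1).
#' @param drop states removed outright (default \code{"grooming"}).
#' @return data.frame with columns \code{state}, \code{start_s},
#'   \code{end_s}.
#' @export
framesToEpochs <- function(labels, t, minDur = 1, drop = "grooming") {
  if (length(labels) != length(t)) {
    stop("labels and t must have equal length")
  }
  if (!length(labels)) {
    return(data.frame(state = character(), start_s = numeric(),
                      end_s = numeric(), stringsAsFactors = FALSE))
  }
  dt <- if (length(t) > 1) stats::median(diff(t)) else 0
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  ep <- data.frame(
    state = r$values,
    start_s = t[starts],
    # half-open: an epoch ends where the next frame begins
    end_s = c(t[starts[-1]], t[length(t)] + dt),
    stringsAsFactors = FALSE
  )
  ep <- ep[!(ep$state %in% drop), , drop = FALSE]
  ep <- ep[(ep$end_s - ep$start_s) >= minDur - 1e-9, , drop = FALSE]
  rownames(ep) <- NULL
  ep
}

# least-squares affine map camera time -> LFP time from matched TTL pulses
.ttlAffine <- function(camTtl, lfpTtl) {
  k <- min(length(camTtl), length(lfpTtl))
  if (k < 1) stop("alignment failure: no shared TTL pulses")
  if (k == 1) {
    c(offset = lfpTtl[1] - camTtl[1], slope = 1)
  } else {
    fit <- stats::lsfit(camTtl[1:k], lfpTtl[1:k])
    c(offset = unname(fit$coefficients[1]),
      slope = unname(fit$coefficients[2]))
  }
}

#' Align behavioral epochs to LFP sample indices
#'
#' Estimates an affine map from camera time to LFP time from matched TTL
#' pulses (a single shared pulse gives a pure offset; two or more also
#' estimate clock drift) and attaches half-open 0-based sample indices to
#' each epoch, clipped to the recording.
#'
#' @param epochs data.frame from [framesToEpochs()].
#' @param camTtl TTL times on the camera clock, s.
#' @param lfpTtl TTL times on the LFP clock, s.
#' @param fs LFP sampling rate, Hz.
#' @param nSamples number of samples in the recording (for clipping).
#' @return \code{epochs} with added columns \code{start_sample},
#'   \code{end_sample} (0-based, half-open) and the mapped \code{start_s},
#'   \code{end_s} re-expressed in LFP time; the affine coefficients are
#'   attached as attribute \code{clockMap}.
#' @export
alignEpochsToLfp <- function(epochs, camTtl, lfpTtl, fs, nSamples) {
  ab <- .ttlAffine(camTtl, lfpTtl)
  startL <- ab["offset"] + ab["slope"] * epochs$start_s
  endL <- ab["offset"] + ab["slope"] * epochs$end_s
  out <- epochs
  out$start_s <- unname(startL)
  out$end_s <- unname(endL)
  nSamples <- as.integer(nSamples)
  out$start_sample <- pmax(0L, pmin(nSamples, as.integer(round(startL * fs))))
  out$end_sample <- pmax(0L, pmin(nSamples, as.integer(round(endL * fs))))
  keep <- out$end_sample > out$start_sample
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clockMap") <- ab
  out
}

#' Segment a session into LFP-aligned behavioral epochs
#'
#' Convenience wrapper running speed computation, frame classification,
#' epoch extraction (grooming and sub-second epochs removed) and TTL
#' alignment in one call.
#'
#' @param tracking a [TrackingTrace-class].
#' @param lfp an [LfpRecording-class].
#' @param explorationMin,zeroTol see [classifyFrames()].
#' @param minDur,drop see [framesToEpochs()].
#' @param smoothWindow see [trackingSpeed()].
#' @return LFP-aligned epoch data.frame (see [alignEpochsToLfp()]).
#' @export
segmentSession <- function(tracking, lfp, explorationMin = 0.05,
                           zeroTol = 1e-3, minDur = 1, drop = "grooming",
                           smoothWindow = 0) {
  sp <- trackingSpeed(tracking, smoothWindow = smoothWindow)
  labels <- classifyFrames(sp, explorationMin, zeroTol)
  ep <- framesToEpochs(labels, tracking@t, minDur = minDur, drop = drop)
  alignEpochsToLfp(ep, ttlTimes(tracking), ttlTimes(lfp),
                   samplingRate(lfp), ncol(lfpData(lfp)))
}

#' Open-field trial metrics
#'
#' Total path length, time spent in / distance traveled in / entries into a
#' centered inner square, for the whole trial and per consecutive window
#' (default 5 min; a trailing partial window is kept and flagged).
#'
#' @param tracking a [TrackingTrace-class].
#' @param innerFraction side of the inner square as a fraction of the arena
#'   side (default 0.5).
#' @param windowS window length for the per-epoch breakdown, s (default
#'   300).
#' @return list with scalars \code{total_distance_m}, \code{inner_time_s},
#'   \code{inner_distance_m}, \code{inner_entries} and a data.frame
#'   \code{per_epoch} (one row per window, with \code{partial} flag).
#' @export
openFieldMetrics <- function(tracking, innerFraction = 0.5, windowS = 300) {
  stopifnot(is(tracking, "TrackingTrace"))
  if (innerFraction <= 0 || innerFraction >= 1) {
    stop("innerFraction must lie in (0, 1)")
  }
  side <- tracking@arenaSide
  lo <- side * (1 - innerFraction) / 2
  hi <- side * (1 + innerFraction) / 2
  n <- length(tracking@t)
  dt <- if (n > 1) stats::median(diff(tracking@t)) else 0
  inside <- tracking@x >= lo & tracking@x <= hi &
    tracking@y >= lo & tracking@y <= hi
  step <- c(0, sqrt(diff(tracking@x)^2 + diff(tracking@y)^2))

  metricsFor <- function(idx) {
    ins <- inside[idx]
    st <- step[idx]
    st[1] <- 0  # do not attribute a step crossing the window boundary
    entries <- sum(diff(ins) == 1)
    if (length(idx) && ins[1] && idx[1] == 1) entries <- entries + 1
    list(total_distance_m = sum(st),
         inner_time_s = sum(ins) * dt,
         inner_distance_m = sum(st[ins]),
         inner_entries = as.integer(entries))
  }

  whole <- metricsFor(seq_len(n))
  whole$total_distance_m <- sum(step)  # include every step for the trial
  whole$inner_distance_m <- sum(step[inside])

  t0 <- tracking@t[1]
  rel <- tracking@t - t0
  total <- rel[n] + dt
  nWin <- max(1L, ceiling(total / windowS - 1e-9))
  rows <- lapply(seq_len(nWin), function(w) {
    sel <- which(rel >= (w - 1) * windowS - 1e-9 & rel < w * windowS - 1e-9)
    m <- metricsFor(sel)
    data.frame(window = w,
               start_s = t0 + (w - 1) * windowS,
               end_s = t0 + min(w * windowS, total),
               total_distance_m = m$total_distance_m,
               inner_time_s = m$inner_time_s,
               inner_distance_m = m$inner_distance_m,
               inner_entries = m$inner_entries,
               partial = (w * windowS) > total + 1e-9)
  })
  c(whole, list(per_epoch = do.call(rbind, rows)))
}
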