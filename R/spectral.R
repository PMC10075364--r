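# Welch spectra per behavioral state, band powers normalized by total
# 0.5-250 Hz power, and top-3-channel subject summaries.

#' Canonical frequency bands
#'
#' The band table used throughout: delta 0.4-4, theta low 5-8, theta high
#' 8-12, slow gamma 30-45, fast gamma 60-120 and high-frequency
#' oscillations 120-250 Hz. Bands are half-open [lo, hi).
#'
#' @return data.frame with columns \code{name}, \code{f_lo}, \code{f_hi}.
#' @export
canonicalBands <- function() {
  data.frame(
    name = c("delta", "theta_low", "theta_high", "slow_gamma",
             "fast_gamma", "hfo"),
    f_lo = c(0.4, 5, 8, 30, 60, 120),
    f_hi = c(4, 8, 12, 45, 120, 250),
    stringsAsFactors = FALSE
  )
}

#' Welch power spectral density
#'
#' One-sided Welch PSD with Hann taper, per-segment constant detrend and
#' density scaling, so the rectangle-rule integral over frequency matches
#' the signal's variance (Parseval).
#'
#' @param x numeric signal (microvolts).
#' @param fs sampling rate, Hz.
#' @param windowS segment length, s (default 1).
#' @param overlap fractional segment overlap (default 0.5).
#' @return a [PowerSpectrum-class].
#' @export
welchPsd <- function(x, fs, windowS = 1, overlap = 0.5) {
  nseg <- round(windowS * fs)
  if (length(x) < nseg) stop("signal shorter than one Welch window")
  acc <- .welchAccumulate(x, fs, nseg, overlap)
  new("PowerSpectrum", freq = acc$freq, density = acc$sum / acc$count,
      fs = fs, nSegments = as.integer(acc$count),
      segPower = acc$power / acc$count)
}

# accumulate Welch segment periodograms (sum, count, detrended segment
# power) over one signal
.welchAccumulate <- function(x, fs, nseg, overlap) {
  w <- .hann(nseg)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  total <- NULL
  power <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- seg - mean(seg)  # constant detrend
    power <- power + mean(seg^2)
    pg <- .segmentPeriodogram(seg, fs, w)
    if (is.null(total)) total <- numeric(length(pg$density))
    total <- total + pg$density
  }
  list(freq = (0:(length(total) - 1)) * fs / nseg, sum = total,
       count = length(starts), power = power)
}

#' Welch PSD pooled across behavioral epochs
#'
#' Computes one PSD per behavioral state by pooling Welch segments from
#' every epoch of that state with equal segment weight. Epochs shorter than
#' one window contribute nothing (the behavior filter removes sub-second
#' epochs upstream).
#'
#' @param x single-channel signal (full recording).
#' @param fs sampling rate, Hz.
#' @param epochs LFP-aligned epoch data.frame (0-based half-open
#'   \code{start_sample}, \code{end_sample}, \code{state}).
#' @param windowS,overlap Welch parameters (1 s, 50\%).
#' @return named list of [PowerSpectrum-class], one per state present.
#' @export
epochPsd <- function(x, fs, epochs, windowS = 1, overlap = 0.5) {
  nseg <- round(windowS * fs)
  out <- list()
  for (st in unique(epochs$state)) {
    eps <- epochs[epochs$state == st, , drop = FALSE]
    total <- NULL
    count <- 0L
    power <- 0
    for (i in seq_len(nrow(eps))) {
      i0 <- eps$start_sample[i] + 1L
      i1 <- eps$end_sample[i]
      if (i1 - i0 + 1L < nseg) next
      acc <- .welchAccumulate(x[i0:i1], fs, nseg, overlap)
      if (is.null(total)) total <- numeric(length(acc$sum))
      total <- total + acc$sum
      count <- count + acc$count
      power <- power + acc$power
    }
    if (count == 0L) next
    out[[st]] <- new("PowerSpectrum",
                     freq = (0:(length(total) - 1)) * fs / nseg,
                     density = total / count, fs = fs,
                     nSegments = as.integer(count),
                     segPower = power / count)
  }
  out
}

#' Band power from a PSD
#'
#' Rectangle-rule integral of the density over the half-open band
#' [f_lo, f_hi).
#'
#' @param psd a [PowerSpectrum-class].
#' @param band length-2 numeric band edges, Hz.
#' @return power in microvolts^2.
#' @export
bandPower <- function(psd, band) {
  stopifnot(is(psd, "PowerSpectrum"), length(band) == 2, band[1] < band[2])
  df <- psd@freq[2] - psd@freq[1]
  if (band[2] > max(psd@freq) + df) {
    stop("band exceeds the PSD frequency range")
  }
  sel <- psd@freq >= band[1] & psd@freq < band[2]
  sum(psd@density[sel]) * df
}

#' Normalized band power
#'
#' Fraction of the total power (default 0.5-250 Hz) carried by a band;
#' invariant to amplitude rescaling of the signal.
#'
#' @param psd a [PowerSpectrum-class].
#' @param band length-2 band edges, Hz. The band may start below the total
#'   range's floor (the conventional band table opens delta at 0.4 Hz while
#'   total power is summed from 0.5 Hz); on a typical 1 Hz analysis grid
#'   the two resolve to the same bins.
#' @param total length-2 total-power range, Hz (default c(0.5, 250)).
#' @return unitless fraction.
#' @export
normalizedBandPower <- function(psd, band, total = c(0.5, 250)) {
  stopifnot(length(band) == 2, band[1] < band[2])
  tot <- bandPower(psd, total)
  if (tot <= 0) stop("degenerate input: zero total power")
  bandPower(psd, band) / tot
}

#' Long-format band-power table for a session
#'
#' Absolute and total-power-normalized band power per (channel, state,
#' band), from state-pooled Welch spectra. Bands whose lower edge falls
#' below the PSD resolution are integrated from the first positive
#' frequency bin.
#'
#' @param lfp an [LfpRecording-class].
#' @param epochs LFP-aligned epoch data.frame.
#' @param bands band table (default [canonicalBands()]).
#' @param channels channel indices to analyze (default all).
#' @param total total-power range, Hz.
#' @param windowS,overlap Welch parameters.
#' @return data.frame with columns \code{channel}, \code{state},
#'   \code{band}, \code{power}, \code{norm_power}.
#' @export
bandPowerTable <- function(lfp, epochs, bands = canonicalBands(),
                           channels = seq_len(nChannels(lfp)),
                           total = c(0.5, 250), windowS = 1, overlap = 0.5) {
  stopifnot(is(lfp, "LfpRecording"))
  rows <- list()
  for (ch in channels) {
    psds <- epochPsd(lfpData(lfp)[ch, ], samplingRate(lfp), epochs,
                     windowS, overlap)
    for (st in names(psds)) {
      psd <- psds[[st]]
      tot <- bandPower(psd, total)
      for (b in seq_len(nrow(bands))) {
        p <- bandPower(psd, c(bands$f_lo[b], bands$f_hi[b]))
        rows[[length(rows) + 1L]] <- data.frame(
          channel = ch, state = st, band = bands$name[b],
          power = p, norm_power = if (tot > 0) p / tot else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Top-k channel summary of band power
#'
#' For one band, ranks channels by their normalized power (pooled across
#' states by the mean, keeping the channel set fixed across the state
#' comparison) and averages the top \code{k} channels, returning one value
#' per state.
#'
#' @param powerTable data.frame from [bandPowerTable()].
#' @param band band name to summarize.
#' @param k number of top channels to average (default 3).
#' @return data.frame with columns \code{state}, \code{value}; the selected
#'   channel indices are attached as attribute \code{channels}.
#' @export
topChannelSummary <- function(powerTable, band, k = 3) {
  tb <- powerTable[powerTable$band == band, , drop = FALSE]
  if (!nrow(tb)) stop("band not present in the power table")
  perCh <- tapply(tb$norm_power, tb$channel, mean)
  if (length(perCh) < k) stop("fewer channels than k")
  top <- as.integer(names(sort(perCh, decreasing = TRUE)[seq_len(k)]))
  sel <- tb[tb$channel %in% top, , drop = FALSE]
  out <- aggregate(norm_power ~ state, data = sel, FUN = mean)
  names(out) <- c("state", "value")
  attr(out, "channels") <- top
  out
}
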