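# Shared signal-processing primitives. All filters are zero-phase
# (forward-backward); all spectra are one-sided density-scaled.

#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass filters a signal with a Butterworth filter applied forward and
#' backward (\code{signal::filtfilt}), giving zero group delay and doubling
#' the effective order. The design corners are pre-warped so that the -3 dB
#' points of the combined (two-pass) response land on the requested band
#' edges.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param band length-2 numeric, band edges in Hz.
#' @param order Butterworth prototype order per pass (default 4; the
#'   band-pass transfer is order \code{2*order} per pass, twice that after
#'   the backward pass).
#' @param prewarp logical; correct the design corners so the two-pass -3 dB
#'   corners match \code{band} (default TRUE).
#' @return filtered signal, with attribute \code{edgeSamples}: the number of
#'   samples at each end dominated by filter transients (callers should
#'   discard them before phase/amplitude statistics).
#' @export
bandpassFilter <- function(x, fs, band, order = 4, prewarp = TRUE) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  if (band[2] >= fs / 2) {
    stop("band must lie strictly below the Nyquist frequency")
  }
  # a band far below the sampling rate makes the transfer-function form
  # ill-conditioned (clustered poles near z = 1); filter at a decimated
  # working rate and resample back — every step is zero-phase
  if (band[2] < fs / 100) {
    n <- length(x)
    fsWork <- 20 * band[2]
    xw <- resampleSignal(as.numeric(x), fs, fsWork)
    yw <- bandpassFilter(xw, fsWork, band, order = order,
                         prewarp = prewarp)
    y <- resampleSignal(as.numeric(yw), fsWork, fs)
    if (length(y) > n) y <- y[seq_len(n)]
    if (length(y) < n) y <- c(y, rep(y[length(y)], n - length(y)))
    attr(y, "edgeSamples") <- .filterEdgeSamples(fs, band)
    return(y)
  }
  edges <- band
  if (prewarp) edges <- .prewarpEdges(band, fs, order)
  flt <- signal::butter(order, edges / (fs / 2), type = "pass")
  y <- signal::filtfilt(flt, x)
  attr(y, "edgeSamples") <- .filterEdgeSamples(fs, band)
  y
}

# squared magnitude (= two-pass forward-backward gain) of a digital filter
.twoPassGain <- function(flt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  kb <- seq_along(flt$b) - 1
  ka <- seq_along(flt$a) - 1
  vapply(z, function(zz) {
    Mod(sum(flt$b * zz^kb) / sum(flt$a * zz^ka))^2
  }, numeric(1))
}

# iteratively widen the design band so the two-pass -3 dB corners of the
# realized filter land on the requested edges
.prewarpEdges <- function(band, fs, order, iters = 3) {
  target <- 1 / sqrt(2)
  edges <- band
  for (it in seq_len(iters)) {
    flt <- signal::butter(order, edges / (fs / 2), type = "pass")
    for (side in 1:2) {
      grid <- band[side] * seq(0.6, 1.5, length.out = 721)
      grid <- grid[grid > 0 & grid < fs / 2]
      g <- .twoPassGain(flt, grid, fs)
      # actual corner: the crossing of the target nearest the band interior
      cross <- if (side == 1) {
        idx <- which(g >= target)
        if (!length(idx)) NA else grid[idx[1]]
      } else {
        idx <- which(g >= target)
        if (!length(idx)) NA else grid[idx[length(idx)]]
      }
      if (is.na(cross) || cross <= 0) next
      edges[side] <- edges[side] * band[side] / cross
    }
    edges[1] <- max(edges[1], band[1] * 0.2)
    edges[2] <- min(edges[2], fs / 2 * 0.999)
    if (edges[1] >= edges[2]) return(band)
  }
  edges
}

# transient span: ~3 time constants of the band's lower corner, capped at a
# third of typical epoch lengths by the caller
.filterEdgeSamples <- function(fs, band) {
  as.integer(ceiling(fs * 3 / (2 * pi * band[1]) + fs * 2 / diff(band)))
}

#' Zero-phase low/high-pass helper for very asymmetric bands
#'
#' For bands whose lower edge is a tiny fraction of Nyquist (e.g. the
#' 0.5-40 Hz sharp-wave band at 1200 Hz) a direct band-pass in transfer
#' function form is numerically fragile; a cascade of a low-order high-pass
#' and a low-pass is stable.
#'
#' @inheritParams bandpassFilter
#' @param hpOrder,lpOrder per-pass orders of the high- and low-pass stages.
#' @return filtered signal with attribute \code{edgeSamples}.
#' @export
cascadeBandpass <- function(x, fs, band, hpOrder = 2, lpOrder = 4) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2], band[2] < fs / 2)
  hp <- signal::butter(hpOrder, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(lpOrder, band[2] / (fs / 2), type = "low")
  y <- signal::filtfilt(lp, signal::filtfilt(hp, x))
  attr(y, "edgeSamples") <- .filterEdgeSamples(fs, band)
  y
}

#' Analytic signal (FFT construction)
#'
#' Returns the complex analytic signal whose real part is \code{x}; the
#' argument gives instantaneous phase, the modulus the amplitude envelope.
#'
#' @param x real numeric signal.
#' @return complex vector of the same length.
#' @export
analyticSignal <- function(x) {
  n <- length(x)
  if (n < 2) stop("signal too short for an analytic representation")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Fourier resampling
#'
#' Resamples a signal to a new rate by truncating (or zero-padding) its
#' discrete spectrum at the new Nyquist frequency, which is inherently
#' anti-aliased. Intended for band-limited LFP traces; the output length is
#' \code{round(length(x) * fsOut / fsIn)}.
#'
#' @param x numeric signal.
#' @param fsIn,fsOut input and output sampling rates, Hz.
#' @return resampled numeric signal.
#' @export
resampleSignal <- function(x, fsIn, fsOut) {
  stopifnot(fsIn > 0, fsOut > 0)
  if (fsIn == fsOut) return(x)
  n <- length(x)
  nOut <- round(n * fsOut / fsIn)
  X <- stats::fft(x)
  Y <- complex(real = numeric(nOut), imaginary = numeric(nOut))
  nKeep <- min(n, nOut)
  half <- floor(nKeep / 2)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half > 1) {
    Y[(nOut - half + 2):nOut] <- X[(n - half + 2):n]
  }
  # split a shared Nyquist bin to keep the output real
  if (nKeep %% 2 == 0 && nOut > nKeep) {
    Y[half + 1] <- X[half + 1] / 2
    Y[nOut - half + 1] <- Conj(X[half + 1]) / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# Hann window (periodic form, as used for spectral averaging)
.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# One-sided density-scaled periodogram of a windowed segment.
# Returns list(freq, density); integral of density * df == mean(w^2 x^2)
# normalized by the window power (Parseval under density scaling).
.segmentPeriodogram <- function(seg, fs, w) {
  n <- length(seg)
  X <- stats::fft(seg * w)
  nf <- floor(n / 2) + 1
  p <- (Mod(X)^2 / (fs * sum(w^2)))[1:nf]
  scale <- rep(2, nf)
  scale[1] <- 1
  if (n %% 2 == 0) scale[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / n, density = p * scale)
}

#' Periodogram peak frequency within a band
#'
#' Zero-pads a short trace to at least 1-Hz spectral resolution and returns
#' the frequency of the maximum of its periodogram within \code{band}.
#'
#' @param x numeric trace (already band-limited by the caller if desired).
#' @param fs sampling rate, Hz.
#' @param band length-2 search band, Hz.
#' @param resolutionHz maximum bin spacing, Hz (default 1; finer via
#'   zero-padding).
#' @return peak frequency in Hz, with attribute \code{power}: the
#'   rectangle-rule band power (units^2) of the unpadded trace over
#'   \code{band}.
#' @export
periodogramPeak <- function(x, fs, band, resolutionHz = 1) {
  stopifnot(length(band) == 2, band[1] < band[2])
  n <- length(x)
  if (n < 4) stop("trace too short for a periodogram")
  x <- x - mean(x)
  # band power on the unpadded grid (density scaling, rectangular window)
  pg <- .segmentPeriodogram(x, fs, rep(1, n))
  df <- fs / n
  inBand <- pg$freq >= band[1] & pg$freq < band[2]
  bandPow <- sum(pg$density[inBand]) * df
  nfft <- max(n, ceiling(fs / resolutionHz))
  xp <- c(x, numeric(nfft - n))
  pgz <- .segmentPeriodogram(xp, fs, rep(1, nfft))
  sel <- pgz$freq >= band[1] & pgz$freq <= band[2]
  if (!any(sel)) stop("band outside the resolvable frequency range")
  f <- pgz$freq[sel][which.max(pgz$density[sel])]
  attr(f, "power") <- bandPow
  f
}

#' Centered moving average
#'
#' @param x numeric vector.
#' @param k window length in samples (forced odd for symmetry).
#' @return smoothed vector, edges averaged over the available samples.
#' @keywords internal
movingAverage <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1) return(x)
  if (k %% 2 == 0) k <- k + 1L
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- (k - 1L) / 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
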