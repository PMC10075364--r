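# Independent oracles used to pin expected values. These deliberately use
# different routes than the package implementation (quadrature demodulation
# instead of the FFT analytic signal, stats::spec.pgram instead of the
# package Welch estimator, a literal double-loop step-up instead of the
# vectorized FDR).

# amplitude envelope of a narrowband component at f0 via quadrature
# demodulation: 2 * |lowpass(x * exp(-i 2 pi f0 t))|; the lowpass is a
# cascade of two moving averages with a zero at the 2*f0 image frequency
quadEnvelope <- function(x, fs, f0, smoothS = NULL) {
  t <- (seq_along(x) - 1) / fs
  z <- x * exp(-2i * pi * f0 * t)
  k <- max(3, round(fs / (2 * f0)))
  ma2 <- function(v) {
    v <- stats::filter(v, rep(1 / k, k), sides = 2)
    stats::filter(v, rep(1 / k, k), sides = 2)
  }
  2 * sqrt(ma2(Re(z))^2 + ma2(Im(z))^2)
}

# log-log spectral slope from base R's raw periodogram (independent of the
# package Welch implementation)
slopeOracle <- function(x, fs, fRange = c(1, 200)) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          plot = FALSE, detrend = TRUE)
  sel <- sp$freq >= fRange[1] & sp$freq <= fRange[2]
  stats::lsfit(log10(sp$freq[sel]), log10(sp$spec[sel]))$coefficients[2]
}

# literal Benjamini-Hochberg step-up from the definition (double loop)
bruteForceBH <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) {
      vals <- c(vals, m * p[ord[j]] / j)
    }
    q[ord[i]] <- min(1, min(vals))
  }
  list(q = q, reject = q <= alpha)
}

# dominant frequency of a short trace by direct periodogram scan
peakFreqOracle <- function(x, fs, band) {
  n <- length(x)
  nfft <- max(n, fs)  # >= 1 Hz resolution
  X <- Mod(stats::fft(c(x - mean(x), numeric(nfft - n))))^2
  f <- (0:(nfft - 1)) * fs / nfft
  sel <- f >= band[1] & f <= band[2]
  f[sel][which.max(X[sel])]
}

# standard single-bout epoch table covering a whole trace
wholeTraceEpochs <- function(n, fs, state = "exploration") {
  data.frame(state = state, start_s = 0, end_s = n / fs,
             start_sample = 0L, end_sample = as.integer(n),
             stringsAsFactors = FALSE)
}

# small two-channel session config used across tests (pyramidal ch 1,
# radiatum ch 2) to keep runtimes desk-scale
smallSessionConfig <- function(...) {
  sessionConfig(nChannels = 2L, pyramidalChannel = 1L, radiatumChannel = 2L,
                thetaChannelGains = c(1, 0.3), ...)
}
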