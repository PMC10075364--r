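# Theta-gamma phase-amplitude coupling: envelope-normalized mean-vector-
# length modulation index, comodulograms over 1-Hz bins, and time-resolved
# PAC on 1-s windows.

#' Instantaneous phase and amplitude envelope
#'
#' Computes the analytic-signal phase of a band-passed slow signal and the
#' analytic-signal magnitude (envelope) of a band-passed fast signal.
#' Filter-transient spans flagged by [bandpassFilter()] on either input are
#' propagated so callers can exclude them.
#'
#' @param phaseSig band-passed slow-oscillation signal.
#' @param ampSig band-passed fast-oscillation signal (same length).
#' @return list with \code{phase} (radians in (-pi, pi]), \code{envelope}
#'   and \code{edgeSamples} (per-side transient span to discard).
#' @export
phaseEnvelope <- function(phaseSig, ampSig) {
  if (length(phaseSig) != length(ampSig)) {
    stop("phase and amplitude signals must have equal length")
  }
  if (stats::sd(phaseSig) == 0 || stats::sd(ampSig) == 0) {
    stop("degenerate input: constant signal has no phase/envelope")
  }
  edge <- max(attr(phaseSig, "edgeSamples") %||% 0L,
              attr(ampSig, "edgeSamples") %||% 0L)
  a1 <- analyticSignal(as.numeric(phaseSig))
  a2 <- analyticSignal(as.numeric(ampSig))
  list(phase = Arg(a1), envelope = Mod(a2),
       edgeSamples = as.integer(min(edge, floor(length(phaseSig) / 3))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean-vector-length modulation index
#'
#' Each sample contributes a complex vector whose length is the fast
#' oscillation's envelope and whose angle is the slow oscillation's phase;
#' the modulation index is the modulus of the mean vector normalized by the
#' mean envelope:
#' \deqn{MI = |\langle A(t) e^{i\phi(t)} \rangle| / \langle A(t) \rangle.}
#' With no coupling the vectors cancel (MI near 0); with a sinusoidally
#' modulated envelope \eqn{A \propto 1 + \cos\phi} the continuous-limit
#' value is exactly 0.5. The normalization bounds MI in [0, 1] and makes it
#' invariant to amplitude rescaling of either signal.
#'
#' @param phase phase samples, radians.
#' @param envelope envelope samples, same length, >= 0.
#' @return list with \code{mi}, \code{n} (samples used) and
#'   \code{meanVector} (the complex mean before normalization).
#' @export
mvlModulationIndex <- function(phase, envelope) {
  if (length(phase) != length(envelope)) {
    stop("phase and envelope must have equal length")
  }
  m <- mean(envelope)
  if (!is.finite(m) || m <= 0) {
    stop("degenerate input: zero mean envelope")
  }
  v <- mean(envelope * exp(1i * phase))
  list(mi = Mod(v) / m, n = length(phase), meanVector = v)
}

#' Kullback-Leibler binned modulation index
#'
#' The 18-bin phase-binned alternative estimator: mean envelope per phase
#' bin, normalized to a distribution, scored by KL divergence from uniform
#' over log(nBins). Provided as a cross-check on the mean-vector-length
#' estimator; not used by the pipeline.
#'
#' @param phase,envelope as in [mvlModulationIndex()].
#' @param nBins number of phase bins (default 18).
#' @return modulation index (unitless, >= 0).
#' @export
klModulationIndex <- function(phase, envelope, nBins = 18) {
  bins <- findInterval(phase, seq(-pi, pi, length.out = nBins + 1),
                       rightmost.closed = TRUE, all.inside = TRUE)
  m <- vapply(seq_len(nBins), function(b) {
    if (any(bins == b)) mean(envelope[bins == b]) else 0
  }, numeric(1))
  if (sum(m) <= 0) stop("degenerate input: zero mean envelope")
  p <- m / sum(m)
  p <- p[p > 0]
  (log(nBins) + sum(p * log(p))) / log(nBins)
}

# per-epoch MI from precomputed phase/envelope over the whole recording
.epochMi <- function(phase, envelope, epochs, edge, nTotal) {
  lo <- edge + 1L
  hi <- nTotal - edge
  mis <- numeric(0)
  for (i in seq_len(nrow(epochs))) {
    i0 <- max(epochs$start_sample[i] + 1L, lo)
    i1 <- min(epochs$end_sample[i], hi)
    if (i1 <= i0) next
    mis <- c(mis, mvlModulationIndex(phase[i0:i1], envelope[i0:i1])$mi)
  }
  mis
}

#' Phase-amplitude comodulogram
#'
#' For every pair of 1-Hz phase and amplitude frequency bins: band-pass the
#' signal around each bin (phase bandwidth 2 Hz; amplitude bandwidth twice
#' the phase frequency, wide enough to carry the modulation sidebands),
#' extract phase and envelope, compute the mean-vector-length MI per
#' behavioral epoch, and average across epochs.
#'
#' @param x single-channel signal (full recording, microvolts).
#' @param fs sampling rate, Hz.
#' @param epochs epoch data.frame with 0-based half-open
#'   \code{start_sample}, \code{end_sample}; epochs shorter than 1 s are
#'   skipped.
#' @param phaseFreqs phase bin centers, Hz (default 5:12).
#' @param ampFreqs amplitude bin centers, Hz (default 30:120).
#' @param phaseBw full phase-filter bandwidth, Hz (default 2).
#' @param ampBwFactor amplitude-filter bandwidth as a multiple of the phase
#'   frequency (default 2, i.e. +/- one phase frequency).
#' @return a [Comodulogram-class].
#' @export
computeComodulogram <- function(x, fs, epochs, phaseFreqs = 5:12,
                                ampFreqs = 30:120, phaseBw = 2,
                                ampBwFactor = 2) {
  epochs <- epochs[(epochs$end_sample - epochs$start_sample) >= fs, ,
                   drop = FALSE]
  if (!nrow(epochs)) stop("no epochs of at least 1 s")
  n <- length(x)
  mi <- matrix(0, nrow = length(phaseFreqs), ncol = length(ampFreqs))
  nEp <- 0L
  for (pi_ in seq_along(phaseFreqs)) {
    fp <- phaseFreqs[pi_]
    # narrow 1-Hz-bin filters: design corners sit on the bin edges
    # (prewarp widening would smear adjacent bins into each other)
    ph <- bandpassFilter(x, fs, c(fp - phaseBw / 2, fp + phaseBw / 2),
                         prewarp = FALSE)
    phase <- Arg(analyticSignal(as.numeric(ph)))
    edgeP <- attr(ph, "edgeSamples")
    halfBw <- fp * ampBwFactor / 2
    for (ai in seq_along(ampFreqs)) {
      fa <- ampFreqs[ai]
      # pad the design corners ~5% so both modulation sidebands pass at
      # full gain in the bin centered on a carrier (the Butterworth
      # response is already -3 dB at its design corners); without the
      # pad, bins that catch one sideband against an attenuated carrier
      # show spurious beat modulation
      lo <- max((fa - halfBw) * 0.95, fp + phaseBw / 2)
      hi <- min((fa + halfBw) / 0.95, fs / 2 * 0.99)
      am <- bandpassFilter(x, fs, c(lo, hi), prewarp = FALSE)
      env <- Mod(analyticSignal(as.numeric(am)))
      edge <- min(max(edgeP, attr(am, "edgeSamples")), floor(n / 3))
      mis <- .epochMi(phase, env, epochs, edge, n)
      mi[pi_, ai] <- mean(mis)
      nEp <- max(nEp, length(mis))
    }
  }
  new("Comodulogram", mi = mi, phaseFreqs = as.numeric(phaseFreqs),
      ampFreqs = as.numeric(ampFreqs), nEpochs = nEp)
}

#' Group-average comodulogram
#'
#' Element-wise mean of subject comodulograms on a common bin grid.
#'
#' @param comods list of [Comodulogram-class] objects.
#' @return a [Comodulogram-class].
#' @export
averageComodulograms <- function(comods) {
  stopifnot(length(comods) >= 1)
  ref <- comods[[1]]
  for (cm in comods[-1]) {
    stopifnot(identical(cm@phaseFreqs, ref@phaseFreqs),
              identical(cm@ampFreqs, ref@ampFreqs))
  }
  m <- Reduce(`+`, lapply(comods, miMatrix)) / length(comods)
  new("Comodulogram", mi = m, phaseFreqs = ref@phaseFreqs,
      ampFreqs = ref@ampFreqs,
      nEpochs = as.integer(sum(vapply(comods, function(cm) cm@nEpochs,
                                      integer(1)))))
}

#' Local maxima of a comodulogram
#'
#' Bins whose MI exceeds all 8-neighbors; used to identify the main
#' frequency modes of modulation.
#'
#' @param comod a [Comodulogram-class].
#' @param minRel discard maxima below this fraction of the global peak
#'   (default 0.5).
#' @return data.frame with \code{phase_hz}, \code{amp_hz}, \code{mi},
#'   sorted by MI descending.
#' @export
comodulogramPeaks <- function(comod, minRel = 0.5) {
  m <- miMatrix(comod)
  nr <- nrow(m)
  nc <- ncol(m)
  peaks <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      nb <- m[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
      if (m[i, j] == max(nb) && sum(nb == max(nb)) == 1 &&
          m[i, j] >= minRel * max(m)) {
        peaks[[length(peaks) + 1L]] <- data.frame(
          phase_hz = comod@phaseFreqs[i], amp_hz = comod@ampFreqs[j],
          mi = m[i, j])
      }
    }
  }
  if (!length(peaks)) {
    return(data.frame(phase_hz = numeric(), amp_hz = numeric(),
                      mi = numeric()))
  }
  out <- do.call(rbind, peaks)
  out[order(-out$mi), , drop = FALSE]
}

#' Time-resolved PAC
#'
#' Band-passes the signal at one phase band and one amplitude band, splits
#' each behavioral epoch into non-overlapping 1-s windows (remainder
#' discarded), and computes the mean-vector-length MI per window. The
#' subject-level summary is the arithmetic mean over windows
#' ([subjectMean()]).
#'
#' @param x single-channel signal.
#' @param fs sampling rate, Hz.
#' @param epochs epoch data.frame (0-based half-open sample indices).
#' @param phaseBand,ampBand length-2 bands, Hz. The band pairs used for the
#'   state comparisons are 6.5-10 / 55-90 Hz and 6.5-9 / 35-45 Hz during
#'   exploration and 6.5-9 / 60-90 Hz during wake immobility.
#' @param epochLen window length, s (default 1).
#' @return a [TPacSeries-class].
#' @export
tpac <- function(x, fs, epochs, phaseBand, ampBand, epochLen = 1) {
  stopifnot(length(phaseBand) == 2, length(ampBand) == 2)
  win <- round(epochLen * fs)
  ph <- bandpassFilter(x, fs, phaseBand)
  am <- bandpassFilter(x, fs, ampBand)
  phase <- Arg(analyticSignal(as.numeric(ph)))
  env <- Mod(analyticSignal(as.numeric(am)))
  edge <- min(max(attr(ph, "edgeSamples"), attr(am, "edgeSamples")),
              floor(length(x) / 3))
  lo <- edge + 1L
  hi <- length(x) - edge
  mis <- numeric(0)
  for (i in seq_len(nrow(epochs))) {
    i0 <- max(epochs$start_sample[i] + 1L, lo)
    i1 <- min(epochs$end_sample[i], hi)
    nWin <- (i1 - i0 + 1L) %/% win
    if (nWin < 1) next
    for (w in seq_len(nWin)) {
      s0 <- i0 + (w - 1L) * win
      mis <- c(mis, mvlModulationIndex(phase[s0:(s0 + win - 1L)],
                                       env[s0:(s0 + win - 1L)])$mi)
    }
  }
  if (!length(mis)) stop("no complete window in any epoch")
  new("TPacSeries", mi = mis, phaseBand = as.numeric(phaseBand),
      ampBand = as.numeric(ampBand), epochLen = epochLen)
}

#' Circular-shift surrogate MI distribution
#'
#' Destroys phase-envelope alignment by circularly shifting the envelope by
#' random offsets of at least \code{minShiftS} seconds and recomputes the
#' MI, giving a null distribution for significance thresholds.
#'
#' @param phase,envelope as in [mvlModulationIndex()].
#' @param fs sampling rate, Hz.
#' @param n number of surrogates (default 200).
#' @param minShiftS minimum shift, s (default 1).
#' @param seed optional seed.
#' @return numeric vector of surrogate MI values.
#' @export
miSurrogates <- function(phase, envelope, fs, n = 200, minShiftS = 1,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- length(envelope)
  minShift <- round(minShiftS * fs)
  if (len <= 2 * minShift) stop("signal too short for the minimum shift")
  shifts <- sample(minShift:(len - minShift), n, replace = TRUE)
  vapply(shifts, function(s) {
    shifted <- c(envelope[(s + 1):len], envelope[1:s])
    mvlModulationIndex(phase, shifted)$mi
  }, numeric(1))
}
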