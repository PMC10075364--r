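# Phase-amplitude coupling: filters, analytic signal, modulation index,
# comodulogram, time-resolved PAC, surrogates.

test_that("band-pass filter passes the band and attenuates outside it", {
  fs <- 1000
  t <- (0:(30 * fs - 1)) / fs
  tone <- function(f) sin(2 * pi * f * t)
  rms <- function(x) sqrt(mean(x[5000:25000]^2))
  inband <- bandpassFilter(tone(8), fs, c(5, 12))
  expect_equal(rms(inband) / rms(tone(8)), 1, tolerance = 0.02)
  # stopband attenuation >= 40 dB for an 8 Hz tone through the
  # slow-gamma band
  out <- bandpassFilter(tone(8), fs, c(30, 45))
  expect_lt(20 * log10(rms(out) / rms(tone(8))), -40)
  expect_error(bandpassFilter(tone(8), fs, c(400, 600)), "Nyquist")
})

test_that("two-pass -3 dB corners land within 0.5 Hz of the band edges", {
  fs <- 1000
  t <- (0:(40 * fs - 1)) / fs
  gain <- function(f, band) {
    y <- bandpassFilter(sin(2 * pi * f * t), fs, band)
    sqrt(mean(y[10000:30000]^2)) / sqrt(0.5)
  }
  target <- 1 / sqrt(2)
  for (band in list(c(5, 12), c(30, 45))) {
    for (edge in band) {
      expect_equal(gain(edge, band), target, tolerance = 0.06)
      # gains 0.5 Hz inside/outside bracket the corner
      inside <- edge + 0.5 * (if (edge == band[1]) 1 else -1)
      outside <- edge - 0.5 * (if (edge == band[1]) 1 else -1)
      expect_gt(gain(inside, band), target)
      expect_lt(gain(outside, band), target)
    }
  }
})

test_that("phase and envelope extraction recover known constructs", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  ph <- cos(2 * pi * 8 * t)
  a <- analyticSignal(ph)
  # phase 0 at t = 0, advancing 2 pi per cycle
  expect_equal(Arg(a)[1], 0, tolerance = 0.01)
  d <- diff(Arg(a))
  d <- d - 2 * pi * round(d / (2 * pi))  # unwrap increments
  expect_equal(sum(d) / (2 * pi), 8 * 10, tolerance = 0.02 * 80)
  # amplitude-modulated carrier: envelope recovered within 3%
  A <- 1 + 0.5 * sin(2 * pi * 2 * t)
  x <- A * cos(2 * pi * 70 * t)
  pe <- phaseEnvelope(ph, x)
  mid <- 1000:9000
  expect_lt(max(abs(pe$envelope[mid] - A[mid]) / A[mid]), 0.03)
  expect_error(phaseEnvelope(rep(1, fs), rep(1, fs)), "degenerate")
  expect_error(phaseEnvelope(ph, x[1:10]), "equal length")
})

test_that("MVL modulation index matches closed forms", {
  set.seed(1)
  n <- 80000
  theta <- 2 * pi * 8 * (0:(n - 1)) / 1000
  phase <- ((theta + pi) %% (2 * pi)) - pi
  # uniform phase, constant envelope: MI ~ 0
  expect_lt(mvlModulationIndex(phase, rep(1, n))$mi, 0.02)
  # envelope 1 + cos(phase): continuous-limit MI exactly 0.5
  expect_equal(mvlModulationIndex(phase, 1 + cos(phase))$mi, 0.5,
               tolerance = 1e-3)
  # generator law: MI = d / (4 - 2d)
  env <- function(d) 1 - d + d * (1 + cos(phase)) / 2
  for (d in c(0.25, 0.5, 0.75, 1)) {
    expect_equal(mvlModulationIndex(phase, env(d))$mi, d / (4 - 2 * d),
                 tolerance = 1e-3)
  }
  expect_error(mvlModulationIndex(phase, rep(0, n)), "degenerate")
})

test_that("MI is scale-invariant and bounded in [0, 1]", {
  set.seed(2)
  for (i in 1:20) {
    n <- 5000
    phase <- runif(n, -pi, pi)
    envl <- abs(rnorm(n)) + 0.1
    mi <- mvlModulationIndex(phase, envl)$mi
    expect_gte(mi, 0)
    expect_lte(mi, 1)
    expect_equal(mvlModulationIndex(phase, 7.3 * envl)$mi, mi,
                 tolerance = 1e-12)
  }
})

test_that("estimated MI increases strictly with generator coupling depth", {
  fs <- 1000
  mis <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(d) {
    sig <- simPacSignal(8, 70, d, durationS = 10, fs = fs, noiseSd = 0.1,
                        seed = 30 + round(100 * d))
    ph <- bandpassFilter(sig$trace, fs, c(6, 10))
    am <- bandpassFilter(sig$trace, fs, c(55, 85))
    pe <- phaseEnvelope(ph, am)
    i <- (pe$edgeSamples + 1):(length(sig$trace) - pe$edgeSamples)
    mvlModulationIndex(pe$phase[i], pe$envelope[i])$mi
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
  expect_lt(mis[1], 0.02)
  # KL cross-check estimator agrees on ordering
  expect_gt(klModulationIndex(
    rep(seq(-pi, pi, length.out = 1000), 50),
    1 + cos(rep(seq(-pi, pi, length.out = 1000), 50))), 0.01)
})

test_that("comodulogram localizes a single injected coupling", {
  fs <- 600
  sig <- simPacSignal(8, 70, 0.8, durationS = 20, fs = fs, noiseSd = 0.3,
                      seed = 2)
  ep <- wholeTraceEpochs(length(sig$trace), fs)
  cm <- computeComodulogram(sig$trace, fs, ep)
  idx <- which(miMatrix(cm) == max(miMatrix(cm)), arr.ind = TRUE)
  expect_lte(abs(cm@phaseFreqs[idx[1]] - 8), 1)
  expect_lte(abs(cm@ampFreqs[idx[2]] - 70), 1)
  expect_true(all(miMatrix(cm) >= 0))
})

test_that("pure noise yields a flat comodulogram", {
  fs <- 600
  x <- simBackgroundNoise(20, fs, exponent = 1, seed = 17)
  ep <- wholeTraceEpochs(length(x), fs)
  cm <- computeComodulogram(x, fs, ep, phaseFreqs = c(6, 8, 10),
                            ampFreqs = seq(35, 95, by = 10))
  expect_lt(max(miMatrix(cm)), 3 * median(miMatrix(cm)))
})

test_that("tPAC separates states with different coupling depths", {
  cfg <- smallSessionConfig(
    fs = 1000, seed = 9L,
    stateSchedule = data.frame(
      state = c("exploration", "wake_immobility"), duration = c(60, 60)),
    pacDepthByState = c(exploration = 0.8, grooming = 0.4,
                        wake_immobility = 0.2),
    swrRateByState = c(exploration = 0, grooming = 0,
                       wake_immobility = 0))
  ses <- simSession(cfg)
  ep <- segmentSession(ses$tracking, ses$lfp)
  x <- lfpData(ses$lfp)[1, ]
  tE <- tpac(x, 1000, ep[ep$state == "exploration", ], c(6.5, 10),
             c(55, 90))
  tI <- tpac(x, 1000, ep[ep$state == "wake_immobility", ], c(6.5, 10),
             c(55, 90))
  se <- function(v) sd(v) / sqrt(length(v))
  gap <- subjectMean(tE) - subjectMean(tI)
  expect_gt(gap, 3 * sqrt(se(miValues(tE))^2 + se(miValues(tI))^2))
  expect_equal(subjectMean(tE), mean(miValues(tE)))
})

test_that("tPAC window SE shrinks as 1/sqrt(n) on stationary coupling", {
  fs <- 500
  sig <- simPacSignal(8, 70, 0.6, durationS = 60, fs = fs, noiseSd = 0.2,
                      seed = 5)
  ep <- wholeTraceEpochs(length(sig$trace), fs)
  series <- tpac(sig$trace, fs, ep, c(6, 10), c(55, 85))
  mis <- miValues(series)
  half <- mis[seq_len(floor(length(mis) / 2))]
  seFull <- sd(mis) / sqrt(length(mis))
  seHalf <- sd(half) / sqrt(length(half))
  expect_equal(seHalf / seFull, sqrt(2), tolerance = 0.35)
})

test_that("phase shuffling collapses coupled MI below the surrogate bound", {
  fs <- 500
  sig <- simPacSignal(8, 70, 0.8, durationS = 20, fs = fs, noiseSd = 0.1,
                      seed = 8)
  ph <- bandpassFilter(sig$trace, fs, c(6, 10))
  am <- bandpassFilter(sig$trace, fs, c(55, 85))
  pe <- phaseEnvelope(ph, am)
  i <- (pe$edgeSamples + 1):(length(sig$trace) - pe$edgeSamples)
  mi <- mvlModulationIndex(pe$phase[i], pe$envelope[i])$mi
  sur <- miSurrogates(pe$phase[i], pe$envelope[i], fs, n = 200, seed = 3)
  expect_gt(mi, quantile(sur, 0.95))
  # an uncoupled fixture stays below the surrogate bound
  sig0 <- simPacSignal(8, 70, 0, durationS = 20, fs = fs, noiseSd = 0.1,
                       seed = 9)
  ph0 <- bandpassFilter(sig0$trace, fs, c(6, 10))
  am0 <- bandpassFilter(sig0$trace, fs, c(55, 85))
  pe0 <- phaseEnvelope(ph0, am0)
  mi0 <- mvlModulationIndex(pe0$phase[i], pe0$envelope[i])$mi
  sur0 <- miSurrogates(pe0$phase[i], pe0$envelope[i], fs, n = 200,
                       seed = 4)
  expect_lt(mi0, quantile(sur0, 0.95))
})
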