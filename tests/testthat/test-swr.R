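# Sharp wave-ripple detection: power signal, dual-threshold detection,
# event features, co-occurrence pairing and occurrence ratios.

test_that("ripple power is silent for theta and localizes bursts", {
  fs <- 2500
  t <- (0:(20 * fs - 1)) / fs
  # pure theta: nothing in the ripple band
  rp <- ripplePowerSignal(50 * sin(2 * pi * 8 * t), fs)
  expect_identical(nrow(detectRipples(rp)), 0L)
  # injected 180 Hz burst: power peak within 8 ms of the burst center
  set.seed(6)
  x <- simBackgroundNoise(20, fs, 1, 20)
  burst <- simSwrTrain(data.frame(state = "wake_immobility", duration = 20),
                       c(wake_immobility = 0), rippleFreq = 180,
                       rippleAmp = 60, fs = fs, seed = 2,
                       nEventsByState = c(wake_immobility = 1))
  rp2 <- ripplePowerSignal(x + burst$pyr, fs)
  center <- mean(c(burst$events$start_s, burst$events$end_s))
  peakT <- (which.max(rp2@power) - 1) / rp2@fs
  # flat-core burst: the power peak can sit anywhere in the 60 ms core
  expect_lt(abs(peakT - center), 0.032)
  # constant input: degenerate flag, zero power
  rp3 <- ripplePowerSignal(rep(1, 10 * fs), fs)
  expect_true(all(rp3@segments$degenerate))
  expect_true(all(rp3@power == 0))
})

test_that("dual-threshold detection obeys the printed filters", {
  fs <- 2500
  set.seed(5)
  bg <- simBackgroundNoise(60, fs, 1, 20)
  inband <- sd(bandpassFilter(bg, fs, c(120, 250)))
  swband <- sd(cascadeBandpass(bg, fs, c(0.5, 40)))
  sched <- data.frame(state = "wake_immobility", duration = 60)
  ep <- data.frame(state = "wake_immobility", start_s = 0, end_s = 60,
                   start_sample = 0L, end_sample = 60L * fs)
  mkSession <- function(freq, durMs) {
    set.seed(5)
    bg <- simBackgroundNoise(60, fs, 1, 20)
    tr <- simSwrTrain(sched, c(wake_immobility = 0), rippleFreq = freq,
                      rippleDurMs = durMs, rippleAmp = 5 * inband,
                      swAmp = 8 * swband, fs = fs, seed = 7,
                      nEventsByState = c(wake_immobility = 10))
    LfpRecording(rbind(bg + tr$pyr, bg + tr$rad), fs,
                 c("pyramidal", "radiatum"))
  }
  # nominal events detected
  ok <- detectSwr(mkSession(180, 60), ep)
  expect_gte(nrow(ok), 9)
  expect_true(all(ok$duration_ms >= 30))
  expect_true(all(ok$psf_hz >= 140))
  expect_true(all(ok$paired_sw))
  # 20 ms bursts always rejected (duration rule)
  expect_identical(nrow(detectSwr(mkSession(180, 20), ep)), 0L)
  # 130 Hz bursts always rejected (peak-frequency rule)
  expect_identical(nrow(detectSwr(mkSession(130, 60), ep)), 0L)
})

test_that("raising the core threshold never increases the event count", {
  bm <- simSwrBenchmarkSession(seed = 3, nJoint = 40, nRippleOnly = 0,
                               nSwOnly = 0, durationS = 120)
  rp <- ripplePowerSignal(lfpData(bm$lfp)[1, ], samplingRate(bm$lfp),
                          epochs = bm$epochs)
  n3 <- nrow(detectRipples(rp, core = 3))
  n4 <- nrow(detectRipples(rp, core = 4))
  expect_lte(n4, n3)
})

test_that("event peak frequency matches a periodogram oracle", {
  fs <- 1200
  t <- (0:(0.06 * fs - 1)) / fs
  b180 <- sin(2 * pi * 180 * t)
  expect_equal(eventPeakFrequency(b180, fs), 180, tolerance = 5 / 180)
  # two-tone event: the dominant tone wins
  two <- 0.5 * sin(2 * pi * 150 * t) + sin(2 * pi * 200 * t)
  expect_equal(eventPeakFrequency(two, fs),
               peakFreqOracle(two, fs, c(120, 250)), tolerance = 1e-9)
  expect_equal(eventPeakFrequency(two, fs), 200, tolerance = 5 / 200)
  expect_error(eventPeakFrequency(b180[1:10], fs), "30 ms")
})

test_that("sharp-wave detection applies amplitude and duration rules", {
  fs <- 1200
  # flat signal: nothing
  expect_identical(nrow(detectSharpWaves(rep(0, 10 * fs), fs)), 0L)
  set.seed(12)
  bg <- simBackgroundNoise(30, fs, 1, 10)
  inject <- function(durMs, amp) {
    tr <- simSwrTrain(data.frame(state = "wake_immobility", duration = 30),
                      c(wake_immobility = 0), swAmp = amp, swDurMs = durMs,
                      rippleAmp = 0, fs = fs, seed = 3,
                      nEventsByState = c(wake_immobility = 3))
    bg + tr$rad
  }
  # 80 ms high-amplitude deflections detected
  sw <- detectSharpWaves(inject(80, 150), fs)
  expect_gte(nrow(sw), 3)
  expect_true(all(sw$duration_ms >= 20 & sw$duration_ms <= 400))
  # the duration window is applied in both directions: the same
  # suprathreshold runs vanish when the admissible range excludes them
  expect_identical(nrow(detectSharpWaves(inject(80, 150), fs,
                                         durMs = c(200, 400))), 0L)
  # crossings longer than 400 ms are rejected: a one-cycle 1 Hz burst
  # (in-band for the 0.5-40 Hz filter) stays above threshold ~440 ms per
  # half-cycle
  set.seed(13)
  long <- simBackgroundNoise(120, fs, 1, 10)
  tb <- (0:(fs - 1)) / fs
  long[60 * fs + seq_len(fs)] <- long[60 * fs + seq_len(fs)] +
    300 * sin(2 * pi * tb)
  hit <- function(ev) any(ev$start_s < 60.9 & ev$end_s > 60.1)
  expect_false(hit(detectSharpWaves(long, fs)))          # > 400 ms: dropped
  expect_true(hit(detectSharpWaves(long, fs,             # sanity: present
                                   durMs = c(20, 600))))
})

test_that("co-occurrence pairing keeps exactly the overlapping ripples", {
  rip <- data.frame(start_s = c(1.0, 2.0, 3.0), end_s = c(1.06, 2.06, 3.06),
                    duration_ms = 60, psf_hz = 180, band_power = 1,
                    peak_power = 4, state = "wake_immobility")
  sw <- data.frame(start_s = c(1.02, 5.0), end_s = c(1.10, 5.1),
                   duration_ms = c(80, 100), peak_uV = c(100, 90))
  kept <- pairSwrEvents(rip, sw)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$start_s, 1.0)
  expect_true(all(kept$paired_sw))
  # empty in, empty out
  expect_identical(nrow(pairSwrEvents(rip[0, ], sw)), 0L)
})

test_that("benchmark distractors are excluded by co-detection", {
  bm <- simSwrBenchmarkSession(seed = 1, nJoint = 30, nRippleOnly = 10,
                               nSwOnly = 10, durationS = 150)
  ev <- detectSwr(bm$lfp, bm$epochs)
  ro <- bm$events[bm$events$kind == "ripple_only", ]
  leaked <- vapply(seq_len(nrow(ro)), function(i) {
    any(ev$start_s < ro$end_s[i] & ro$start_s[i] < ev$end_s)
  }, logical(1))
  expect_identical(sum(leaked), 0L)
  joint <- bm$events[bm$events$kind == "joint", ]
  hits <- vapply(seq_len(nrow(joint)), function(i) {
    any(ev$start_s < joint$end_s[i] & joint$start_s[i] < ev$end_s)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("slow-gamma features quantify 40 Hz content during events", {
  fs <- 1200
  t <- (0:(0.2 * fs - 1)) / fs
  ev <- list(start_s = 0.05, end_s = 0.11)
  x1 <- 10 * sin(2 * pi * 40 * t)
  f1 <- slowGammaFeatures(x1, fs, ev)
  expect_equal(f1$psf_hz, 40, tolerance = 2 / 40)
  expect_true(f1$extended)
  # power scales with amplitude squared
  f2 <- slowGammaFeatures(2 * x1, fs, ev)
  expect_equal(f2$power / f1$power, 4, tolerance = 0.1)
})

test_that("occurrence ratio reflects per-state rates", {
  ep <- data.frame(state = c("exploration", "wake_immobility"),
                   start_s = c(0, 100), end_s = c(100, 200))
  mk <- function(nE, nI) {
    data.frame(state = rep(c("exploration", "wake_immobility"),
                           c(nE, nI)))
  }
  expect_equal(swrOccurrenceRatio(mk(10, 10), ep), 1)
  expect_equal(swrOccurrenceRatio(mk(2, 10), ep), 0.2)
  expect_equal(swrOccurrenceRatio(mk(0, 10), ep), 0)
  expect_warning(r <- swrOccurrenceRatio(mk(5, 0), ep), "infinite")
  expect_identical(r, Inf)
  epBad <- ep[1, ]
  expect_error(swrOccurrenceRatio(mk(1, 1), epBad), "zero total duration")
})

test_that("every retained event satisfies all four printed filters", {
  bm <- simSwrBenchmarkSession(seed = 2, nJoint = 40, nRippleOnly = 10,
                               nSwOnly = 10, durationS = 180)
  ev <- detectSwr(bm$lfp, bm$epochs)
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$duration_ms >= 30))
  expect_true(all(ev$psf_hz >= 140))
  expect_true(all(ev$paired_sw))
  expect_true(all(ev$end_s > ev$start_s))
})
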