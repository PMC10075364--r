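# Synthetic session generator: spectral shape of the background, PAC
# construction, event train statistics, tracking speeds, determinism.

test_that("background noise follows the requested spectral slope", {
  # white noise: flat spectrum
  x0 <- simBackgroundNoise(10, 1000, exponent = 0, seed = 3)
  expect_lt(abs(slopeOracle(x0, 1000)), 0.2)
  # pink noise: slope -1 on the log-log periodogram over 1-200 Hz
  x1 <- simBackgroundNoise(60, 1000, exponent = 1, seed = 7)
  expect_lt(abs(slopeOracle(x1, 1000) - (-1)), 0.2)
  expect_lt(abs(mean(x1)), 1e-9)
  expect_equal(sd(x1), 1, tolerance = 1e-9)
})

test_that("background generation is deterministic and validates input", {
  a <- simBackgroundNoise(10, 1000, exponent = 1, seed = 1)
  b <- simBackgroundNoise(10, 1000, exponent = 1, seed = 1)
  expect_identical(a, b)
  expect_error(simBackgroundNoise(-1, 1000), "positive")
  expect_error(simBackgroundNoise(10, 0), "positive")
})

test_that("PAC signal envelope follows the stated modulation law", {
  # depth 1: envelope minimum reaches 0 (up to phase sampling); depth 0:
  # constant envelope
  s1 <- simPacSignal(8, 70, 1, durationS = 2, fs = 1000)
  expect_lt(min(s1$envelope), 1e-3)
  s0 <- simPacSignal(8, 70, 0, durationS = 2, fs = 1000)
  expect_equal(max(s0$envelope), min(s0$envelope))
  # depth 0.5: max/min envelope ratio is (1)/(0.5) = 2 by the algebra,
  # recovered from the generated fast rhythm by the quadrature oracle
  # (slow rhythm omitted so the oracle demodulates the carrier alone)
  s <- simPacSignal(8, 70, 0.5, ampPhase = 0, durationS = 10, fs = 1000)
  env <- quadEnvelope(s$trace, 1000, 70)
  mid <- env[1000:9000]
  expect_equal(max(mid) / min(mid), 2, tolerance = 0.1)
  expect_error(simPacSignal(8, 70, 1.2), "pacDepth")
  expect_error(simPacSignal(70, 8, 0.5), "fAmp")
})

test_that("SWR train event counts follow per-state Poisson statistics", {
  sched <- data.frame(state = c("exploration", "wake_immobility"),
                      duration = c(50, 100))
  # rate 0 everywhere: empty
  tr0 <- simSwrTrain(sched, c(exploration = 0, wake_immobility = 0),
                     fs = 1000, seed = 1)
  expect_identical(nrow(tr0$events), 0L)
  expect_true(all(tr0$pyr == 0) && all(tr0$rad == 0))
  # rate 0.5/s in immobility only over 100 s: count within the Poisson
  # 99% interval of mean 50 and confined to immobility
  tr <- simSwrTrain(sched, c(exploration = 0, wake_immobility = 0.5),
                    fs = 1000, seed = 2)
  expect_gte(nrow(tr$events), qpois(0.005, 50))
  expect_lte(nrow(tr$events), qpois(0.995, 50))
  expect_true(all(tr$events$state == "wake_immobility"))
  # non-overlap and containment invariants
  expect_true(all(diff(tr$events$start_s) > 0))
  expect_true(all(tr$events$start_s >= 0 & tr$events$end_s <= 150))
  ovl <- head(tr$events$end_s, -1) > tail(tr$events$start_s, -1)
  expect_false(any(ovl))
})

test_that("injected ripple bursts carry the configured frequency", {
  fs <- 2500
  sched <- data.frame(state = "wake_immobility", duration = 20)
  tr <- simSwrTrain(sched, c(wake_immobility = 0), rippleFreq = 180,
                    rippleDurMs = 60, rippleAmp = 50, fs = fs, seed = 4,
                    nEventsByState = c(wake_immobility = 1))
  ev <- tr$events
  expect_identical(nrow(ev), 1L)
  idx <- (round(ev$start_s * fs) + 1):round(ev$end_s * fs)
  expect_equal(peakFreqOracle(tr$pyr[idx], fs, c(120, 250)), 180,
               tolerance = 5 / 180)
})

test_that("tracking speeds respect the state class boundaries strictly", {
  sched <- data.frame(
    state = c("exploration", "grooming", "wake_immobility"),
    duration = c(10, 10, 10))
  g <- simTracking(sched, frameRate = 30, arenaSide = 1, seed = 5)
  sp <- trackingSpeed(g$tracking)
  expect_true(all(sp[g$labels == "exploration"] > 0.05))
  gr <- sp[g$labels == "grooming"]
  expect_true(all(gr > 0 & gr <= 0.05))
  expect_true(all(sp[g$labels == "wake_immobility"] == 0))
  # immobility-only schedule: all displacements zero
  gi <- simTracking(data.frame(state = "wake_immobility", duration = 10),
                    seed = 1)
  expect_true(all(diff(gi$tracking@x) == 0) && all(diff(gi$tracking@y) == 0))
  expect_error(simTracking(sched, arenaSide = -1), "arenaSide")
})

test_that("scheduled exploration speed yields the expected path length", {
  sched <- data.frame(state = "exploration", duration = 30)
  g <- simTracking(sched, frameRate = 30, arenaSide = 2,
                   speedByState = c(exploration = 0.2, grooming = 0.03,
                                    wake_immobility = 0), seed = 6)
  pathLen <- sum(sqrt(diff(g$tracking@x)^2 + diff(g$tracking@y)^2))
  # speed x time = 6 m, minus one frame of discretization
  expect_equal(pathLen, 0.2 * 30, tolerance = 0.02)
})

test_that("full sessions are bit-identical under a fixed seed", {
  cfg <- smallSessionConfig(
    seed = 5L, fs = 1000,
    stateSchedule = data.frame(state = "exploration", duration = 5))
  a <- simSession(cfg)
  b <- simSession(cfg)
  expect_identical(lfpData(a$lfp), lfpData(b$lfp))
  expect_identical(a$tracking@x, b$tracking@x)
  expect_identical(a$truth@swrEvents, b$truth@swrEvents)
})

test_that("session ground truth tiles the session and stays inside it", {
  cfg <- smallSessionConfig(
    seed = 8L, fs = 1000,
    stateSchedule = data.frame(
      state = c("exploration", "wake_immobility"), duration = c(30, 30)),
    swrRateByState = c(exploration = 0.1, grooming = 0,
                       wake_immobility = 0.4))
  ses <- simSession(cfg)
  ev <- ses$truth@swrEvents
  expect_true(all(ev$start_s >= 0 & ev$end_s <= 60))
  expect_identical(length(ses$truth@frameState), 60L * 30L)
  expect_false(any(ses$truth@frameState == ""))
})

test_that("session config validity catches inconsistent parameters", {
  expect_error(sessionConfig(pacDepthByState = c(exploration = 1.5,
                                                 grooming = 0,
                                                 wake_immobility = 0)),
               "0, 1")
  expect_error(sessionConfig(fs = 100), "twice the highest")
  expect_error(sessionConfig(pyramidalChannel = 99L), "out of range")
  expect_error(sessionConfig(bogus = 1), "unknown")
})
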