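test_that("breath-signal extraction recovers the injected modulation", {
  cfg <- sceneConfig(rrBpm = 15, durationS = 10, noiseSd = 0,
                     driftAmplitude = 0, seed = 4)
  sc <- simulateThermalSequence(cfg)
  sig <- extractBreathSignal(sc$sequence, sc$detections)
  expect_equal(nSamples(sig), nSamples(sc$sequence))
  expect_true(sig@normalized)
  expect_gt(cor(traceValues(sig), sc$truth@maskTrace), 0.99)
})

test_that("missing detections are gap-filled up to the limit", {
  cfg <- sceneConfig(rrBpm = 15, durationS = 5, noiseSd = 0,
                     driftAmplitude = 0, seed = 4)
  sc <- simulateThermalSequence(cfg)
  dets <- sc$detections
  dets[70:72] <- list(NULL)  # 3-frame dropout
  sig <- extractBreathSignal(sc$sequence, dets)
  expect_equal(nSamples(sig), length(dets))

  dets[60:66] <- list(NULL)  # 7-frame dropout exceeds the limit
  expect_error(extractBreathSignal(sc$sequence, dets), "gap-fill limit")
})

test_that("a constant sequence yields a flagged, unnormalized signal", {
  frames <- array(30, dim = c(20, 20, 60))
  seqT <- thermalSequence(frames, fs = 30)
  det <- faceDetection(x = 2, y = 2, w = 14, h = 14, yEye = 8)
  expect_warning(sig <- extractBreathSignal(seqT, rep(list(det), 60)),
                 "zero-range")
  expect_true(sig@degenerate)
  expect_false(sig@normalized)
})

test_that("P2P converts mean inter-peak intervals to BPM", {
  # noiseless 4 s period in a 10 s window: peaks 4 s apart
  cfg <- sceneConfig(rrBpm = 15, durationS = 10, fs = 30, noiseSd = 0,
                     driftAmplitude = 0, seed = 1)
  est <- rrPeakToPeak(simulateBreathingTrace(cfg), windowS = 10)
  expect_equal(est@rr, 15, tolerance = 0.05)
  expect_false(est@tachypneaFlag)

  # flat signal: no peaks, indeterminate, never a number
  flat <- breathSignal(rep(0.5, 301), fs = 30)
  estF <- rrPeakToPeak(flat, windowS = 10)
  expect_true(is.na(estF@rr))
  expect_equal(estF@reason, "fewer_than_two_peaks")

  expect_error(rrPeakToPeak(flat, windowS = 8), ">= 10")
})

test_that("spectral RR equals the brute-force DFT argmax on every test signal", {
  for (rr in c(7, 12, 15, 21, 30)) {
    for (seed in c(1, 9)) {
      cfg <- sceneConfig(rrBpm = rr, durationS = 30, fs = 30,
                         noiseSd = 0.03, driftAmplitude = 0.1, seed = seed)
      sig <- simulateBreathingTrace(cfg)
      est <- rrSpectral(sig, windowS = 30)
      idx <- 1:nSamples(sig)
      # oracle sees the identically preprocessed window
      x <- traceValues(sig)
      x <- x - mean(x)
      x <- vitalcam:::lowPass(x, 30, 1.0)
      expect_equal(est@rr, oracleDftArgmaxBpm(x, 30), tolerance = 1e-9)
    }
  }
})

test_that("spectral RR flags structureless input instead of guessing", {
  set.seed(17)
  noise <- breathSignal(rnorm(901), fs = 30)
  est <- rrSpectral(noise, windowS = 30)
  expect_true(is.na(est@rr) || est@lowConfidence)

  expect_error(rrSpectral(noise, windowS = 15), ">= 20")
})

test_that("window-size rules follow resolution and slowest-rate constraints", {
  expect_equal(minRRWindow("fft", resolutionBpm = 3), 20)
  expect_equal(minRRWindow("p2p", rrMinBpm = 6), 10)
  expect_equal(minRRWindow("fft", resolutionBpm = 6), 10)
  expect_equal(rrResolutionBpm(20), 3)
  expect_equal(rrResolutionBpm(30), 2)
})

test_that("the Nyquist bound caps the measurable rate", {
  expect_equal(maxMeasurableRR(30), 900)
  expect_equal(maxMeasurableRR(2), 60)
  expect_equal(maxMeasurableRR(1), 30)
  expect_error(maxMeasurableRR(0), "fs")
})

test_that("tachypnea screening is strictly greater than 20 BPM", {
  expect_true(screenTachypnea(21))
  expect_false(screenTachypnea(20))
  expect_false(screenTachypnea(6))
})

test_that("respiratory heat loss follows the convective + evaporative terms", {
  expect_equal(respiratoryHeatLoss(100, 34, 5.87), 0)
  expect_equal(respiratoryHeatLoss(100, 24, 3.87), 1.4 + 3.46, tolerance = 1e-9)
  # linear in metabolic rate
  expect_equal(respiratoryHeatLoss(200, 24, 3.87),
               2 * respiratoryHeatLoss(100, 24, 3.87))
  amb <- ambientConditions(24, 3.87)
  expect_equal(respiratoryHeatLoss(100, amb), 4.86)
  expect_error(respiratoryHeatLoss(-5, amb), "M")
})
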