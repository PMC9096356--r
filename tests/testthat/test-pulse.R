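test_that("temporal normalization maps channels to unit-mean traces", {
  tr <- channelTraces(rep(5, 50), rep(7, 50), rep(9, 50), fs = 30)
  n <- temporalNormalize(tr)
  expect_equal(unname(n), matrix(1, 50, 3))

  set.seed(12)
  tr2 <- channelTraces(runif(100, 1, 2), runif(100, 1, 2), runif(100, 1, 2), fs = 30)
  expect_equal(unname(colMeans(temporalNormalize(tr2))), rep(1, 3),
               tolerance = 1e-12)

  # intensity invariance: a global gain cancels entirely
  tr3 <- channelTraces(3 * tr2@traces[, 1], 3 * tr2@traces[, 2],
                       3 * tr2@traces[, 3], fs = 30)
  expect_equal(temporalNormalize(tr3), temporalNormalize(tr2))

  bad <- channelTraces(c(0, 0), c(1, 1), c(1, 1), fs = 30)
  expect_error(temporalNormalize(bad), "positive")
})

test_that("POS projection matches the fixed matrix and kills common mode", {
  ones <- matrix(1, 10, 3, dimnames = list(NULL, c("r", "g", "b")))
  s <- posProject(ones)
  expect_equal(s$s1, rep(0, 10))
  expect_equal(s$s2, rep(0, 10))

  eps <- 0.01
  m1 <- matrix(rep(c(1, 1 + eps, 1 - eps), each = 5), 5, 3)
  s1 <- posProject(m1)
  expect_equal(s1$s1, rep(2 * eps, 5))
  expect_equal(s1$s2, rep(0, 5))

  m2 <- matrix(rep(c(1 + eps, 1, 1), each = 5), 5, 3)
  s2 <- posProject(m2)
  expect_equal(s2$s1, rep(0, 5))
  expect_equal(s2$s2, rep(-2 * eps, 5))

  # oracle equivalence on random matrices
  set.seed(33)
  for (i in 1:10) {
    m <- matrix(runif(60, 0.5, 1.5), 20, 3)
    got <- posProject(m)
    want <- oraclePosProject(m)
    expect_equal(got$s1, want$s1)
    expect_equal(got$s2, want$s2)
  }
})

test_that("variance-ratio combination is constructive in phase, destructive in antiphase", {
  t <- seq(0, 5, by = 1 / 30)
  s1 <- sin(2 * pi * 1.2 * t)

  expect_warning(h0 <- posCombine(s1, rep(0, length(s1))), "sigma")
  expect_equal(h0, s1)

  expect_equal(posCombine(s1, s1), 2 * s1)          # in phase, equal variance
  expect_equal(posCombine(s1, -s1), rep(0, length(s1)))  # antiphase cancels
})

test_that("the overlap-added pulse is zero-mean with zero-mean projections", {
  cfg <- sceneConfig(hrBpm = 72, durationS = 10, noiseSd = 0.002, seed = 8)
  pu <- posPulse(simulateReflectanceTraces(cfg)$traces)
  expect_equal(mean(pu@h), 0, tolerance = 1e-9)
  expect_equal(mean(pu@s1), 0, tolerance = 1e-9)
  expect_equal(mean(pu@s2), 0, tolerance = 1e-9)
  expect_equal(nSamples(pu), 300)
})

test_that("a pulse-free scene yields no fabricated heart rate", {
  flat <- channelTraces(rep(0.5, 300), rep(0.6, 300), rep(0.4, 300), fs = 30)
  expect_warning(pu <- posPulse(flat), "sigma")
  est <- estimateHeartRate(pu, latencyS = 10)
  expect_true(is.na(est@hr))
  expect_equal(est@reason, "no_pulsatile_content")
})

test_that("heart rate is recovered within one spectral bin, with or without specular load", {
  binBpm <- 6  # 10 s latency at 30 Hz: 0.1 Hz bins
  for (hr in c(45, 60, 66, 90, 120, 150)) {
    cfg <- sceneConfig(hrBpm = hr, durationS = 10, noiseSd = 0, seed = 9)
    clean <- simulateReflectanceTraces(cfg, specularAmp = 0)
    loaded <- simulateReflectanceTraces(cfg, specularAmp = 0.05)
    eClean <- estimateHeartRate(posPulse(clean$traces), latencyS = 10)
    eLoaded <- estimateHeartRate(posPulse(loaded$traces), latencyS = 10)
    expect_lte(abs(eClean@hr - hr), binBpm)
    # the common-mode disturbance must not move the estimate by more than a bin
    expect_lte(abs(eLoaded@hr - eClean@hr), binBpm)
  }
})

test_that("end-to-end pipeline is invariant to global intensity scaling", {
  cfg <- sceneConfig(hrBpm = 77, durationS = 10, noiseSd = 0.002, seed = 5)
  tr <- simulateReflectanceTraces(cfg)$traces
  scaled <- channelTraces(3.7 * tr@traces[, 1], 3.7 * tr@traces[, 2],
                          3.7 * tr@traces[, 3], fs = tr@fs)
  e1 <- estimateHeartRate(posPulse(tr), latencyS = 10)
  e2 <- estimateHeartRate(posPulse(scaled), latencyS = 10)
  expect_identical(e1@hr, e2@hr)
})

test_that("tachycardia is flagged strictly above 100 BPM", {
  expect_true(screenTachycardia(101))
  expect_false(screenTachycardia(100))
  expect_false(screenTachycardia(99))

  # fine spectral bins (60 s latency -> 1 BPM) resolve the boundary
  for (hr in c(99, 101)) {
    cfg <- sceneConfig(hrBpm = hr, durationS = 60, noiseSd = 0, seed = 2)
    sc <- simulateReflectanceTraces(cfg, specularAmp = 0)
    est <- estimateHeartRate(posPulse(sc$traces), latencyS = 60)
    expect_equal(est@hr, hr, tolerance = 1.01)
    expect_identical(est@tachycardiaFlag, hr > 100)
  }

  expect_error(estimateHeartRate(posPulse(
    simulateReflectanceTraces(sceneConfig(durationS = 5, seed = 1))$traces),
    latencyS = 10), "latency")
})
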