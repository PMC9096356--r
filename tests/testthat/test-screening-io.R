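makeScene <- function(rrBpm = 18, hrBpm = 72, skinTempC = 34.2,
                      distanceM = 2, ambientTempC = 19, durationS = 12,
                      seed = 11) {
  cfg <- sceneConfig(rrBpm = rrBpm, hrBpm = hrBpm, skinTempC = skinTempC,
                     distanceM = distanceM, ambientTempC = ambientTempC,
                     durationS = durationS, noiseSd = 0.03,
                     driftAmplitude = 0.05, seed = seed)
  list(cfg = cfg,
       thermal = simulateThermalSequence(cfg),
       refl = simulateReflectanceTraces(sceneConfig(
         rrBpm = rrBpm, hrBpm = hrBpm, skinTempC = skinTempC,
         distanceM = distanceM, ambientTempC = ambientTempC,
         durationS = durationS, noiseSd = 0.002, seed = seed)))
}

test_that("quick screening recovers all three vitals of a healthy scene", {
  sc <- makeScene()
  rep <- runScreening(thermal = sc$thermal[c("sequence", "detections")],
                      traces = sc$refl$traces,
                      ambient = ambientConditions(19),
                      calib = defaultThermalBias(),
                      baselineC = 34.2, subjectId = "synthetic-01")
  expect_s4_class(rep, "VitalsReport")
  expect_equal(rep@temperature@tCompensated, 34.2, tolerance = 0.1)
  expect_equal(rep@temperature@dM, 2, tolerance = 0.01)
  expect_equal(rep@rr@rr, 18, tolerance = 2)
  expect_equal(rep@hr@hr, 72, tolerance = 6)
  expect_false(rep@temperature@feverFlag)
  expect_false(rep@rr@tachypneaFlag)
  expect_false(rep@hr@tachycardiaFlag)
  expect_identical(rep@rr@method, "p2p")
  expect_identical(rep@rr@windowS, 10)
  expect_identical(rep@hr@latencyS, 10)
})

test_that("threshold crossings raise the screening flags", {
  sc <- makeScene(rrBpm = 25, seed = 13)
  rep <- runScreening(thermal = sc$thermal[c("sequence", "detections")],
                      traces = NULL, ambient = ambientConditions(19),
                      calib = defaultThermalBias(), baselineC = 34.2)
  expect_true(rep@rr@tachypneaFlag)

  # fever: hot subject against a cooler cohort baseline
  scF <- makeScene(skinTempC = 35.4, seed = 14)
  repF <- runScreening(thermal = scF$thermal[c("sequence", "detections")],
                       traces = NULL, ambient = ambientConditions(19),
                       calib = defaultThermalBias(), baselineC = 34.2)
  expect_true(repF@temperature@feverFlag)
})

test_that("missing inputs propagate as nulls with reason codes", {
  sc <- makeScene()
  rep <- runScreening(thermal = sc$thermal[c("sequence", "detections")],
                      traces = NULL, ambient = ambientConditions(19),
                      calib = defaultThermalBias(), baselineC = 34.2)
  expect_null(rep@hr)
  expect_identical(unname(rep@reasons["hr"]), "no_channel_traces")

  rep2 <- runScreening(thermal = NULL, traces = sc$refl$traces,
                       ambient = ambientConditions(19),
                       calib = defaultThermalBias(), baselineC = 34.2)
  expect_null(rep2@temperature)
  expect_null(rep2@rr)
  expect_identical(unname(rep2@reasons["temperature"]), "no_thermal_input")
})

test_that("monitor mode emits one RR estimate per 30 s window", {
  cfg <- sceneConfig(rrBpm = 14, durationS = 60, fs = 10, noiseSd = 0.03,
                     driftAmplitude = 0.05, seed = 21)
  th <- simulateThermalSequence(cfg)
  rep <- runScreening(thermal = th[c("sequence", "detections")],
                      traces = NULL, ambient = ambientConditions(22),
                      calib = defaultThermalBias(), baselineC = 34.2,
                      mode = "monitor")
  expect_length(rep@rrSeries, 2)
  for (e in rep@rrSeries) {
    expect_identical(e@method, "fft")
    expect_equal(e@rr, 14, tolerance = 2)
  }
  expect_identical(rep@rr@rr, rep@rrSeries[[2]]@rr)
})

test_that("trace CSV round trips and rejects malformed schemas", {
  sig <- simulateBreathingTrace(sceneConfig(durationS = 5, seed = 2))
  p <- file.path(tempdir(), "trace.csv")
  writeTraceCSV(sig, p)
  back <- readTraceCSV(p)
  expect_equal(traceValues(back), traceValues(sig), tolerance = 1e-9)
  expect_equal(sampleRate(back), 30, tolerance = 1e-6)

  df <- utils::read.csv(p)
  df$t_s[3] <- df$t_s[5]  # non-monotonic time
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(readTraceCSV(p), "non-monotonic")

  df2 <- utils::read.csv(p)
  names(df2)[2] <- "temp"  # unknown column, named in the error
  utils::write.csv(df2, p, row.names = FALSE)
  expect_error(readTraceCSV(p), "temp")
})

test_that("channel traces, detections and calibrations round trip", {
  tr <- simulateReflectanceTraces(sceneConfig(durationS = 4, seed = 6))$traces
  p <- file.path(tempdir(), "channels.csv")
  writeChannelTracesCSV(tr, p)
  expect_equal(readChannelTracesCSV(p)@traces, tr@traces, tolerance = 1e-9)

  dets <- list(simulateDetection(2), NULL, simulateDetection(3, pitch = 10))
  pj <- file.path(tempdir(), "dets.json")
  writeDetectionsJSON(dets, pj)
  back <- readDetectionsJSON(pj)
  expect_length(back, 3)
  expect_null(back[[2]])
  expect_equal(back[[1]]@box@w, dets[[1]]@box@w, tolerance = 1e-12)
  expect_equal(back[[3]]@pitch, 10)

  cal <- fitThermalCalibration(simulateCalibrationGrid(reps = 2, seed = 5))
  pc <- file.path(tempdir(), "calib.json")
  writeCalibrationJSON(cal, pc)
  calBack <- readCalibrationJSON(pc)
  for (s in c("a", "b", "c", "d"))
    expect_equal(slot(calBack, s), slot(cal, s), tolerance = 1e-12)
})

test_that("thermal sequences survive the 16-bit TIFF round trip", {
  sc <- simulateThermalSequence(sceneConfig(durationS = 1, seed = 3))
  p <- file.path(tempdir(), "seq.tiff")
  writeThermalSequenceTIFF(sc$sequence, p)
  back <- readThermalSequenceTIFF(p)
  expect_equal(dim(back@frames), dim(sc$sequence@frames))
  span <- diff(range(sc$sequence@frames))
  expect_lt(max(abs(back@frames - sc$sequence@frames)), span / 65535)
  expect_equal(sampleRate(back), 30)
})

test_that("vitals reports round trip through JSON, including indeterminates", {
  sc <- makeScene()
  rep <- runScreening(thermal = sc$thermal[c("sequence", "detections")],
                      traces = sc$refl$traces, ambient = ambientConditions(19),
                      calib = defaultThermalBias(), baselineC = 34.2)
  p <- file.path(tempdir(), "report.json")
  writeVitalsReportJSON(rep, p)
  back <- readVitalsReportJSON(p)
  expect_equal(back@temperature@tCompensated, rep@temperature@tCompensated)
  expect_equal(back@rr@rr, rep@rr@rr)
  expect_equal(back@hr@hr, rep@hr@hr)
  expect_identical(back@subjectId, rep@subjectId)

  # indeterminate stage serializes as explicit null + reason
  flat <- breathSignal(rep(0.5, 301), fs = 30)
  ind <- rrPeakToPeak(flat, windowS = 10)
  repInd <- new("VitalsReport", subjectId = "x", temperature = NULL,
                rr = ind, hr = NULL, mode = "quick",
                reasons = c(temperature = "no_thermal_input",
                            hr = "no_channel_traces"),
                timestamp = "2026-01-01T00:00:00+0000")
  writeVitalsReportJSON(repInd, p)
  raw <- jsonlite::read_json(p)
  expect_null(raw$rr$rr_bpm)
  expect_identical(raw$rr$reason, "fewer_than_two_peaks")
  backInd <- readVitalsReportJSON(p)
  expect_true(is.na(backInd@rr@rr))

  pcsv <- file.path(tempdir(), "log.csv")
  if (file.exists(pcsv)) unlink(pcsv)
  appendVitalsReportCSV(rep, pcsv)
  appendVitalsReportCSV(repInd, pcsv)
  log <- utils::read.csv(pcsv)
  expect_equal(nrow(log), 2)
  expect_true(is.na(log$rr_bpm[2]))
})
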