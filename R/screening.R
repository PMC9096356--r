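#' Run the vital-signs screening pipeline
#'
#' Ties the stages together: forehead skin temperature (compensated for
#' ambient and distance, distance inferred from the face-box diagonal),
#' respiratory rate from the mask-ROI breathing signal, heart rate from
#' tri-channel forehead traces via POS — each followed by its screening
#' threshold (fever, tachypnea, tachycardia).
#'
#' Two modes:
#' * `"quick"` — consumes exactly the first 10 s of input: P2P respiratory
#'   rate over a 10 s window and heart-rate latency 10 s, for rapid triage.
#' * `"monitor"` — FFT respiratory rate over consecutive
#'   `monitorWindowS`-second windows (one estimate per window, collected in
#'   `rrSeries`), for continuous monitoring.
#'
#' A missing or failed stage yields NULL in the report plus a reason code —
#' never a fabricated number. Indeterminate rate estimates propagate as NA
#' with their own reason.
#'
#' @param thermal NULL, or list(sequence = [ThermalSequence-class],
#'   detections = list of [FaceDetection-class]).
#' @param traces NULL or a [ChannelTraces-class].
#' @param ambient an [AmbientConditions-class].
#' @param calib a [ThermalCalibration-class] for temperature compensation.
#' @param mode "quick" or "monitor".
#' @param baselineC fever baseline (degC), e.g. from [baselineFromCohort()].
#' @param feverMarginC fever margin (degC), default 0.5.
#' @param latencyS heart-rate latency (s), default 10.
#' @param monitorWindowS monitoring RR window (s), default 30.
#' @param subjectId identifier written into the report.
#' @return A [VitalsReport-class].
#' @examples
#' cfg <- sceneConfig(rrBpm = 18, hrBpm = 72, skinTempC = 34.2,
#'                    distanceM = 2, ambientTempC = 19, seed = 11)
#' scene <- simulateThermalSequence(cfg)
#' refl <- simulateReflectanceTraces(cfg)
#' calib <- defaultThermalBias()  # generating model doubles as calibration
#' runScreening(thermal = scene[c("sequence", "detections")],
#'              traces = refl$traces,
#'              ambient = ambientConditions(19), calib = calib,
#'              baselineC = 34.2)
#' @export
runScreening <- function(thermal = NULL, traces = NULL, ambient, calib,
                         mode = c("quick", "monitor"), baselineC,
                         feverMarginC = 0.5, latencyS = 10,
                         monitorWindowS = 30, subjectId = "anonymous") {
  mode <- match.arg(mode)
  stopifnot(is(ambient, "AmbientConditions"), is(calib, "ThermalCalibration"))
  reasons <- character()
  temperature <- NULL
  rr <- NULL
  rrSeries <- list()
  hr <- NULL

  if (is.null(thermal)) {
    reasons["temperature"] <- "no_thermal_input"
    reasons["rr"] <- "no_thermal_input"
  } else {
    seqT <- thermal$sequence
    dets <- thermal$detections
    stopifnot(is(seqT, "ThermalSequence"))
    spanS <- if (mode == "quick") 10 else nSamples(seqT) / sampleRate(seqT)
    idx <- windowSamples(nSamples(seqT), sampleRate(seqT), min(spanS, nSamples(seqT) / sampleRate(seqT)))

    det1 <- Filter(Negate(is.null), dets)[[1]]
    dist <- estimateDistance(det1)
    tIRs <- vapply(idx, function(i) {
      det <- if (is.null(dets[[i]])) det1 else dets[[i]]
      roiTemperature(seqT@frames[, , i], foreheadROI(det))
    }, numeric(1))
    tIR <- mean(tIRs)
    tComp <- compensateTemperature(tIR, ambient, dist$dM, calib)
    temperature <- new("TemperatureReading", tIR = tIR, tCompensated = tComp,
                       dM = dist$dM, tAmbient = ambient@tAmbient,
                       feverFlag = screenFever(tComp, baselineC, feverMarginC))

    sig <- extractBreathSignal(seqT, dets)
    if (mode == "quick") {
      rr <- rrPeakToPeak(sig, windowS = 10)
    } else {
      nWin <- floor((nSamples(sig) / sampleRate(sig)) / monitorWindowS)
      if (nWin < 1L) {
        reasons["rr"] <- "signal_shorter_than_monitor_window"
      } else {
        rrSeries <- lapply(seq_len(nWin) - 1L, function(w)
          rrSpectral(sig, windowS = monitorWindowS, startS = w * monitorWindowS))
        rr <- rrSeries[[nWin]]
      }
    }
  }

  if (is.null(traces)) {
    reasons["hr"] <- "no_channel_traces"
  } else {
    hr <- estimateHeartRate(posPulse(traces), latencyS = latencyS)
  }

  new("VitalsReport", subjectId = subjectId, temperature = temperature,
      rr = rr, hr = hr, mode = mode, rrSeries = rrSeries, reasons = reasons,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
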