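#' Sampling rate accessor
#'
#' @param x a ThermalSequence, BreathSignal, ChannelTraces or PulseSignal.
#' @return numeric(1), the sampling/frame rate in Hz.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' Trace values accessor
#'
#' @param x a BreathSignal or PulseSignal.
#' @return numeric vector of sample values (the pulse waveform h(t) for a
#'   PulseSignal).
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' Number of frames / samples
#'
#' @param x a ThermalSequence, BreathSignal, ChannelTraces or PulseSignal.
#' @return integer(1).
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname sampleRate
setMethod("sampleRate", "ThermalSequence", function(x) x@fs)
#' @rdname sampleRate
setMethod("sampleRate", "BreathSignal", function(x) x@fs)
#' @rdname sampleRate
setMethod("sampleRate", "ChannelTraces", function(x) x@fs)
#' @rdname sampleRate
setMethod("sampleRate", "PulseSignal", function(x) x@fs)

#' @rdname traceValues
setMethod("traceValues", "BreathSignal", function(x) x@values)
#' @rdname traceValues
setMethod("traceValues", "PulseSignal", function(x) x@h)

#' @rdname nSamples
setMethod("nSamples", "ThermalSequence", function(x) dim(x@frames)[3L])
#' @rdname nSamples
setMethod("nSamples", "BreathSignal", function(x) length(x@values))
#' @rdname nSamples
setMethod("nSamples", "ChannelTraces", function(x) nrow(x@traces))
#' @rdname nSamples
setMethod("nSamples", "PulseSignal", function(x) length(x@h))

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI [%g, %g) x [%g, %g)  (%g x %g px)\n",
              object@x0, object@x1, object@y0, object@y1,
              object@x1 - object@x0, object@y1 - object@y0))
})

setMethod("show", "FaceDetection", function(object) {
  b <- object@box
  cat(sprintf("FaceDetection box=(%.1f, %.1f, %.1f x %.1f) yEye=%.1f pitch=%.1f yaw=%.1f\n",
              b@x, b@y, b@w, b@h, object@yEye, object@pitch, object@yaw))
})

setMethod("show", "ThermalSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ThermalSequence: %d frames of %d x %d px at %g Hz (%.1f s)\n",
              d[3], d[1], d[2], object@fs, d[3] / object@fs))
  cat(sprintf("  temperature range: [%.2f, %.2f] degC\n",
              min(object@frames), max(object@frames)))
})

setMethod("show", "BreathSignal", function(object) {
  cat(sprintf("BreathSignal: %d samples at %g Hz (%.1f s), %s%s\n",
              length(object@values), object@fs, length(object@values) / object@fs,
              if (object@normalized) "normalized [0,1]" else "raw (degC)",
              if (object@degenerate) " [degenerate: zero range]" else ""))
})

setMethod("show", "ChannelTraces", function(object) {
  m <- colMeans(object@traces)
  cat(sprintf("ChannelTraces: %d samples at %g Hz; channel means r=%.3g g=%.3g b=%.3g\n",
              nrow(object@traces), object@fs, m[1], m[2], m[3]))
})

setMethod("show", "ThermalCalibration", function(object) {
  cat("ThermalCalibration: bias(D, Ta) = (a*Ta + b)*(D + c) - d\n")
  cat(sprintf("  a = %.5g degC/m/degC, b = %.5g degC/m, c = %.4g m, d = %.4g degC\n",
              object@a, object@b, object@c, object@d))
  cat(sprintf("  ambient range [%g, %g] degC; fitted on: %s\n",
              object@ambientRange[1], object@ambientRange[2], object@fittedOn))
  if (length(object@r2))
    cat("  fit R2: ", paste(sprintf("%s=%.4f", names(object@r2), object@r2), collapse = ", "), "\n")
})

setMethod("show", "RREstimate", function(object) {
  if (is.na(object@rr)) {
    cat(sprintf("RREstimate (%s, %g s window): indeterminate [%s]\n",
                object@method, object@windowS, object@reason))
  } else {
    cat(sprintf("RREstimate (%s, %g s window): %.1f BPM, tachypnea=%s%s\n",
                object@method, object@windowS, object@rr, object@tachypneaFlag,
                if (object@lowConfidence) " [low confidence]" else ""))
  }
})

setMethod("show", "HREstimate", function(object) {
  if (is.na(object@hr)) {
    cat(sprintf("HREstimate (%g s latency): indeterminate [%s]\n",
                object@latencyS, object@reason))
  } else {
    cat(sprintf("HREstimate (%g s latency): %.1f BPM, tachycardia=%s\n",
                object@latencyS, object@hr, object@tachycardiaFlag))
  }
})

setMethod("show", "TemperatureReading", function(object) {
  cat(sprintf("TemperatureReading: T_IR=%.2f degC -> T_compensated=%.2f degC (D=%.2f m, T_ambient=%.1f degC), fever=%s\n",
              object@tIR, object@tCompensated, object@dM, object@tAmbient, object@feverFlag))
})

setMethod("show", "VitalsReport", function(object) {
  cat(sprintf("VitalsReport [%s mode] subject '%s' at %s\n",
              object@mode, object@subjectId, object@timestamp))
  if (is.null(object@temperature)) {
    cat(sprintf("  temperature: null (%s)\n", object@reasons[["temperature"]]))
  } else {
    cat(sprintf("  temperature: %.2f degC, fever=%s\n",
                object@temperature@tCompensated, object@temperature@feverFlag))
  }
  if (is.null(object@rr)) {
    cat(sprintf("  respiratory rate: null (%s)\n", object@reasons[["rr"]]))
  } else if (is.na(object@rr@rr)) {
    cat(sprintf("  respiratory rate: indeterminate (%s)\n", object@rr@reason))
  } else {
    cat(sprintf("  respiratory rate: %.1f BPM (%s), tachypnea=%s\n",
                object@rr@rr, object@rr@method, object@rr@tachypneaFlag))
  }
  if (is.null(object@hr)) {
    cat(sprintf("  heart rate: null (%s)\n", object@reasons[["hr"]]))
  } else if (is.na(object@hr@hr)) {
    cat(sprintf("  heart rate: indeterminate (%s)\n", object@hr@reason))
  } else {
    cat(sprintf("  heart rate: %.1f BPM, tachycardia=%s\n",
                object@hr@hr, object@hr@tachycardiaFlag))
  }
})
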