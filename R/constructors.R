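#' Construct a bounding box
#'
#' @param x,y top-left corner (px, 0-based).
#' @param w,h width and height (px), > 0.
#' @return A [BoundingBox-class].
#' @export
boundingBox <- function(x, y, w, h) new("BoundingBox", x = x, y = y, w = w, h = h)

#' Construct a face detection record
#'
#' @param box a [BoundingBox-class], or missing if `x,y,w,h` are given.
#' @param yEye eye-line y coordinate (px).
#' @param pitch,yaw head pose angles (degrees).
#' @param x,y,w,h alternative scalar box specification.
#' @return A [FaceDetection-class].
#' @examples
#' det <- faceDetection(x = 10, y = 20, w = 100, h = 120, yEye = 60)
#' foreheadROI(det)
#' @export
faceDetection <- function(box, yEye, pitch = 0, yaw = 0, x, y, w, h) {
  if (missing(box)) box <- boundingBox(x, y, w, h)
  new("FaceDetection", box = box, yEye = yEye, pitch = pitch, yaw = yaw)
}

#' Construct a thermal frame sequence
#'
#' @param frames H x W x T numeric array of temperatures (degC).
#' @param fs frame rate (Hz).
#' @param t0 time of first frame (s).
#' @return A [ThermalSequence-class].
#' @export
thermalSequence <- function(frames, fs, t0 = 0)
  new("ThermalSequence", frames = frames, fs = fs, t0 = t0)

#' Construct a breathing signal
#'
#' @param values numeric trace (degC raw, or unitless if normalized).
#' @param fs sampling rate (Hz).
#' @param t0 time of first sample (s).
#' @param normalized whether `values` are min-max normalized to [0, 1].
#' @param degenerate TRUE when the raw trace had zero range.
#' @return A [BreathSignal-class].
#' @export
breathSignal <- function(values, fs, t0 = 0, normalized = FALSE, degenerate = FALSE)
  new("BreathSignal", values = values, fs = fs, t0 = t0,
      normalized = normalized, degenerate = degenerate)

#' Construct tri-channel reflectance traces
#'
#' @param r,g,b equal-length numeric traces of the 630, 532 and 465 nm
#'   channels (arbitrary linear units).
#' @param fs sampling rate (Hz).
#' @return A [ChannelTraces-class].
#' @export
channelTraces <- function(r, g, b, fs) {
  if (length(r) != length(g) || length(g) != length(b))
    stop("channel traces must have equal lengths")
  new("ChannelTraces", traces = cbind(r = r, g = g, b = b), fs = fs)
}

#' Construct ambient conditions
#'
#' @param tAmbient ambient temperature (degC).
#' @param pA ambient/vapour pressure (kPa).
#' @return An [AmbientConditions-class].
#' @export
ambientConditions <- function(tAmbient, pA = 101.3)
  new("AmbientConditions", tAmbient = tAmbient, pA = pA)

#' Construct a thermal calibration
#'
#' The bias model is `bias(D, Ta) = (a*Ta + b)*(D + c) - d` with D in metres;
#' see [ThermalCalibration-class]. The all-zero calibration makes
#' [compensateTemperature()] the identity.
#'
#' @param a ambient sensitivity of the distance slope (degC/m/degC).
#' @param b distance-slope intercept (degC/m).
#' @param c additive distance offset (m).
#' @param d global temperature offset (degC).
#' @param ambientRange ambient range (degC) the calibration covers.
#' @param r2 optional named numeric of fit diagnostics.
#' @param fittedOn provenance tag.
#' @return A [ThermalCalibration-class].
#' @export
thermalCalibration <- function(a = 0, b = 0, c = 0, d = 0,
                               ambientRange = c(19, 28), r2 = numeric(),
                               fittedOn = "unspecified")
  new("ThermalCalibration", a = a, b = b, c = c, d = d,
      ambientRange = ambientRange, r2 = r2, fittedOn = fittedOn)

#' Default synthetic thermal bias
#'
#' The generator's default ambient/distance bias, chosen so that the
#' uncompensated error structure matches field observations of IR cameras
#' without a black-body reference: the distance slope is most negative in
#' cold rooms, giving a maximum absolute bias of about 1.3 degC at 5 m and
#' 19 degC ambient, shrinking to about 0.4 degC at 28 degC ambient.
#'
#' @return A [ThermalCalibration-class].
#' @export
defaultThermalBias <- function()
  thermalCalibration(a = 0.0173737, b = -0.5664646, c = 0.5, d = 0,
                     ambientRange = c(19, 28), fittedOn = "synthetic default")

#' Configure a synthetic scene
#'
#' Defines the ground-truth conditions a synthetic scene is rendered from:
#' physiological rates, skin and ambient temperature, subject distance, pose,
#' noise and drift levels, and the RNG seed. Defaults describe a resting
#' adult screened indoors at the system's intended operating distance.
#'
#' @param durationS scene length (s).
#' @param fs frame/sampling rate (Hz).
#' @param rrBpm true respiratory rate (breaths/min).
#' @param hrBpm true heart rate (beats/min).
#' @param skinTempC true forehead skin temperature (degC).
#' @param ambientTempC ambient temperature (degC).
#' @param distanceM subject distance (m).
#' @param noiseSd additive Gaussian noise s.d. (units of the perturbed signal).
#' @param driftAmplitude slow baseline drift amplitude (same units).
#' @param pitch,yaw head pose (degrees).
#' @param seed RNG seed (integer).
#' @return A [SceneConfig-class].
#' @examples
#' cfg <- sceneConfig(rrBpm = 18, hrBpm = 72, seed = 7)
#' sig <- simulateBreathingTrace(cfg)
#' @export
sceneConfig <- function(durationS = 30, fs = 30, rrBpm = 15, hrBpm = 72,
                        skinTempC = 34, ambientTempC = 23, distanceM = 2,
                        noiseSd = 0.03, driftAmplitude = 0.1,
                        pitch = 0, yaw = 0, seed = 1L)
  new("SceneConfig", durationS = durationS, fs = fs, rrBpm = rrBpm,
      hrBpm = hrBpm, skinTempC = skinTempC, ambientTempC = ambientTempC,
      distanceM = distanceM, noiseSd = noiseSd, driftAmplitude = driftAmplitude,
      pitch = pitch, yaw = yaw, seed = as.integer(seed))
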