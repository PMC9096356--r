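# Synthetic scene generators.
#
# Every generator seeds a single RNG from the SceneConfig seed at entry, so a
# fixed configuration is bit-reproducible, and returns the generating values
# as ground truth so downstream estimators can be validated without any
# recorded data.

#' Synthetic facemask breathing trace
#'
#' Renders the mask-ROI mean-temperature trace of a breathing subject: a
#' periodic oscillation at the true respiratory rate (exhalation peaks,
#' inhalation troughs) on a baseline, plus optional slow sinusoidal drift
#' (frequency <= 0.02 Hz) and additive i.i.d. Gaussian noise. The default
#' phase places an exhalation peak at t = 0, so a window of exactly one
#' period carries peaks on both endpoints.
#'
#' The oscillation is sinusoidal by default; `waveform = "fast_exhale"`
#' skews each cycle so the exhalation rise is faster than the inhalation
#' decay, as mask temperature traces often look in practice.
#'
#' @param config a [SceneConfig-class]; uses durationS, fs, rrBpm, noiseSd,
#'   driftAmplitude and seed.
#' @param amplitude oscillation amplitude (degC), default 0.3.
#' @param baseline mask baseline temperature (degC).
#' @param phase oscillation phase at t = 0 (radians); 0 = exhalation peak.
#' @param driftFreqHz drift frequency (Hz), must be <= 0.02.
#' @param waveform "sinusoid" or "fast_exhale".
#' @return A raw (unnormalized) [BreathSignal-class] of length
#'   round(durationS * fs).
#' @examples
#' sig <- simulateBreathingTrace(sceneConfig(rrBpm = 15, seed = 1))
#' rrSpectral(sig, windowS = 30)
#' @export
simulateBreathingTrace <- function(config, amplitude = 0.3, baseline = 32,
                                   phase = 0, driftFreqHz = 0.01,
                                   waveform = c("sinusoid", "fast_exhale")) {
  stopifnot(is(config, "SceneConfig"))
  waveform <- match.arg(waveform)
  if (driftFreqHz > 0.02) stop("'driftFreqHz' must be <= 0.02 Hz (slow drift)")
  set.seed(config@seed)
  n <- as.integer(round(config@durationS * config@fs))
  t <- (seq_len(n) - 1) / config@fs
  theta <- 2 * pi * (config@rrBpm / 60) * t + phase
  osc <- switch(waveform,
                sinusoid = cos(theta),
                fast_exhale = cos(theta + 0.4 * sin(theta)))
  driftPhase <- stats::runif(1, 0, 2 * pi)
  drift <- config@driftAmplitude * sin(2 * pi * driftFreqHz * t + driftPhase)
  noise <- stats::rnorm(n, 0, config@noiseSd)
  breathSignal(baseline + amplitude * osc + drift + noise, config@fs)
}

#' Synthetic face detection fixture
#'
#' A detection record geometrically consistent with a subject distance and
#' head pose under the monocular distance model: the frontal bounding box
#' has diagonal L = (k / D)^(1/p) with frontal width 0.6 L and height 0.8 L
#' (0.36 + 0.64 = 1, so the frontal diagonal is exactly L), and the pose
#' foreshortens the apparent width by cos(yaw) and height by cos(pitch).
#' [correctedDiagonal()] followed by [distanceFromDiagonal()] therefore
#' recovers the distance exactly.
#'
#' @param distanceM subject distance (m), > 0.
#' @param pitch,yaw head pose (degrees), |angle| < 90.
#' @param frameWidth,frameHeight frame dimensions (px) used to centre the
#'   box; an error is raised if the box does not fit.
#' @param k,p distance power-law constants, see [distanceFromDiagonal()].
#' @return A [FaceDetection-class].
#' @export
simulateDetection <- function(distanceM, pitch = 0, yaw = 0,
                              frameWidth = 160, frameHeight = 120,
                              k = 140.22, p = 1.14) {
  if (distanceM <= 0) stop("'distanceM' must be > 0")
  L <- diagonalFromDistance(distanceM, k, p)
  w <- 0.6 * L * cos(yaw * pi / 180)
  h <- 0.8 * L * cos(pitch * pi / 180)
  if (w + 2 > frameWidth || h + 2 > frameHeight)
    stop(sprintf("face box (%.0f x %.0f px) at %.2f m does not fit a %d x %d frame",
                 w, h, distanceM, frameWidth, frameHeight))
  x <- (frameWidth - w) / 2
  y <- (frameHeight - h) / 2
  faceDetection(boundingBox(x, y, w, h), yEye = y + 0.45 * h,
                pitch = pitch, yaw = yaw)
}

#' Synthetic thermal frame sequence
#'
#' Renders a thermal scene with known ground truth. The frame background
#' sits at the ambient temperature; within the face bounding box, forehead
#' ROI pixels read the true skin temperature plus the ambient/distance bias
#' of the supplied model, and mask-ROI pixels additionally carry the
#' breathing oscillation. All pixels receive i.i.d. Gaussian sensor noise.
#' Per-frame detection fixtures are generated with [simulateDetection()], so
#' the bounding-box geometry is consistent with the configured distance.
#'
#' The bias model is deliberately the same parametric family that
#' [fitThermalCalibration()] fits, which makes bias-compensation round trips
#' well-posed (a documented circularity of the synthetic validation).
#'
#' @param config a [SceneConfig-class].
#' @param bias a [ThermalCalibration-class] acting as the generating bias
#'   model; [defaultThermalBias()] by default. Pass the all-zero
#'   [thermalCalibration()] for unbiased frames.
#' @param frameWidth,frameHeight frame size (px).
#' @param maskAmplitude breathing oscillation amplitude in the mask ROI
#'   (degC), default 0.3.
#' @param maskOffset mask baseline relative to skin temperature (degC),
#'   default -1.5 (fabric is cooler than skin).
#' @param faceOffset non-ROI face pixels relative to skin temperature (degC).
#' @return list(sequence = [ThermalSequence-class], detections = list of
#'   [FaceDetection-class] (one per frame), truth = [GroundTruth-class] with
#'   the noiseless per-frame mask-ROI mean in `maskTrace`).
#' @export
simulateThermalSequence <- function(config, bias = defaultThermalBias(),
                                    frameWidth = 80, frameHeight = 60,
                                    maskAmplitude = 0.3, maskOffset = -1.5,
                                    faceOffset = -1) {
  stopifnot(is(config, "SceneConfig"), is(bias, "ThermalCalibration"))
  set.seed(config@seed)
  n <- as.integer(round(config@durationS * config@fs))
  t <- (seq_len(n) - 1) / config@fs

  det <- simulateDetection(config@distanceM, config@pitch, config@yaw,
                           frameWidth, frameHeight)
  fhROI <- foreheadROI(det)
  mkROI <- maskROI(det)
  box <- det@box
  bx <- (roundHalfAway(box@x) + 1):roundHalfAway(box@x + box@w)
  by <- (roundHalfAway(box@y) + 1):roundHalfAway(box@y + box@h)

  biasV <- thermalBias(bias, config@distanceM, config@ambientTempC)
  driftPhase <- stats::runif(1, 0, 2 * pi)
  drift <- config@driftAmplitude * sin(2 * pi * 0.01 * t + driftPhase)
  maskMean <- config@skinTempC + maskOffset + biasV +
    maskAmplitude * cos(2 * pi * (config@rrBpm / 60) * t) + drift

  frames <- array(0, dim = c(frameHeight, frameWidth, n))
  for (i in seq_len(n)) {
    fr <- matrix(config@ambientTempC, frameHeight, frameWidth)
    fr[by, bx] <- config@skinTempC + faceOffset + biasV
    fr[(fhROI@y0 + 1):fhROI@y1, (fhROI@x0 + 1):fhROI@x1] <- config@skinTempC + biasV
    fr[(mkROI@y0 + 1):mkROI@y1, (mkROI@x0 + 1):mkROI@x1] <- maskMean[i]
    if (config@noiseSd > 0)
      fr <- fr + stats::rnorm(length(fr), 0, config@noiseSd)
    frames[, , i] <- fr
  }

  truth <- new("GroundTruth", rrBpm = config@rrBpm, hrBpm = config@hrBpm,
               skinTempC = config@skinTempC, distanceM = config@distanceM,
               maskTrace = maskMean, seed = config@seed)
  list(sequence = thermalSequence(frames, config@fs),
       detections = rep(list(det), n),
       truth = truth)
}

#' Synthetic tri-channel reflectance traces
#'
#' Renders forehead reflectance traces under the dichromatic model: each
#' channel is its stationary mean modulated by a pulsatile component at the
#' true heart rate (relative strength given by the pulsatile unit vector,
#' strongest in green) and a specular/motion disturbance shared identically
#' across channels:
#'
#'   c_k(t) = I0 * mu_k * (1 + a_p * u_p[k] * pulse(t) + a_s * s(t) + noise)
#'
#' Because the common-mode s(t) is identical in all channels, the POS
#' projection annihilates it, which is what the generator exists to
#' exercise.
#'
#' @param config a [SceneConfig-class]; uses durationS, fs, hrBpm, noiseSd
#'   and seed.
#' @param pulseAmp pulsatile amplitude a_p (relative), > 0; default 0.01
#'   (the blood-volume pulse is of order 1% of skin reflectance).
#' @param specularAmp common-mode disturbance amplitude a_s (relative).
#' @param channelMeans stationary channel means mu (r, g, b), arbitrary
#'   positive units.
#' @param i0 global intensity scalar.
#' @param pulsatileVector relative pulsatile strengths per channel; the
#'   default (0.33, 0.77, 0.53)/norm is the canonical skin pulsatile
#'   signature, strongest in green.
#' @return list(traces = [ChannelTraces-class], truth = [GroundTruth-class]).
#' @examples
#' sc <- simulateReflectanceTraces(sceneConfig(hrBpm = 66, durationS = 10,
#'                                             noiseSd = 0, seed = 3),
#'                                 specularAmp = 0)
#' estimateHeartRate(posPulse(sc$traces))
#' @export
simulateReflectanceTraces <- function(config, pulseAmp = 0.01,
                                      specularAmp = 0.02,
                                      channelMeans = c(r = 0.45, g = 0.55, b = 0.35),
                                      i0 = 1,
                                      pulsatileVector = c(0.33, 0.77, 0.53)) {
  stopifnot(is(config, "SceneConfig"))
  if (pulseAmp <= 0) stop("'pulseAmp' must be > 0")
  if (specularAmp < 0) stop("'specularAmp' must be >= 0")
  set.seed(config@seed)
  n <- as.integer(round(config@durationS * config@fs))
  t <- (seq_len(n) - 1) / config@fs
  up <- pulsatileVector / sqrt(sum(pulsatileVector^2))

  pulse <- cos(2 * pi * (config@hrBpm / 60) * t + stats::runif(1, 0, 2 * pi))
  # shared low-frequency disturbance (motion / specular surrogate)
  sDist <- sin(2 * pi * 0.08 * t + stats::runif(1, 0, 2 * pi)) +
    0.6 * sin(2 * pi * 0.21 * t + stats::runif(1, 0, 2 * pi))
  if (max(abs(sDist)) > 0) sDist <- sDist / max(abs(sDist))

  tr <- vapply(1:3, function(k) {
    noise <- if (config@noiseSd > 0) stats::rnorm(n, 0, config@noiseSd) else numeric(n)
    i0 * channelMeans[k] * (1 + pulseAmp * up[k] * pulse + specularAmp * sDist + noise)
  }, numeric(n))

  truth <- new("GroundTruth", rrBpm = config@rrBpm, hrBpm = config@hrBpm,
               skinTempC = config@skinTempC, distanceM = config@distanceM,
               maskTrace = numeric(), seed = config@seed)
  list(traces = channelTraces(tr[, 1], tr[, 2], tr[, 3], config@fs),
       truth = truth)
}

#' Synthetic calibration measurement grid
#'
#' Forehead IR readings of a subject with known skin temperature over a grid
#' of distances and ambient temperatures, biased by the supplied model plus
#' Gaussian sensor noise — the design of a thermal calibration experiment.
#'
#' @param distances distances (m).
#' @param ambients ambient temperatures (degC).
#' @param trueTempC true skin temperature (degC).
#' @param bias a [ThermalCalibration-class] generating bias model.
#' @param reps readings per (distance, ambient) cell.
#' @param noiseSd sensor noise s.d. (degC).
#' @param seed RNG seed.
#' @return data.frame(t_ir, true_temp, t_ambient, d_m, rep), ready for
#'   [fitThermalCalibration()].
#' @export
simulateCalibrationGrid <- function(distances = 2:5, ambients = c(19, 21, 24, 28),
                                    trueTempC = 34, bias = defaultThermalBias(),
                                    reps = 10, noiseSd = 0.1, seed = 1L) {
  set.seed(as.integer(seed))
  g <- expand.grid(rep = seq_len(reps), d_m = distances, t_ambient = ambients)
  g$true_temp <- trueTempC
  g$t_ir <- trueTempC + thermalBias(bias, g$d_m, g$t_ambient) +
    stats::rnorm(nrow(g), 0, noiseSd)
  g[, c("t_ir", "true_temp", "t_ambient", "d_m", "rep")]
}
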