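#' @import methods
NULL

#' Face bounding box
#'
#' Axis-aligned facial bounding box in pixel coordinates, 0-based with the
#' origin at the top-left of the frame and y increasing downward. Coordinates
#' may be fractional: face detectors report sub-pixel boxes.
#'
#' @slot x,y numeric(1), top-left corner (px).
#' @slot w,h numeric(1), width and height (px), strictly positive.
#' @export
setClass("BoundingBox",
  representation(x = "numeric", y = "numeric", w = "numeric", h = "numeric"),
  validity = function(object) {
    msg <- character()
    for (s in c("x", "y", "w", "h")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v)) msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
    }
    if (length(msg) == 0L) {
      if (object@w <= 0) msg <- c(msg, "'w' must be > 0")
      if (object@h <= 0) msg <- c(msg, "'h' must be > 0")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Per-frame face detection
#'
#' A face bounding box together with the eye-line y coordinate and the head
#' pose angles, as produced by an external face detector and PnP pose solver.
#' This is the geometric substrate from which the forehead and facemask
#' regions of interest and the subject distance are derived.
#'
#' @slot box A [BoundingBox-class].
#' @slot yEye numeric(1), y coordinate of the eye landmarks (px); must lie
#'   strictly inside the box vertically.
#' @slot pitch,yaw numeric(1), head pose angles in degrees, |angle| < 90.
#' @export
setClass("FaceDetection",
  representation(box = "BoundingBox", yEye = "numeric",
                 pitch = "numeric", yaw = "numeric"),
  validity = function(object) {
    msg <- character()
    b <- object@box
    if (!(object@yEye > b@y && object@yEye < b@y + b@h))
      msg <- c(msg, "'yEye' must satisfy y < yEye < y + h")
    if (abs(object@pitch) >= 90) msg <- c(msg, "|pitch| must be < 90 degrees")
    if (abs(object@yaw) >= 90) msg <- c(msg, "|yaw| must be < 90 degrees")
    if (length(msg)) msg else TRUE
  }
)

#' Rectangular region of interest
#'
#' Half-open pixel rectangle [x0, x1) x [y0, y1), 0-based. A pixel with
#' 0-based column c and row r belongs to the ROI iff x0 <= c < x1 and
#' y0 <= r < y1.
#'
#' @slot x0,y0,x1,y1 integer-valued numeric(1); x1 > x0 and y1 > y0.
#' @export
setClass("ROI",
  representation(x0 = "numeric", y0 = "numeric", x1 = "numeric", y1 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@x1 <= object@x0) msg <- c(msg, "'x1' must be > 'x0'")
    if (object@y1 <= object@y0) msg <- c(msg, "'y1' must be > 'y0'")
    if (length(msg)) msg else TRUE
  }
)

#' Thermal frame sequence
#'
#' Time-ordered stack of 2-D temperature grids in degrees Celsius at a fixed
#' frame rate. Frames are stored as an H x W x T array indexed [row, col,
#' frame]; row 1 is the top of the image.
#'
#' @slot frames 3-D numeric array, H x W x T, degrees Celsius.
#' @slot fs numeric(1), frame rate in Hz.
#' @slot t0 numeric(1), time of the first frame in seconds.
#' @export
setClass("ThermalSequence",
  representation(frames = "array", fs = "numeric", t0 = "numeric"),
  prototype(t0 = 0),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@frames)) != 3L)
      msg <- c(msg, "'frames' must be a 3-D array (H x W x T)")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "'fs' must be a positive scalar (Hz)")
    if (length(msg)) msg else TRUE
  }
)

#' Breathing signal
#'
#' One-dimensional trace of the facemask-ROI mean temperature: the raw
#' breathing signal. Exhalation produces temperature peaks and inhalation
#' troughs. Values are either raw degrees Celsius or min-max normalized to
#' [0, 1] (`normalized = TRUE`). A constant input trace cannot be normalized;
#' such signals are returned raw with `degenerate = TRUE`.
#'
#' @slot values numeric vector, length >= 2.
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot t0 numeric(1), time of the first sample (s).
#' @slot normalized logical(1), whether values are min-max normalized.
#' @slot degenerate logical(1), TRUE when normalization was impossible
#'   (zero-range input).
#' @export
setClass("BreathSignal",
  representation(values = "numeric", fs = "numeric", t0 = "numeric",
                 normalized = "logical", degenerate = "logical"),
  prototype(t0 = 0, normalized = FALSE, degenerate = FALSE),
  validity = function(object) {
    msg <- character()
    if (length(object@values) < 2L) msg <- c(msg, "'values' must have length >= 2")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "'fs' must be a positive scalar (Hz)")
    if (isTRUE(object@normalized) && length(object@values) >= 2L) {
      rng <- range(object@values)
      if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
        msg <- c(msg, "normalized values must lie within [0, 1]")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Tri-channel reflectance traces
#'
#' Three time-aligned mean-intensity traces of the forehead ROI from
#' monochrome cameras filtered at 630 nm (r), 532 nm (g) and 465 nm (b), in
#' arbitrary linear camera units. Channel order is fixed as (r, g, b) and
#' validated: a permuted order silently breaks the POS projection, so traces
#' carry channel labels.
#'
#' @slot traces numeric matrix, n x 3, columns named "r", "g", "b".
#' @slot fs numeric(1), sampling rate in Hz.
#' @export
setClass("ChannelTraces",
  representation(traces = "matrix", fs = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@traces) != 3L || !identical(colnames(object@traces), c("r", "g", "b")))
      msg <- c(msg, "'traces' must have exactly the columns c(\"r\", \"g\", \"b\") in that order")
    if (nrow(object@traces) < 2L) msg <- c(msg, "traces must have length >= 2")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "'fs' must be a positive scalar (Hz)")
    if (length(msg)) msg else TRUE
  }
)

#' Ambient conditions
#'
#' Ambient temperature and vapour/ambient pressure, as reported by an
#' environmental sensor (e.g. a Bosch BME280). The pressure enters the
#' respiratory heat-exchange estimate; the temperature drives the thermal
#' bias compensation.
#'
#' @slot tAmbient numeric(1), ambient temperature in degrees Celsius,
#'   within (-20, 50).
#' @slot pA numeric(1), pressure in kPa, within (0, 110).
#' @export
setClass("AmbientConditions",
  representation(tAmbient = "numeric", pA = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@tAmbient > -20 && object@tAmbient < 50))
      msg <- c(msg, "'tAmbient' must lie in (-20, 50) degrees C")
    if (!(object@pA > 0 && object@pA < 110))
      msg <- c(msg, "'pA' must lie in (0, 110) kPa")
    if (length(msg)) msg else TRUE
  }
)

#' Thermal bias calibration
#'
#' Parameters of the ambient/distance bias model of an IR camera reading.
#' The measured minus true temperature is modelled as
#'
#'   bias(D, T_ambient) = (a * T_ambient + b) * (D + c) - d
#'
#' with D the subject distance in metres. The distance slope
#' `a * T_ambient + b` (degrees C per metre) is itself linear in the ambient
#' temperature and is non-positive over the calibrated ambient range:
#' readings drop with distance, and drop faster in colder rooms.
#' Compensation inverts this model, removing the need for a black-body
#' reference at fixed distance.
#'
#' @slot a numeric(1), ambient sensitivity of the distance slope
#'   (degC / m / degC).
#' @slot b numeric(1), distance-slope intercept (degC / m).
#' @slot c numeric(1), additive distance offset (m).
#' @slot d numeric(1), global temperature offset (degC).
#' @slot ambientRange numeric(2), ambient range (degC) over which the
#'   calibration was established (slope must be <= 0 across it).
#' @slot r2 named numeric, diagnostic R-squared values of the calibration
#'   fit stages (empty for hand-specified calibrations).
#' @slot fittedOn character(1), free-text provenance tag.
#' @export
setClass("ThermalCalibration",
  representation(a = "numeric", b = "numeric", c = "numeric", d = "numeric",
                 ambientRange = "numeric", r2 = "numeric", fittedOn = "character"),
  prototype(ambientRange = c(19, 28), r2 = numeric(), fittedOn = "unspecified"),
  validity = function(object) {
    msg <- character()
    for (s in c("a", "b", "c", "d")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v)) msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
    }
    if (length(object@ambientRange) != 2L || any(!is.finite(object@ambientRange)))
      msg <- c(msg, "'ambientRange' must be two finite values")
    if (length(msg) == 0L) {
      sl <- object@a * object@ambientRange + object@b
      if (any(sl > 1e-9))
        msg <- c(msg, "distance slope a*T_ambient + b must be <= 0 over 'ambientRange'")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Compensated temperature reading
#'
#' @slot tIR numeric(1), raw forehead ROI temperature (degC).
#' @slot tCompensated numeric(1), ambient/distance-compensated temperature (degC).
#' @slot dM numeric(1), subject distance (m).
#' @slot tAmbient numeric(1), ambient temperature (degC).
#' @slot feverFlag logical(1).
#' @export
setClass("TemperatureReading",
  representation(tIR = "numeric", tCompensated = "numeric", dM = "numeric",
                 tAmbient = "numeric", feverFlag = "logical"),
  validity = function(object) {
    if (!is.finite(object@tCompensated)) "'tCompensated' must be finite" else TRUE
  }
)

#' Respiratory-rate estimate
#'
#' An indeterminate estimate (e.g. fewer than two detectable breaths in the
#' window) carries `rr = NA` and a machine-readable `reason`; it is never a
#' fabricated number.
#'
#' @slot rr numeric(1), breaths per minute, or NA if indeterminate.
#' @slot method character(1), "p2p" or "fft".
#' @slot windowS numeric(1), analysis window length (s).
#' @slot tachypneaFlag logical(1), NA if indeterminate.
#' @slot lowConfidence logical(1), TRUE when the spectral peak is weakly
#'   dominant (fft method only).
#' @slot reason character(1), reason code when indeterminate, else "".
#' @export
setClass("RREstimate",
  representation(rr = "numeric", method = "character", windowS = "numeric",
                 tachypneaFlag = "logical", lowConfidence = "logical",
                 reason = "character"),
  prototype(lowConfidence = FALSE, reason = ""),
  validity = function(object) {
    if (!object@method %in% c("p2p", "fft")) return("'method' must be \"p2p\" or \"fft\"")
    if (!is.na(object@rr) && object@rr <= 0) return("'rr' must be positive when determinate")
    TRUE
  }
)

#' Heart-rate estimate
#'
#' @slot hr numeric(1), beats per minute, or NA if indeterminate.
#' @slot latencyS numeric(1), seconds of signal consumed before estimating.
#' @slot tachycardiaFlag logical(1), NA if indeterminate.
#' @slot reason character(1), reason code when indeterminate, else "".
#' @export
setClass("HREstimate",
  representation(hr = "numeric", latencyS = "numeric",
                 tachycardiaFlag = "logical", reason = "character"),
  prototype(reason = ""),
  validity = function(object) {
    if (!is.na(object@hr) && (object@hr < 30 || object@hr > 240))
      return("determinate 'hr' must lie in [30, 240] BPM")
    TRUE
  }
)

#' POS pulse signal
#'
#' The blood-volume pulse waveform h(t) recovered by the
#' plane-orthogonal-to-skin projection, together with the two intermediate
#' projected traces. Each is a zero-mean unitless trace.
#'
#' @slot h numeric vector, the pulse waveform.
#' @slot s1,s2 numeric vectors, the projected traces (overlap-added across
#'   sliding windows, same length as h).
#' @slot fs numeric(1), sampling rate (Hz).
#' @export
setClass("PulseSignal",
  representation(h = "numeric", s1 = "numeric", s2 = "numeric", fs = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@h)
    if (length(object@s1) != n || length(object@s2) != n)
      msg <- c(msg, "'s1', 's2' must have the same length as 'h'")
    if (length(object@fs) != 1L || object@fs <= 0) msg <- c(msg, "'fs' must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' Synthetic scene configuration
#'
#' The ground-truth physiological and environmental state from which the
#' synthetic generators render thermal sequences, breathing traces and
#' tri-channel reflectance traces. A fixed seed makes every generator
#' bit-reproducible.
#'
#' @slot durationS numeric(1), scene length (s), > 0.
#' @slot fs numeric(1), frame/sampling rate (Hz), > 0.
#' @slot rrBpm numeric(1), true respiratory rate (breaths/min), in
#'   [6, min(900, 60 * fs / 2)).
#' @slot hrBpm numeric(1), true heart rate (beats/min), in [30, 240].
#' @slot skinTempC numeric(1), true forehead skin temperature (degC).
#' @slot ambientTempC numeric(1), ambient temperature (degC).
#' @slot distanceM numeric(1), subject-to-camera distance (m), in (0.2, 10].
#' @slot noiseSd numeric(1), additive Gaussian noise s.d. in the units of the
#'   signal it perturbs (degC for thermal, relative intensity for reflectance).
#' @slot driftAmplitude numeric(1), amplitude of the slow (<= 0.02 Hz)
#'   sinusoidal baseline drift, same units as the signal.
#' @slot pitch,yaw numeric(1), head pose (degrees).
#' @slot seed integer(1), RNG seed.
#' @export
setClass("SceneConfig",
  representation(durationS = "numeric", fs = "numeric", rrBpm = "numeric",
                 hrBpm = "numeric", skinTempC = "numeric", ambientTempC = "numeric",
                 distanceM = "numeric", noiseSd = "numeric",
                 driftAmplitude = "numeric", pitch = "numeric", yaw = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@durationS <= 0) msg <- c(msg, "'durationS' must be > 0")
    if (object@fs <= 0) msg <- c(msg, "'fs' must be > 0")
    if (object@rrBpm < 6 || object@rrBpm > min(900, 60 * object@fs / 2))
      msg <- c(msg, "'rrBpm' must lie in [6, min(900, 60*fs/2)] (Nyquist)")
    if (object@hrBpm < 30 || object@hrBpm > 240)
      msg <- c(msg, "'hrBpm' must lie in [30, 240]")
    if (object@distanceM <= 0.2 || object@distanceM > 10)
      msg <- c(msg, "'distanceM' must lie in (0.2, 10] m")
    if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
    if (object@driftAmplitude < 0) msg <- c(msg, "'driftAmplitude' must be >= 0")
    if (abs(object@pitch) >= 90 || abs(object@yaw) >= 90)
      msg <- c(msg, "pose angles must be < 90 degrees in magnitude")
    if (length(msg)) msg else TRUE
  }
)

#' Ground truth of a synthetic scene
#'
#' @slot rrBpm,hrBpm,skinTempC,distanceM numeric(1), the generating values.
#' @slot maskTrace numeric, per-frame ground-truth mask-ROI mean temperature
#'   (degC), empty when not applicable.
#' @slot seed integer(1), the RNG seed used.
#' @export
setClass("GroundTruth",
  representation(rrBpm = "numeric", hrBpm = "numeric", skinTempC = "numeric",
                 distanceM = "numeric", maskTrace = "numeric", seed = "integer"))

#' Vital-signs screening report
#'
#' Assembled output of the screening pipeline: compensated skin temperature
#' with fever flag, respiratory rate with tachypnea flag, heart rate with
#' tachycardia flag, plus the distance and ambient context. Stages that could
#' not run hold NULL and a reason code in `reasons`.
#'
#' @slot subjectId character(1).
#' @slot temperature [TemperatureReading-class] or NULL.
#' @slot rr [RREstimate-class] or NULL.
#' @slot hr [HREstimate-class] or NULL.
#' @slot mode character(1), "quick" or "monitor".
#' @slot rrSeries list of [RREstimate-class], one per monitoring window
#'   (empty in quick mode); `rr` holds the latest of them.
#' @slot reasons named character, reason codes for absent stages.
#' @slot timestamp character(1), ISO-8601 creation time.
#' @export
setClass("VitalsReport",
  representation(subjectId = "character", temperature = "ANY", rr = "ANY",
                 hr = "ANY", mode = "character", rrSeries = "list",
                 reasons = "character", timestamp = "character"),
  prototype(reasons = character(), rrSeries = list()),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("quick", "monitor")) msg <- c(msg, "'mode' must be \"quick\" or \"monitor\"")
    ok <- function(x, cls) is.null(x) || is(x, cls)
    if (!ok(object@temperature, "TemperatureReading")) msg <- c(msg, "'temperature' must be NULL or TemperatureReading")
    if (!ok(object@rr, "RREstimate")) msg <- c(msg, "'rr' must be NULL or RREstimate")
    if (!ok(object@hr, "HREstimate")) msg <- c(msg, "'hr' must be NULL or HREstimate")
    if (length(msg)) msg else TRUE
  }
)
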