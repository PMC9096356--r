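#' Extract the breathing signal from a thermal sequence
#'
#' Respiration through a facemask retains exhaled heat in the mask
#' microenvironment, so the mask-ROI mean temperature oscillates with
#' breathing: exhalation produces peaks, inhalation troughs. This function
#' averages the mask-ROI pixels of every frame and min-max normalizes the
#' resulting trace to [0, 1].
#'
#' Frames with a missing detection (NULL entry) reuse the previous frame's
#' ROI for up to `maxGap` consecutive frames; longer gaps are an error. A
#' constant trace cannot be normalized and is returned raw with
#' `degenerate = TRUE`.
#'
#' @param seq a [ThermalSequence-class].
#' @param dets list of [FaceDetection-class], one per frame (NULL allowed for
#'   missing frames).
#' @param normalize min-max normalize to [0, 1] (default TRUE).
#' @param maxGap maximum run of gap-filled frames (default 5).
#' @return A [BreathSignal-class] of length nSamples(seq).
#' @export
extractBreathSignal <- function(seq, dets, normalize = TRUE, maxGap = 5L) {
  stopifnot(is(seq, "ThermalSequence"))
  nT <- nSamples(seq)
  if (length(dets) != nT)
    stop(sprintf("need one detection per frame: %d detections for %d frames",
                 length(dets), nT))
  vals <- numeric(nT)
  lastRoi <- NULL
  gap <- 0L
  for (i in seq_len(nT)) {
    det <- dets[[i]]
    if (is.null(det)) {
      gap <- gap + 1L
      if (gap > maxGap || is.null(lastRoi))
        stop(sprintf("missing detections exceed the gap-fill limit (%d frames) at frame %d",
                     maxGap, i))
      roi <- lastRoi
    } else {
      roi <- maskROI(det)
      lastRoi <- roi
      gap <- 0L
    }
    vals[i] <- mean(roiPixels(seq@frames[, , i], roi))
  }
  rng <- range(vals)
  if (normalize) {
    if (diff(rng) < 1e-9) {
      warning("zero-range mask trace; returning unnormalized signal (degenerate)")
      return(breathSignal(vals, seq@fs, seq@t0, normalized = FALSE, degenerate = TRUE))
    }
    vals <- (vals - rng[1]) / diff(rng)
    return(breathSignal(vals, seq@fs, seq@t0, normalized = TRUE))
  }
  breathSignal(vals, seq@fs, seq@t0, normalized = FALSE)
}

#' Respiratory rate by inter-peak intervals (P2P)
#'
#' Time-domain estimator: detect breath peaks on the detrended signal and
#' convert the mean inter-peak interval to breaths per minute,
#' rr = 60 / mean(diff(peak times)). Operable from a 10 s window — one full
#' period of the slowest physiological rate (6 BPM), whose two bounding peaks
#' fall on the window endpoints — which makes it the quick-screening method.
#'
#' Fewer than two detected peaks yield an indeterminate estimate (`rr = NA`
#' with a reason code), never a number.
#'
#' @param sig a [BreathSignal-class].
#' @param windowS analysis window (s), >= 10; the window is the first
#'   `windowS` seconds of the signal (endpoint inclusive), offset by
#'   `startS`.
#' @param startS window start (s) relative to the signal start.
#' @param rrMaxBpm fastest rate considered (BPM); sets the minimum peak
#'   spacing 60/rrMaxBpm s.
#' @param prominenceFrac minimum peak prominence as a fraction of the
#'   detrended signal's interquartile range.
#' @param tachypneaBpm screening threshold (BPM).
#' @return An [RREstimate-class].
#' @seealso [rrSpectral()], [minRRWindow()]
#' @export
rrPeakToPeak <- function(sig, windowS = 10, startS = 0, rrMaxBpm = 42,
                         prominenceFrac = 0.2, tachypneaBpm = 20) {
  stopifnot(is(sig, "BreathSignal"))
  if (windowS < minRRWindow("p2p"))
    stop(sprintf("P2P window must be >= %g s (one period of the slowest measurable rate)",
                 minRRWindow("p2p")))
  fs <- sig@fs
  idx <- windowSamples(length(sig@values), fs, windowS, startS)
  x <- sig@values[idx]
  # edge-safe preprocessing: breath peaks may sit on the window endpoints
  x <- detrendForPeaks(x, fs)
  x <- smoothMA(x, fs)

  iqr <- stats::IQR(x)
  peaks <- findSignalPeaks(x, fs, minSpacingS = 60 / rrMaxBpm,
                           minProminence = prominenceFrac * iqr)
  if (length(peaks) < 2L)
    return(new("RREstimate", rr = NA_real_, method = "p2p", windowS = windowS,
               tachypneaFlag = NA, reason = "fewer_than_two_peaks"))
  rr <- 60 / mean(diff(peaks) / fs)
  new("RREstimate", rr = rr, method = "p2p", windowS = windowS,
      tachypneaFlag = screenTachypnea(rr, tachypneaBpm))
}

#' Respiratory rate by spectral peak (FFT)
#'
#' Frequency-domain estimator: detrend, low-pass filter, and take the
#' magnitude spectrum of the window; the respiratory rate is 60 times the
#' frequency of the largest magnitude within the physiological band. The
#' frequency resolution is the reciprocal of the window length (1/t_w Hz), so
#' a 20 s window resolves 3 BPM; accordingly the minimum window is 20 s and
#' the method suits continuous monitoring rather than quick screening.
#'
#' Off-bin true rates are reported at the nearest bin. Setting
#' `zeroPad = TRUE` interpolates the spectrum on a 4x finer grid; it is off
#' by default so the reported resolution matches the window length.
#'
#' A spectrum without usable content in the band (flat signal) is
#' indeterminate; a peak that barely dominates the band (energy concentration
#' below `minConcentration`) is flagged low-confidence.
#'
#' @param sig a [BreathSignal-class].
#' @param windowS analysis window (s), >= 20.
#' @param startS window start (s).
#' @param band physiological search band in Hz, default c(0.08, 0.7)
#'   (about 5-42 BPM); keeps baseline drift and cardiac harmonics out of the
#'   argmax.
#' @param lowPassHz low-pass cutoff before the FFT (Hz).
#' @param zeroPad logical, 4x zero-padded spectrum refinement.
#' @param minConcentration minimum fraction of band energy within the peak
#'   bin and its two neighbours for a confident estimate.
#' @param tachypneaBpm screening threshold (BPM).
#' @return An [RREstimate-class].
#' @seealso [rrPeakToPeak()], [minRRWindow()], [rrResolutionBpm()]
#' @export
rrSpectral <- function(sig, windowS = 30, startS = 0, band = c(0.08, 0.7),
                       lowPassHz = 1.0, zeroPad = FALSE,
                       minConcentration = 0.4, tachypneaBpm = 20) {
  stopifnot(is(sig, "BreathSignal"))
  if (windowS < minRRWindow("fft"))
    stop(sprintf("FFT window must be >= %g s (frequency-resolution floor)",
                 minRRWindow("fft")))
  fs <- sig@fs
  idx <- windowSamples(length(sig@values), fs, windowS, startS)
  x <- sig@values[idx]
  x <- x - mean(x)
  x <- lowPass(x, fs, cutoffHz = lowPassHz)

  spec <- bandSpectrum(x, fs, band[1], band[2],
                       zeroPadFactor = if (zeroPad) 4L else 1L)
  if (!nrow(spec) || max(spec$mag) < 1e-12 * length(x))
    return(new("RREstimate", rr = NA_real_, method = "fft", windowS = windowS,
               tachypneaFlag = NA, reason = "empty_spectrum"))
  iMax <- which.max(spec$mag)
  pw <- spec$mag^2
  conc <- sum(pw[max(1, iMax - 1):min(nrow(spec), iMax + 1)]) / sum(pw)
  rr <- 60 * spec$freq[iMax]
  new("RREstimate", rr = rr, method = "fft", windowS = windowS,
      tachypneaFlag = screenTachypnea(rr, tachypneaBpm),
      lowConfidence = conc < minConcentration)
}

#' Minimum analysis window for RR estimation
#'
#' For the FFT method the window controls the frequency resolution
#' f_R = 1/t_w, so resolving `resolutionBpm` requires t_w = 60/resolutionBpm
#' seconds (20 s for 3 BPM). For the time-domain P2P method the constraint is
#' instead that the window span one full period of the slowest rate of
#' interest so two peaks fit in it: t_w = 60/rrMinBpm (10 s for 6 BPM).
#'
#' @param method "fft" or "p2p".
#' @param rrMinBpm slowest rate to measure (BPM), P2P constraint.
#' @param resolutionBpm required resolution (BPM), FFT constraint.
#' @return numeric(1), seconds.
#' @export
minRRWindow <- function(method = c("fft", "p2p"), rrMinBpm = 6, resolutionBpm = 3) {
  method <- match.arg(method)
  switch(method,
         fft = 60 / resolutionBpm,
         p2p = 60 / rrMinBpm)
}

#' Frequency resolution of a spectral RR window
#'
#' f_R = f_s / n = 1 / t_w, reported in BPM: 60 / t_w. Independent of the
#' sampling rate, which only sets the Nyquist ceiling.
#'
#' @param windowS window length (s).
#' @return numeric(1), BPM.
#' @export
rrResolutionBpm <- function(windowS) 60 / windowS

#' Maximum measurable respiratory rate
#'
#' Nyquist bound: the sampling rate must be at least twice the signal
#' frequency, so the fastest measurable rate is 60 * fs / 2 BPM (900 BPM at
#' 30 Hz — far above any physiological rate, so the frame rate never limits
#' tachypnea screening).
#'
#' @param fs sampling rate (Hz).
#' @return numeric(1), BPM.
#' @export
maxMeasurableRR <- function(fs) {
  if (fs <= 0) stop("'fs' must be > 0")
  60 * fs / 2
}

#' Tachypnea screen
#'
#' @param rrBpm respiratory rate (BPM); vectorized.
#' @param threshold screening threshold, default 20 BPM.
#' @return logical, TRUE when rrBpm is strictly greater than the threshold.
#' @export
screenTachypnea <- function(rrBpm, threshold = 20) rrBpm > threshold

#' Respiratory heat exchange with the environment
#'
#' Parsons' estimate of the convective plus evaporative heat loss through
#' respiration,
#'
#'   C_res + E_res = 0.0014 M (34 - T_ambient) + 0.0173 M (5.87 - P_a),
#'
#' with M the metabolic rate (W/m^2), T_ambient in degC and P_a the ambient
#' vapour pressure in kPa. This exchange, trapped by a facemask's
#' microenvironment, is what makes the mask-ROI temperature oscillate with
#' breathing.
#'
#' @param M metabolic rate (W/m^2), > 0.
#' @param ambient an [AmbientConditions-class], or the ambient temperature in
#'   degC (with `pA` supplied separately).
#' @param pA vapour pressure (kPa) when `ambient` is numeric.
#' @return numeric(1), W/m^2 (positive = heat lost to the environment).
#' @export
respiratoryHeatLoss <- function(M, ambient, pA = NULL) {
  if (any(M <= 0)) stop("'M' must be > 0")
  if (is(ambient, "AmbientConditions")) {
    tA <- ambient@tAmbient
    pA <- ambient@pA
  } else {
    tA <- ambient
    if (is.null(pA)) stop("supply 'pA' (kPa) when 'ambient' is numeric")
  }
  0.0014 * M * (34 - tA) + 0.0173 * M * (5.87 - pA)
}
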