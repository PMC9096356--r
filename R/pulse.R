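#' Temporal normalization of channel traces
#'
#' Divides each channel by its temporal mean over the window so the mean
#' signal equals the unit vector. This removes the intensity scale (camera
#' gain, illumination level): scaling all channels by any positive constant
#' leaves the output unchanged, which is the point of the normalization.
#'
#' @param traces a [ChannelTraces-class], or an n x 3 matrix with columns
#'   (r, g, b).
#' @return n x 3 matrix of normalized traces, each column with mean exactly 1.
#' @export
temporalNormalize <- function(traces) {
  m <- if (is(traces, "ChannelTraces")) traces@traces else as.matrix(traces)
  mu <- colMeans(m)
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("channel temporal means must be positive (saturated or invalid ROI?)")
  sweep(m, 2, mu, "/")
}

#' POS projection
#'
#' Projects temporally normalized (r, g, b) traces onto the two axes of the
#' plane orthogonal to the skin-tone direction, via the fixed 2 x 3 matrix
#'
#'   P = | 0  1 -1 |
#'       |-2  1  1 |
#'
#' i.e. S1 = g - b and S2 = -2r + g + b per time step. Both rows of P sum to
#' zero, so any common-mode component (equal in all three channels — the
#' specular/intensity part) is annihilated, while the blood-volume pulse,
#' strongest in the green channel, survives in both projections.
#'
#' @param normalized n x 3 matrix from [temporalNormalize()].
#' @return list(s1, s2), numeric vectors of length n.
#' @export
posProject <- function(normalized) {
  m <- as.matrix(normalized)
  if (ncol(m) != 3L) stop("'normalized' must have 3 columns (r, g, b)")
  list(s1 = m[, 2] - m[, 3],
       s2 = -2 * m[, 1] + m[, 2] + m[, 3])
}

#' POS combination of projected traces
#'
#' Combines the two projected traces into one pulse waveform,
#'
#'   h = S1 + (sigma(S1) / sigma(S2)) * S2,
#'
#' where sigma is the sample standard deviation over the window. Equalizing
#' the variances makes in-phase projections add constructively while
#' antiphase (motion/specular-dominated) content cancels. When sigma(S2) is
#' zero the ratio is undefined and h falls back to S1 with a warning.
#'
#' @param s1,s2 equal-length numeric vectors.
#' @return numeric vector h of the same length.
#' @export
posCombine <- function(s1, s2) {
  if (length(s1) != length(s2) || length(s1) < 2L)
    stop("'s1' and 's2' must be equal-length vectors of length >= 2")
  sd2 <- stats::sd(s2)
  if (sd2 < 1e-12) {
    warning("sigma(S2) = 0; falling back to h = S1 for this window")
    return(s1)
  }
  s1 + (stats::sd(s1) / sd2) * s2
}

#' Recover the pulse waveform from channel traces (POS)
#'
#' Full plane-orthogonal-to-skin pipeline over sliding windows: within each
#' window of `windowS` seconds the traces are temporally normalized,
#' projected ([posProject()]) and combined ([posCombine()]); the zero-mean
#' window waveforms are then overlap-added into one pulse signal. The short
#' window (default 1.6 s, 48 samples at 30 Hz) keeps the normalization local,
#' which is what makes the method robust to slow intensity and motion drift.
#'
#' @param traces a [ChannelTraces-class].
#' @param windowS sliding-window length in seconds (default 1.6).
#' @return A [PulseSignal-class] of length nSamples(traces).
#' @seealso [estimateHeartRate()]
#' @export
posPulse <- function(traces, windowS = 1.6) {
  stopifnot(is(traces, "ChannelTraces"))
  fs <- traces@fs
  n <- nSamples(traces)
  l <- max(2L, as.integer(round(windowS * fs)))
  if (l > n) l <- n
  h <- numeric(n)
  s1Acc <- numeric(n)
  s2Acc <- numeric(n)
  hadZeroSigma <- FALSE
  for (m in 1:(n - l + 1L)) {
    idx <- m:(m + l - 1L)
    cn <- temporalNormalize(traces@traces[idx, , drop = FALSE])
    s <- posProject(cn)
    hw <- withCallingHandlers(
      posCombine(s$s1, s$s2),
      warning = function(w) {
        if (grepl("sigma\\(S2\\)", conditionMessage(w))) {
          hadZeroSigma <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    h[idx] <- h[idx] + (hw - mean(hw))
    s1Acc[idx] <- s1Acc[idx] + (s$s1 - mean(s$s1))
    s2Acc[idx] <- s2Acc[idx] + (s$s2 - mean(s$s2))
  }
  if (hadZeroSigma)
    warning("sigma(S2) = 0 in at least one window; used h = S1 there")
  new("PulseSignal", h = h, s1 = s1Acc, s2 = s2Acc, fs = fs)
}

#' Heart rate from a pulse waveform
#'
#' Spectral estimation over the first `latencyS` seconds of the pulse signal
#' (the latency is how long a subject is recorded before an estimate is
#' made; 10 s by default, matching the quick respiratory screen). The
#' waveform is band-passed to the cardiac band, Hann-tapered, and the heart
#' rate is 60 times the frequency of the periodogram maximum within the
#' band. Tachycardia is flagged strictly above `tachycardiaBpm`.
#'
#' @param pulse a [PulseSignal-class] (or a [ChannelTraces-class], which is
#'   first passed through [posPulse()]).
#' @param latencyS seconds of signal used (default 10); the signal must be at
#'   least this long.
#' @param band cardiac band in Hz, default c(0.7, 4) (42-240 BPM).
#' @param tachycardiaBpm screening threshold, default 100 BPM.
#' @param method "periodogram" (default) or "welch" (averaged modified
#'   periodograms over 50%-overlapping half-length segments; coarser bins,
#'   lower variance).
#' @return An [HREstimate-class].
#' @export
estimateHeartRate <- function(pulse, latencyS = 10, band = c(0.7, 4),
                              tachycardiaBpm = 100,
                              method = c("periodogram", "welch")) {
  method <- match.arg(method)
  if (is(pulse, "ChannelTraces")) pulse <- posPulse(pulse)
  stopifnot(is(pulse, "PulseSignal"))
  fs <- pulse@fs
  need <- as.integer(floor(latencyS * fs))
  if (length(pulse@h) < need)
    stop(sprintf("signal shorter than the %g s latency (%d < %d samples)",
                 latencyS, length(pulse@h), need))
  x <- pulse@h[seq_len(need)]
  if (stats::sd(x) < 1e-12)
    return(new("HREstimate", hr = NA_real_, latencyS = latencyS,
               tachycardiaFlag = NA, reason = "no_pulsatile_content"))
  x <- bandPass(x, fs, band[1], band[2])

  if (method == "welch") {
    seg <- max(4L, floor(length(x) / 2))
    step <- max(1L, floor(seg / 2))
    starts <- seq(1L, length(x) - seg + 1L, by = step)
    specs <- lapply(starts, function(s0)
      bandSpectrum(x[s0:(s0 + seg - 1L)], fs, band[1], band[2], hann = TRUE))
    mag <- Reduce(`+`, lapply(specs, function(s) s$mag^2)) / length(specs)
    spec <- data.frame(freq = specs[[1]]$freq, mag = sqrt(mag))
  } else {
    spec <- bandSpectrum(x, fs, band[1], band[2], hann = TRUE)
  }
  if (!nrow(spec) || max(spec$mag) < 1e-12)
    return(new("HREstimate", hr = NA_real_, latencyS = latencyS,
               tachycardiaFlag = NA, reason = "no_pulsatile_content"))
  hr <- 60 * spec$freq[which.max(spec$mag)]
  new("HREstimate", hr = hr, latencyS = latencyS,
      tachycardiaFlag = screenTachycardia(hr, tachycardiaBpm))
}

#' Tachycardia screen
#'
#' @param hrBpm heart rate (BPM); vectorized.
#' @param threshold screening threshold, default 100 BPM.
#' @return logical, TRUE when hrBpm is strictly greater than the threshold.
#' @export
screenTachycardia <- function(hrBpm, threshold = 100) hrBpm > threshold
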