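# Shared signal-processing helpers (internal).

# Round half away from zero (base round() rounds half to even, which would
# make ROI bounds depend on parity).
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# Subtract a centered moving-average baseline. Edge values are replicated so
# the baseline is defined over the full trace. For traces shorter than the
# averaging window this degenerates toward mean removal.
detrendMovingAverage <- function(x, fs, windowS = 10) {
  n <- length(x)
  w <- min(round(windowS * fs), n)
  if (w %% 2 == 0) w <- w - 1
  if (w < 3) return(x - mean(x))
  k <- (w - 1) / 2
  xp <- c(rep(x[1], k), x, rep(x[n], k))
  ma <- stats::filter(xp, rep(1 / w, w), sides = 2)
  x - as.numeric(ma[(k + 1):(k + n)])
}

# Edge-safe detrending for peak detection. The usual zero-phase filters and
# moving-average baselines distort the first and last half window, which is
# fatal here: the shortest admissible P2P window carries its two breath peaks
# on the window endpoints. For windows up to `maShortS` seconds a least-squares
# line is subtracted (slow drift is near-linear over such spans); longer
# windows subtract a centered moving-average baseline, whose edge distortion
# is amortized over many interior peaks.
detrendForPeaks <- function(x, fs, maShortS = 15, maWindowS = 10) {
  n <- length(x)
  if (n <= maShortS * fs) {
    t <- seq_len(n)
    return(stats::resid(stats::lm(x ~ t)))
  }
  detrendMovingAverage(x, fs, maWindowS)
}

# Short centered moving-average smoother with edge replication: symmetric
# (no phase shift) and, unlike an IIR filter run forward-backward, free of
# boundary transients that would displace endpoint peaks.
smoothMA <- function(x, fs, widthS = 1 / 3) {
  w <- max(3L, as.integer(round(widthS * fs)))
  if (w %% 2 == 0) w <- w + 1L
  n <- length(x)
  if (w >= n) return(x)
  k <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], k), x, rep(x[n], k))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2)[(k + 1):(k + n)])
}

# Zero-phase low-pass Butterworth. Falls back to the identity when the cutoff
# is at or above Nyquist (nothing to remove).
lowPass <- function(x, fs, cutoffHz, order = 4) {
  wn <- cutoffHz / (fs / 2)
  if (wn >= 1) return(x)
  bf <- signal::butter(order, wn, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Zero-phase band-pass Butterworth.
bandPass <- function(x, fs, lowHz, highHz, order = 4) {
  ny <- fs / 2
  wl <- lowHz / ny
  wh <- min(highHz / ny, 0.999)
  if (wl <= 0) return(lowPass(x, fs, highHz, order))
  bf <- signal::butter(order, c(wl, wh), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# One-sided magnitude spectrum restricted to [fMin, fMax] Hz.
# Returns data.frame(freq, mag). The mean is removed first; an optional Hann
# taper controls leakage for short windows.
bandSpectrum <- function(x, fs, fMin, fMax, hann = FALSE, zeroPadFactor = 1) {
  x <- x - mean(x)
  n <- length(x)
  if (hann) {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    x <- x * w
  }
  nfft <- n * max(1L, as.integer(zeroPadFactor))
  mag <- Mod(stats::fft(c(x, rep(0, nfft - n))))
  freq <- (seq_len(nfft) - 1) * fs / nfft
  keep <- freq >= fMin & freq <= fMax & freq <= fs / 2
  data.frame(freq = freq[keep], mag = mag[keep])
}

# Peak detection by local maxima with a prominence floor and minimum spacing.
# Endpoint maxima are admitted (with a clipped comparison window): a breath
# peak falling exactly on a window boundary still counts, which matters for
# the shortest admissible windows where the first and last samples carry
# consecutive exhalation peaks.
#
# Returns integer indices of kept peaks, in increasing order.
findSignalPeaks <- function(x, fs, minSpacingS, minProminence) {
  n <- length(x)
  k <- max(1L, as.integer(round(minSpacingS * fs / 2)))
  cand <- integer()
  i <- 1L
  while (i <= n) {
    lo <- max(1L, i - k)
    hi <- min(n, i + k)
    win <- x[lo:hi]
    if (x[i] >= max(win)) {
      # collapse plateaus: take the centre of a run of equal maxima
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      cand <- c(cand, as.integer((i + j) %/% 2))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) return(integer())

  prominence <- vapply(cand, function(p) {
    # walk out on each side until a higher sample or the boundary; the base
    # on that side is the minimum encountered. A peak sitting on a signal
    # boundary has no samples on that side: the boundary does not bound the
    # prominence (base -Inf), so endpoint peaks are judged by their interior
    # side alone.
    leftBase <- x[p]
    j <- p
    while (j > 1L && x[j - 1L] <= x[p]) { j <- j - 1L; leftBase <- min(leftBase, x[j]) }
    if (j == 1L) leftBase <- -Inf           # reached the boundary unchallenged
    rightBase <- x[p]
    j <- p
    while (j < n && x[j + 1L] <= x[p]) { j <- j + 1L; rightBase <- min(rightBase, x[j]) }
    if (j == n) rightBase <- -Inf
    x[p] - max(leftBase, rightBase)
  }, numeric(1))
  keep <- cand[prominence >= minProminence & prominence > 0]
  if (length(keep) < 2L) return(keep)

  # enforce minimum spacing, preferring taller peaks
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer()
  minGap <- minSpacingS * fs
  for (p in ord) {
    if (!length(sel) || all(abs(sel - p) >= minGap)) sel <- c(sel, p)
  }
  sort(sel)
}

# Extract a `windowS`-second window starting at `startS`, endpoint
# inclusive: samples with startS <= t <= startS + windowS, i.e.
# floor(windowS*fs) + 1 samples. A window of t_w seconds thus spans
# t in [0, t_w] and contains both endpoints of a breath cycle whose period
# equals the window length. A trace generated as round(duration*fs) samples
# ends one sample short of `duration` seconds; a window requesting exactly
# the full trace is therefore allowed to be that one sample shorter.
windowSamples <- function(nTotal, fs, windowS, startS = 0) {
  i0 <- as.integer(round(startS * fs)) + 1L
  i1 <- i0 + as.integer(floor(windowS * fs))
  if (i1 == nTotal + 1L) i1 <- nTotal
  if (i1 > nTotal) stop(sprintf(
    "window of %g s starting at %g s needs %d samples but the signal has %d",
    windowS, startS, i1 - i0 + 1L, nTotal))
  i0:i1
}
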