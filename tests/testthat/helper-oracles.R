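# Independent oracles, kept deliberately naive and separate from the package
# implementation paths they check.

# Brute-force DFT argmax: explicit trigonometric sums over the Fourier grid
# k/n * fs, restricted to [fMinHz, fMaxHz]. No call into stats::fft or any
# package spectral code.
oracleDftArgmaxBpm <- function(x, fs, fMinHz = 0.08, fMaxHz = 0.7) {
  x <- x - mean(x)
  n <- length(x)
  t <- seq_len(n) - 1
  ks <- seq(0, floor(n / 2))
  freqs <- ks * fs / n
  keep <- freqs >= fMinHz & freqs <= fMaxHz
  mags <- vapply(ks[keep], function(k) {
    ang <- 2 * pi * k * t / n
    sqrt(sum(x * cos(ang))^2 + sum(x * sin(ang))^2)
  }, numeric(1))
  60 * freqs[keep][which.max(mags)]
}

# Hand POS projection matrix multiply: P = [[0, 1, -1], [-2, 1, 1]].
oraclePosProject <- function(m) {
  P <- rbind(c(0, 1, -1), c(-2, 1, 1))
  out <- m %*% t(P)
  list(s1 = out[, 1], s2 = out[, 2])
}
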