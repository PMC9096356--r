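---
title: "Contactless vital-sign estimation: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless vital-sign estimation: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalcam)
```

`vitalcam` estimates three vital signs from camera data alone — forehead skin
temperature from thermal frames, respiratory rate from the facemask-region
thermal oscillation, and heart rate from tri-channel facial reflectance — and
screens each against a clinical threshold (fever, tachypnea > 20 BPM,
tachycardia > 100 BPM). This vignette is the package's own account of the
underlying models, the tunable parameters and why their defaults are what
they are, what the synthetic scene generator does and does not emulate, and
the numerical choices a maintainer would want written down.

## Face geometry

All measurements start from an external face detection: a bounding box
(top-left `(x, y)`, width `w`, height `h`, 0-based pixel coordinates, y
down), the eye-line y coordinate `yEye`, and head pose angles (pitch, yaw)
from a PnP pose solver. Detection itself is out of scope; detections enter
as fixtures (`FaceDetection` objects, or the JSON interchange format).

Two rectangular ROIs are derived:

* **forehead** — `[x, x + w) x [y, yEye)`: the skin patch for temperature
  and heart rate;
* **facemask** — `[x + 0.1 w, x + 0.9 w) x [y + 0.5 h, y + h)`: the lower
  half of the face where a mask sits, for respiration.

ROIs are half-open pixel rectangles; fractional bounds are rounded
half-away-from-zero (base R's `round()` rounds half to even, which would
make ROI edges depend on coordinate parity). With the eye line in the upper
half of the box the two ROIs are disjoint, which the tests assert.

**Distance from the face box.** Subject distance follows an inverse power
law of the bounding-box diagonal, `D = k L^(-p)` with defaults
`k = 140.22`, `p = 1.14` (D in metres, L in pixels) — properties of a
specific camera/optics combination, refittable from `(L, D)` samples with
`fitDistanceModel()` (OLS in log-log space). Because a tilted head
foreshortens the apparent box, the raw diagonal is first pose-corrected:

```
L_corrected = sqrt( (w / cos(yaw))^2 + (h / cos(pitch))^2 )
```

Division (not multiplication) by the cosines is the physically coherent
direction: foreshortening shrinks apparent extent, so the correction must
enlarge it. Angles at or beyond 90° are errors (the face would not be
detectable anyway).

## Thermal compensation without a black body

An IR camera without a co-located black-body reference mis-reads skin
temperature by an amount that grows roughly linearly with subject distance,
with a slope that itself depends (roughly linearly) on the ambient
temperature — the colder the room, the steeper the drop. The package models
the bias of a raw reading `T_IR` as

```
bias(D, T_ambient) = (a T_ambient + b) (D + c) - d
```

and `compensateTemperature()` subtracts it back. The structure (linear in
D; slope linear in ambient) is the modelled physics; the four constants are
camera properties and are always refit from data via
`fitThermalCalibration()`, a three-stage OLS that mirrors the model:
per-ambient bias-vs-distance lines, then slope-vs-ambient, then
intercept-vs-slope (whose coefficients are `c` and `-d`). On noiseless data
from the model family recovery is exact (asserted to 1e-8); when all
per-ambient slopes coincide, `c` and `d` are not separately identifiable
and the fit collapses `c` to 0 with a warning rather than returning an
arbitrary split.

The calibration is trusted over 0.5–5 m; outside that range compensation
extrapolates and warns. Fever screening compares the compensated reading
against a population baseline (mean of a small healthy cohort scanned under
similar conditions) plus a margin, default 0.5 °C, strict inequality.

The ROI statistic for "skin temperature" is the mean by default; `max` and
`p95` are available because fever-screening practice sometimes prefers
hot-spot readings. Nothing downstream depends on the choice.

## Respiratory rate from the facemask

Respiration exchanges heat with the environment (`respiratoryHeatLoss()`
implements the standard convective + evaporative estimate
`0.0014 M (34 - T_a) + 0.0173 M (5.87 - P_a)`); a facemask traps part of
that exchange in a microenvironment, so the mask-ROI mean temperature
oscillates with breathing — exhalation peaks, inhalation troughs. That
per-frame mean, min-max normalized to [0, 1], is the breathing signal. A
constant trace cannot be normalized and comes back raw with a `degenerate`
flag; detection dropouts are gap-filled from the previous ROI for at most 5
frames, beyond which extraction fails loudly rather than inventing data.

Two estimators:

* **P2P** (`rrPeakToPeak()`): mean inter-peak interval on the detrended
  signal, converted to BPM. Its minimum window is one full period of the
  slowest rate of interest — 10 s for 6 BPM — so it is the quick-screening
  method. The two peaks bounding a full period fall on the window
  *endpoints*, which drives several numerical choices below.
* **FFT** (`rrSpectral()`): magnitude-spectrum argmax over a physiological
  band. The frequency resolution is `1/t_w` Hz (60/t_w BPM), so resolving
  3 BPM requires a 20 s window — the continuous-monitoring method.

The Nyquist ceiling `60 fs / 2` BPM (900 BPM at 30 Hz) never binds for
human rates.

Numerical choices, all configurable:

* **Band** 0.08–0.7 Hz (≈5–42 BPM) for the spectral argmax: excludes
  baseline drift below and cardiac/harmonic content above.
* **Low-pass** before the FFT: zero-phase 4th-order Butterworth at 1.0 Hz —
  comfortably above the band, well below cardiac frequencies.
* **Edge-safe preprocessing for P2P**: windows up to 15 s are detrended by
  subtracting an OLS line (slow drift is near-linear over such spans) and
  smoothed by a short (~0.33 s) centered moving average with edge
  replication. Zero-phase IIR filtering and moving-average baselines were
  rejected here because their boundary transients displace or erase
  endpoint peaks, which the shortest admissible window depends on. Longer
  windows use a 10 s centered moving-average baseline, whose edge
  distortion is amortized over many interior peaks.
* **Peak detection**: local maxima with minimum spacing `60/rr_max` s
  (rr_max = 42 BPM) and minimum topographic prominence 0.2 × the IQR of
  the preprocessed window. Endpoint maxima are admitted, with the signal
  boundary treated as non-binding for prominence (a walk that reaches the
  boundary unchallenged contributes base −Inf). Fewer than two peaks is an
  *indeterminate* result — `NA` plus a reason code, never a number.
* **Off-bin rates**: the spectral estimator reports the nearest bin. An
  optional 4× zero-padding refinement exists but is off by default so the
  reported resolution matches the window length. A spectral peak holding
  under 40% of the band energy (peak bin ± 1) is flagged low-confidence;
  an empty band is indeterminate.

Tachypnea is flagged strictly above 20 BPM.

## Heart rate by plane-orthogonal-to-skin (POS)

The blood-volume pulse modulates skin reflectance by roughly 1%, strongest
around 500–600 nm (green). Three monochrome channels centred at 630, 532
and 465 nm are reduced to their forehead-ROI means, giving traces
`(r, g, b)`. Under the dichromatic model each channel is its stationary
mean times `(1 + pulsatile + specular)` where the specular/motion part is
common-mode across channels. Per sliding window:

1. **Temporal normalization**: divide each channel by its window mean
   (means become exactly 1; any global gain cancels — the pipeline is
   provably invariant to intensity scaling, asserted end-to-end).
2. **Projection**: `S1 = g - b`, `S2 = -2r + g + b` — the two rows of
   `P = [[0, 1, -1], [-2, 1, 1]]`. Both rows sum to zero, so the
   common-mode component is annihilated exactly.
3. **Combination**: `h = S1 + (σ(S1)/σ(S2)) S2`. Equal-variance in-phase
   content doubles; antiphase content cancels. `σ(S2) = 0` falls back to
   `h = S1` with a warning.

Windows are 1.6 s (48 samples at 30 Hz) with overlap-add of the zero-mean
window waveforms — the short window keeps the normalization local, which is
what buys motion robustness. Whether to run one global window or sliding
windows is a genuine design fork; the sliding/overlap-add convention was
chosen because the method's robustness argument rests on local
normalization.

`estimateHeartRate()` consumes the first `latencyS` seconds (default 10 s,
matching the quick respiratory screen, so a full quick screen needs only
10 s of recording), band-passes to 0.7–4 Hz (42–240 BPM), and takes the
Hann-tapered periodogram argmax; Welch averaging is available for noisier
deployments. At 10 s latency the spectral bin is 6 BPM; accuracy improves
with latency, and the tests assert the 20 s error never exceeds the 10 s
error on matched scenes. Tachycardia is flagged strictly above 100 BPM.

## The synthetic scene generator

Every stage is validated against scenes with known ground truth, generated
from a single seeded RNG per call (fixed seed ⇒ bit-identical output):

* **Breathing traces**: sinusoid at the true rate (optional fast-exhale
  skew), amplitude 0.3 °C — the mask oscillation amplitude is not a
  published physical constant, so it is an explicit parameter with a
  plausible default — plus slow sinusoidal drift (≤ 0.02 Hz) and i.i.d.
  Gaussian noise. Default phase puts an exhalation peak at t = 0.
* **Thermal sequences**: ambient background, skin-temperature forehead,
  breathing-modulated mask region, all offset by the bias model and
  per-pixel noise; detection fixtures whose geometry inverts the distance
  power law exactly.
* **Reflectance traces**: dichromatic model with pulsatile unit vector
  (0.33, 0.77, 0.53)/‖·‖ (strongest in green), pulsatile amplitude 1%,
  and a two-tone low-frequency common-mode disturbance as the
  specular/motion surrogate.

The generator's default bias parameters (`defaultThermalBias()`: slope
−0.24 °C/m at 19 °C ambient shrinking to −0.08 °C/m at 28 °C, distance
offset 0.5 m) were chosen once so that the *uncompensated* error over the
2–5 m × 19–28 °C operating envelope peaks at about 1.3 °C in the
cold-room/far corner — the error structure a black-body-free IR camera
shows in the field.

Two honesty notes. First, the generator draws its bias from the same
parametric family the calibration fits: bias-compensation round trips are
therefore well-posed by construction, and passing them shows correct
inversion, not that the linear-slope model captures every real camera.
Second, the generator does not attempt photorealism, radiometric camera
simulation, detector failure modes, or mask-fabric physics beyond the
periodic-temperature abstraction — so passing tests demonstrate the
estimators' signal-processing correctness under the stated signal model,
not clinical performance on human subjects.

## Validation design and problem sizes

The test suite's synthetic experiments use, as the package's chosen
designs:

* **Respiration**: 30 seeded traces, true RR uniform in 6–35 BPM, 30 Hz,
  30 s, noise s.d. 0.1 × the oscillation amplitude, drift on. Bounds
  asserted: FFT @ 30 s MAE ≤ 1.6 BPM; P2P @ 10 s MAE ≤ 2.1 BPM; 95% of
  estimates within max(one bin, 2 BPM); rank correlation between |error|
  and true rate below 0.5 (errors carry no rate-dependent structure).
* **Temperature**: 4 distances × 4 ambients × 10 readings, sensor noise
  0.1 °C; calibration fitted on half the readings, evaluated on the held-out
  half. Bounds: compensated MAE ≤ 0.3 °C; residual distance slope of
  compensated readings < 0.02 °C/m; compensation strictly beats raw
  readings.
* **Heart rate**: 30 seeded traces, true HR uniform in 45–150 BPM, 10 s at
  30 Hz, specular disturbance 5× the pulsatile amplitude, channel noise
  0.5× the pulsatile amplitude (ROI-mean noise is heavily suppressed by
  spatial averaging, so sub-pulsatile noise is the realistic regime).
  Bounds: MAE ≤ 8 BPM at 10 s latency; exact intensity-scaling invariance;
  noiseless recovery within one spectral bin across 45–150 BPM.
* **Oracles**: the spectral RR path is asserted equal to a brute-force
  trigonometric DFT argmax; the POS projection equal to a hand matrix
  multiply; the calibration fit exact on noiseless data.

`scripts/acceptance.R` re-runs the three stochastic experiments from
scratch at a caller-supplied seed and writes the measured MAEs as JSON.

## Known limitations

* The distance power-law constants and the thermal-bias constants are
  camera-specific; deploying on new hardware requires refitting both.
* P2P's endpoint-peak convention can, on monotone window edges, accept a
  boundary sample as a peak; detrending makes this rare, but pathological
  drift shapes inside a 10 s window can still bias the interval mean.
* The spectral estimators report nearest-bin rates; at 10 s latency the
  HR bin is 6 BPM, which is the dominant error term near the bound.
* Indeterminate results (flat signals, too few peaks, empty bands) are
  first-class outcomes; pipelines consuming reports must handle explicit
  nulls with reason codes.
* Heart-rate validation covers the stated reflectance model only; lighting
  spectra, skin-tone variation and large motion are outside the generator's
  scope.
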