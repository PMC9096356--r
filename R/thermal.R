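#' Summarize ROI temperature
#'
#' Reduce the pixels of a thermal frame inside an ROI to a single skin
#' temperature. The statistic defaults to the arithmetic mean; the maximum or
#' the 95th percentile can be selected for fever-screening setups that prefer
#' hot-spot readings.
#'
#' @param frame numeric matrix of temperatures (degC), [row, col].
#' @param roi an [ROI-class] inside the frame.
#' @param statistic "mean" (default), "max" or "p95".
#' @return numeric(1), degrees Celsius.
#' @export
roiTemperature <- function(frame, roi, statistic = c("mean", "max", "p95")) {
  statistic <- match.arg(statistic)
  px <- roiPixels(frame, roi)
  switch(statistic,
         mean = mean(px),
         max = max(px),
         p95 = unname(stats::quantile(px, 0.95, type = 7)))
}

#' Compensate a skin-temperature reading for ambient and distance
#'
#' An IR camera without a black-body reference reads low by an amount that
#' grows with subject distance, with a slope that depends on the ambient
#' temperature. Compensation subtracts the fitted bias back:
#'
#'   T_compensated = T_IR - (a*T_ambient + b) * (D + c) + d
#'
#' With the all-zero calibration this is the identity. The operation is
#' affine in T_IR with unit coefficient, so it never distorts temperature
#' differences between subjects measured under identical conditions.
#'
#' @param tIR raw ROI temperature (degC); vectorized.
#' @param ambient an [AmbientConditions-class], or the ambient temperature in
#'   degC as a plain number.
#' @param dM subject distance in metres (> 0); vectorized (recycled with tIR).
#' @param calib a [ThermalCalibration-class].
#' @param calibratedRange distances (m) the calibration is trusted over;
#'   outside it a warning is emitted and the model extrapolates.
#' @return Compensated temperature(s), degC.
#' @seealso [fitThermalCalibration()], [screenFever()]
#' @export
compensateTemperature <- function(tIR, ambient, dM, calib,
                                  calibratedRange = c(0.5, 5)) {
  stopifnot(is(calib, "ThermalCalibration"))
  tAmb <- if (is(ambient, "AmbientConditions")) ambient@tAmbient else ambient
  if (any(dM <= 0)) stop("'dM' must be > 0")
  if (any(dM < calibratedRange[1] | dM > calibratedRange[2]))
    warning(sprintf("distance outside the calibrated range [%g, %g] m; extrapolating",
                    calibratedRange[1], calibratedRange[2]))
  slope <- calib@a * tAmb + calib@b
  tIR - slope * (dM + calib@c) + calib@d
}

#' Predicted thermal bias of a raw reading
#'
#' The modelled measurement bias `(a*Ta + b)*(D + c) - d`, i.e. what the
#' camera reads minus the true skin temperature. Used by the synthetic
#' generator and by diagnostics; [compensateTemperature()] subtracts exactly
#' this quantity.
#'
#' @param calib a [ThermalCalibration-class].
#' @param dM distance (m); vectorized.
#' @param tAmbient ambient temperature (degC); vectorized.
#' @return Bias in degC.
#' @export
thermalBias <- function(calib, dM, tAmbient) {
  stopifnot(is(calib, "ThermalCalibration"))
  (calib@a * tAmbient + calib@b) * (dM + calib@c) - calib@d
}

#' Fit the ambient/distance thermal calibration
#'
#' Three-stage ordinary least squares mirroring the structure of the bias
#' model:
#'
#' 1. per ambient level, regress the bias (T_IR - true temperature) on
#'    distance: slope s_k and intercept i_k;
#' 2. regress s_k on the ambient temperature: coefficients (a, b);
#' 3. regress i_k on s_k: i = c*s - d gives the distance offset c and global
#'    offset d.
#'
#' On noiseless data drawn from the model family the recovery is exact. When
#' the per-ambient slopes are (numerically) identical, c and d are not
#' separately identifiable; c is then set to 0 and the mean intercept is
#' absorbed into d, with a warning.
#'
#' @param samples data.frame with columns `t_ir` (measured, degC),
#'   `true_temp` (reference, degC), `t_ambient` (degC), `d_m` (m). At least
#'   two ambient levels with at least two distinct distances each.
#' @return A [ThermalCalibration-class] with per-stage R-squared diagnostics.
#' @examples
#' truth <- defaultThermalBias()
#' grid <- expand.grid(d_m = 2:5, t_ambient = c(19, 21, 24, 28))
#' grid$true_temp <- 34
#' grid$t_ir <- 34 + thermalBias(truth, grid$d_m, grid$t_ambient)
#' fitThermalCalibration(grid)
#' @export
fitThermalCalibration <- function(samples) {
  req <- c("t_ir", "true_temp", "t_ambient", "d_m")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("missing columns in 'samples': ", paste(miss, collapse = ", "))
  samples <- as.data.frame(samples)
  samples$bias <- samples$t_ir - samples$true_temp
  # noiseless inputs produce exact fits; summary.lm warns about them
  rsq <- function(fit) suppressWarnings(summary(fit)$r.squared)

  levels_ <- sort(unique(samples$t_ambient))
  if (length(levels_) < 2L)
    stop("calibration needs at least two ambient levels; only one present ",
         "(the ambient dependence of the slope is unidentifiable)")
  perAmb <- lapply(levels_, function(ta) {
    s <- samples[samples$t_ambient == ta, ]
    if (length(unique(s$d_m)) < 2L)
      stop(sprintf("ambient level %g degC has fewer than two distinct distances", ta))
    fit <- stats::lm(bias ~ d_m, data = s)
    data.frame(t_ambient = ta,
               slope = unname(stats::coef(fit)["d_m"]),
               intercept = unname(stats::coef(fit)["(Intercept)"]),
               r2 = rsq(fit))
  })
  perAmb <- do.call(rbind, perAmb)

  fitSlope <- stats::lm(slope ~ t_ambient, data = perAmb)
  a <- unname(stats::coef(fitSlope)["t_ambient"])
  b <- unname(stats::coef(fitSlope)["(Intercept)"])

  if (stats::sd(perAmb$slope) < 1e-12) {
    warning("per-ambient slopes are identical; 'c' is unidentifiable and set to 0")
    cOff <- 0
    dOff <- -mean(perAmb$intercept)
    r2Off <- NA_real_
  } else {
    fitOff <- stats::lm(intercept ~ slope, data = perAmb)
    cOff <- unname(stats::coef(fitOff)["slope"])
    dOff <- -unname(stats::coef(fitOff)["(Intercept)"])
    r2Off <- rsq(fitOff)
  }

  r2 <- c(distance = mean(perAmb$r2),
          slope_vs_ambient = rsq(fitSlope),
          offsets = r2Off)
  thermalCalibration(a = a, b = b, c = cOff, d = dOff,
                     ambientRange = range(samples$t_ambient), r2 = r2,
                     fittedOn = sprintf("%d samples, %d ambient levels",
                                        nrow(samples), length(levels_)))
}

#' Fever screen
#'
#' Flags a compensated skin temperature strictly above a population baseline
#' plus a margin. The baseline is typically the mean compensated reading of a
#' small cohort of healthy subjects scanned under similar ambient conditions
#' (see [baselineFromCohort()]).
#'
#' @param tCompensated compensated temperature (degC); vectorized.
#' @param baseline population baseline (degC).
#' @param margin margin above baseline (degC), default 0.5.
#' @return logical, TRUE when tCompensated > baseline + margin.
#' @export
screenFever <- function(tCompensated, baseline, margin = 0.5)
  tCompensated > baseline + margin

#' Population baseline from a cohort scan
#'
#' @param tCompensated vector of compensated readings of known-healthy
#'   subjects (degC).
#' @return numeric(1), their mean.
#' @export
baselineFromCohort <- function(tCompensated) {
  if (!length(tCompensated)) stop("empty cohort")
  mean(tCompensated)
}
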