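# Readers and writers for the on-disk interchange formats: traces as CSV,
# detections / calibrations / reports as JSON, thermal sequences as 16-bit
# multi-frame TIFF with a JSON sidecar. All schemas carry a version tag.

SCHEMA_VERSION <- "1"

checkColumns <- function(df, expected, what, path) {
  extra <- setdiff(names(df), expected)
  if (length(extra))
    stop(sprintf("unknown column(s) in %s '%s': %s", what, path,
                 paste(extra, collapse = ", ")))
  miss <- setdiff(expected, names(df))
  if (length(miss))
    stop(sprintf("missing column(s) in %s '%s': %s", what, path,
                 paste(miss, collapse = ", ")))
}

checkMonotonicTime <- function(t, path) {
  if (any(diff(t) <= 0))
    stop(sprintf("non-monotonic 't_s' in '%s' (line %d)",
                 path, which(diff(t) <= 0)[1] + 1L))
}

#' Write / read a breathing trace as CSV
#'
#' Columns: `t_s`, `value`. The sampling rate is recovered from the median
#' time step on read; non-monotonic time or unexpected columns are schema
#' errors.
#'
#' @param sig a [BreathSignal-class].
#' @param path file path.
#' @return `readTraceCSV` returns a [BreathSignal-class];
#'   `writeTraceCSV` returns `path` invisibly.
#' @export
writeTraceCSV <- function(sig, path) {
  stopifnot(is(sig, "BreathSignal"))
  t <- sig@t0 + (seq_along(sig@values) - 1) / sig@fs
  utils::write.csv(data.frame(t_s = t, value = sig@values), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceCSV
#' @export
readTraceCSV <- function(path) {
  df <- utils::read.csv(path)
  checkColumns(df, c("t_s", "value"), "trace CSV", path)
  checkMonotonicTime(df$t_s, path)
  fs <- 1 / stats::median(diff(df$t_s))
  breathSignal(df$value, fs, t0 = df$t_s[1],
               normalized = all(df$value >= 0 & df$value <= 1))
}

#' Write / read tri-channel traces as CSV
#'
#' Columns: `t_s`, `r`, `g`, `b`.
#'
#' @param traces a [ChannelTraces-class].
#' @param path file path.
#' @return `readChannelTracesCSV` returns a [ChannelTraces-class].
#' @export
writeChannelTracesCSV <- function(traces, path) {
  stopifnot(is(traces, "ChannelTraces"))
  t <- (seq_len(nSamples(traces)) - 1) / traces@fs
  utils::write.csv(cbind(data.frame(t_s = t), as.data.frame(traces@traces)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeChannelTracesCSV
#' @export
readChannelTracesCSV <- function(path) {
  df <- utils::read.csv(path)
  checkColumns(df, c("t_s", "r", "g", "b"), "channel-trace CSV", path)
  checkMonotonicTime(df$t_s, path)
  channelTraces(df$r, df$g, df$b, fs = 1 / stats::median(diff(df$t_s)))
}

#' Write / read per-frame detections as JSON
#'
#' Records `{frame, x, y, w, h, y_eye, pitch_deg, yaw_deg}` under a
#' versioned envelope. Frames without a detection are simply absent and read
#' back as NULL entries.
#'
#' @param dets list of [FaceDetection-class] (NULL entries allowed).
#' @param path file path.
#' @param nFrames total frame count on read (defaults to the largest frame
#'   index present).
#' @return `readDetectionsJSON` returns a list of [FaceDetection-class] /
#'   NULL of length `nFrames`.
#' @export
writeDetectionsJSON <- function(dets, path) {
  recs <- lapply(seq_along(dets), function(i) {
    d <- dets[[i]]
    if (is.null(d)) return(NULL)
    list(frame = i, x = d@box@x, y = d@box@y, w = d@box@w, h = d@box@h,
         y_eye = d@yEye, pitch_deg = d@pitch, yaw_deg = d@yaw)
  })
  recs <- Filter(Negate(is.null), recs)
  jsonlite::write_json(list(version = SCHEMA_VERSION, n_frames = length(dets),
                            detections = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDetectionsJSON
#' @export
readDetectionsJSON <- function(path, nFrames = NULL) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$detections)) stop(sprintf("'%s' has no 'detections' field", path))
  if (is.null(nFrames)) nFrames <- obj$n_frames
  dets <- vector("list", nFrames)
  for (r in obj$detections) {
    req <- c("frame", "x", "y", "w", "h", "y_eye", "pitch_deg", "yaw_deg")
    miss <- setdiff(req, names(r))
    if (length(miss))
      stop(sprintf("detection record in '%s' missing field(s): %s",
                   path, paste(miss, collapse = ", ")))
    dets[[r$frame]] <- faceDetection(boundingBox(r$x, r$y, r$w, r$h),
                                     yEye = r$y_eye, pitch = r$pitch_deg,
                                     yaw = r$yaw_deg)
  }
  dets
}

#' Write / read a thermal calibration as JSON
#'
#' Fields `{a, b, c_m, d, ambient_range, fitted_on, r2, version}`.
#'
#' @param calib a [ThermalCalibration-class].
#' @param path file path.
#' @return `readCalibrationJSON` returns a [ThermalCalibration-class].
#' @export
writeCalibrationJSON <- function(calib, path) {
  stopifnot(is(calib, "ThermalCalibration"))
  jsonlite::write_json(list(version = SCHEMA_VERSION, a = calib@a, b = calib@b,
                            c_m = calib@c, d = calib@d,
                            ambient_range = calib@ambientRange,
                            fitted_on = calib@fittedOn,
                            r2 = as.list(calib@r2)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibrationJSON
#' @export
readCalibrationJSON <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("a", "b", "c_m", "d")
  miss <- setdiff(req, names(o))
  if (length(miss))
    stop(sprintf("calibration '%s' missing field(s): %s", path,
                 paste(miss, collapse = ", ")))
  r2 <- if (length(o$r2)) unlist(o$r2) else numeric()
  thermalCalibration(a = o$a, b = o$b, c = o$c_m, d = o$d,
                     ambientRange = if (!is.null(o$ambient_range)) o$ambient_range else c(19, 28),
                     r2 = r2,
                     fittedOn = if (!is.null(o$fitted_on)) o$fitted_on else "unspecified")
}

#' Write / read a thermal sequence as 16-bit TIFF
#'
#' Frames are linearly quantized to 16 bits over their global range and
#' written as a multi-frame TIFF; the affine dequantization (t_min, t_max),
#' frame rate and t0 go to a JSON sidecar at `<path>.json`. Quantization
#' error is bounded by range/65535 (sub-millikelvin for facial scenes).
#'
#' @param seq a [ThermalSequence-class].
#' @param path TIFF file path.
#' @return `readThermalSequenceTIFF` returns a [ThermalSequence-class].
#' @export
writeThermalSequenceTIFF <- function(seq, path) {
  stopifnot(is(seq, "ThermalSequence"))
  tMin <- min(seq@frames)
  tMax <- max(seq@frames)
  span <- if (tMax > tMin) tMax - tMin else 1
  frames <- lapply(seq_len(nSamples(seq)), function(i)
    (seq@frames[, , i] - tMin) / span)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(version = SCHEMA_VERSION, fs = seq@fs, t0 = seq@t0,
                            t_min = tMin, t_max = tMax),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeThermalSequenceTIFF
#' @export
readThermalSequenceTIFF <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  span <- if (meta$t_max > meta$t_min) meta$t_max - meta$t_min else 1
  arr <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]] * span + meta$t_min
  thermalSequence(arr, fs = meta$fs, t0 = meta$t0)
}

rrToList <- function(rr) {
  if (is.null(rr)) return(NULL)
  list(rr_bpm = if (is.na(rr@rr)) NULL else rr@rr,
       method = rr@method, window_s = rr@windowS,
       tachypnea_flag = if (is.na(rr@tachypneaFlag)) NULL else rr@tachypneaFlag,
       low_confidence = rr@lowConfidence,
       reason = if (nzchar(rr@reason)) rr@reason else NULL)
}

rrFromList <- function(o) {
  if (is.null(o)) return(NULL)
  new("RREstimate",
      rr = if (is.null(o$rr_bpm)) NA_real_ else o$rr_bpm,
      method = o$method, windowS = o$window_s,
      tachypneaFlag = if (is.null(o$tachypnea_flag)) NA else o$tachypnea_flag,
      lowConfidence = isTRUE(o$low_confidence),
      reason = if (is.null(o$reason)) "" else o$reason)
}

#' Write / read a vitals report as JSON
#'
#' Serializes the full screening report. Indeterminate estimates appear as
#' explicit nulls with a reason code; absent stages as nulls with their
#' reason under `reasons`. `read(write(x))` reproduces the report.
#'
#' @param report a [VitalsReport-class].
#' @param path file path.
#' @return `readVitalsReportJSON` returns a [VitalsReport-class].
#' @export
writeVitalsReportJSON <- function(report, path) {
  stopifnot(is(report, "VitalsReport"))
  tp <- report@temperature
  hr <- report@hr
  obj <- list(
    version = SCHEMA_VERSION,
    subject_id = report@subjectId,
    mode = report@mode,
    timestamp = report@timestamp,
    temperature = if (is.null(tp)) NULL else
      list(t_ir = tp@tIR, t_compensated = tp@tCompensated, d_m = tp@dM,
           t_ambient = tp@tAmbient, fever_flag = tp@feverFlag),
    rr = rrToList(report@rr),
    rr_series = lapply(report@rrSeries, rrToList),
    hr = if (is.null(hr)) NULL else
      list(hr_bpm = if (is.na(hr@hr)) NULL else hr@hr,
           latency_s = hr@latencyS,
           tachycardia_flag = if (is.na(hr@tachycardiaFlag)) NULL else hr@tachycardiaFlag,
           reason = if (nzchar(hr@reason)) hr@reason else NULL),
    reasons = as.list(report@reasons))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeVitalsReportJSON
#' @export
readVitalsReportJSON <- function(path) {
  o <- jsonlite::read_json(path)
  tp <- if (is.null(o$temperature)) NULL else
    new("TemperatureReading", tIR = o$temperature$t_ir,
        tCompensated = o$temperature$t_compensated, dM = o$temperature$d_m,
        tAmbient = o$temperature$t_ambient, feverFlag = o$temperature$fever_flag)
  hr <- if (is.null(o$hr)) NULL else
    new("HREstimate",
        hr = if (is.null(o$hr$hr_bpm)) NA_real_ else o$hr$hr_bpm,
        latencyS = o$hr$latency_s,
        tachycardiaFlag = if (is.null(o$hr$tachycardia_flag)) NA else o$hr$tachycardia_flag,
        reason = if (is.null(o$hr$reason)) "" else o$hr$reason)
  reasons <- unlist(o$reasons)
  if (is.null(reasons)) reasons <- character()
  new("VitalsReport", subjectId = o$subject_id, temperature = tp,
      rr = rrFromList(o$rr), hr = hr, mode = o$mode,
      rrSeries = lapply(o$rr_series, rrFromList),
      reasons = reasons, timestamp = o$timestamp)
}

#' Append a vitals report to a CSV log
#'
#' One row per report with the flat columns timestamp, subject_id, mode,
#' t_ir, t_compensated, t_ambient, d_m, fever_flag, rr_bpm, rr_method,
#' rr_window_s, tachypnea_flag, hr_bpm, hr_latency_s, tachycardia_flag.
#' Missing/indeterminate fields are NA.
#'
#' @param report a [VitalsReport-class].
#' @param path CSV path; the header is written when the file does not exist.
#' @return `path`, invisibly.
#' @export
appendVitalsReportCSV <- function(report, path) {
  stopifnot(is(report, "VitalsReport"))
  tp <- report@temperature
  rr <- report@rr
  hr <- report@hr
  row <- data.frame(
    timestamp = report@timestamp,
    subject_id = report@subjectId,
    mode = report@mode,
    t_ir = if (is.null(tp)) NA_real_ else tp@tIR,
    t_compensated = if (is.null(tp)) NA_real_ else tp@tCompensated,
    t_ambient = if (is.null(tp)) NA_real_ else tp@tAmbient,
    d_m = if (is.null(tp)) NA_real_ else tp@dM,
    fever_flag = if (is.null(tp)) NA else tp@feverFlag,
    rr_bpm = if (is.null(rr)) NA_real_ else rr@rr,
    rr_method = if (is.null(rr)) NA_character_ else rr@method,
    rr_window_s = if (is.null(rr)) NA_real_ else rr@windowS,
    tachypnea_flag = if (is.null(rr)) NA else rr@tachypneaFlag,
    hr_bpm = if (is.null(hr)) NA_real_ else hr@hr,
    hr_latency_s = if (is.null(hr)) NA_real_ else hr@latencyS,
    tachycardia_flag = if (is.null(hr)) NA else hr@tachycardiaFlag)
  utils::write.table(row, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
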