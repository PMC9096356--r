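#' Forehead region of interest
#'
#' The forehead ROI spans the full width of the facial bounding box from its
#' top edge down to the eye line: top-left corner (x, y), bottom-right corner
#' (x + w, yEye). It is the source of the skin-temperature reading (thermal
#' frames) and of the tri-channel reflectance traces (heart rate).
#'
#' Fractional bounds are rounded half-away-from-zero to integer pixels; the
#' resulting rectangle is half-open ([ROI-class]).
#'
#' @param det a [FaceDetection-class].
#' @return An [ROI-class].
#' @seealso [maskROI()]
#' @examples
#' foreheadROI(faceDetection(x = 10, y = 20, w = 100, h = 120, yEye = 60))
#' @export
foreheadROI <- function(det) {
  stopifnot(is(det, "FaceDetection"))
  b <- det@box
  x0 <- roundHalfAway(b@x); x1 <- roundHalfAway(b@x + b@w)
  y0 <- roundHalfAway(b@y); y1 <- roundHalfAway(det@yEye)
  if (y1 <= y0)
    stop("degenerate forehead ROI: eye line at or above the box top (invalid landmarks)")
  new("ROI", x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

#' Facemask region of interest
#'
#' The mask ROI covers the lower half of the face where a facemask sits:
#' top-left corner (x + 0.1 w, y + 0.5 h), bottom-right corner
#' (x + 0.9 w, y + h). Its mean temperature over time is the raw breathing
#' signal. Fractional bounds are rounded half-away-from-zero.
#'
#' @param det a [FaceDetection-class].
#' @return An [ROI-class].
#' @seealso [foreheadROI()], [extractBreathSignal()]
#' @examples
#' maskROI(faceDetection(x = 0, y = 0, w = 100, h = 100, yEye = 40))
#' @export
maskROI <- function(det) {
  stopifnot(is(det, "FaceDetection"))
  b <- det@box
  if (b@w < 3 || b@h < 2)
    stop("bounding box too small for a mask ROI (needs at least 3 x 2 px)")
  x0 <- roundHalfAway(b@x + 0.1 * b@w); x1 <- roundHalfAway(b@x + 0.9 * b@w)
  y0 <- roundHalfAway(b@y + 0.5 * b@h); y1 <- roundHalfAway(b@y + b@h)
  if (x1 <= x0 || y1 <= y0)
    stop("bounding box too small for a mask ROI after rounding")
  new("ROI", x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

#' Pose-corrected bounding-box diagonal
#'
#' A tilted head foreshortens the apparent bounding box: yaw shrinks the
#' width by cos(yaw) and pitch shrinks the height by cos(pitch). The
#' corrected diagonal undoes the foreshortening before the diagonal is
#' converted to a distance:
#'
#'   L_corrected = sqrt( (w / cos(yaw))^2 + (h / cos(pitch))^2 )
#'
#' Angles are taken in degrees at the interface.
#'
#' @param det a [FaceDetection-class].
#' @return numeric(1), the corrected diagonal in pixels.
#' @seealso [distanceFromDiagonal()]
#' @export
correctedDiagonal <- function(det) {
  stopifnot(is(det, "FaceDetection"))
  if (abs(det@pitch) >= 90 || abs(det@yaw) >= 90)
    stop("pose angles must be below 90 degrees in magnitude (cos <= 0)")
  cy <- cos(det@yaw * pi / 180)
  cp <- cos(det@pitch * pi / 180)
  sqrt((det@box@w / cy)^2 + (det@box@h / cp)^2)
}

#' Monocular distance from the face-box diagonal
#'
#' Subject distance follows a calibrated inverse power law of the
#' (pose-corrected) bounding-box diagonal:
#'
#'   D = k * L^(-p),   defaults k = 140.22, p = 1.14  (D in metres, L in px)
#'
#' Larger faces are closer; the relationship is strictly decreasing in L.
#' The constants are calibration properties of a specific camera and can be
#' overridden or refit with [fitDistanceModel()].
#'
#' @param L the corrected diagonal in pixels (> 0); vectorized.
#' @param k,p power-law constants.
#' @return Distance(s) in metres.
#' @examples
#' distanceFromDiagonal(76.4)  # ~1 m
#' distanceFromDiagonal(50)    # ~1.62 m
#' @export
distanceFromDiagonal <- function(L, k = 140.22, p = 1.14) {
  if (any(L <= 0)) stop("'L' must be > 0")
  k * L^(-p)
}

#' Invert the distance power law
#'
#' Diagonal a face box would have at a given distance: L = (k / D)^(1/p).
#' Exact inverse of [distanceFromDiagonal()]; used by the synthetic detection
#' generator.
#'
#' @param D distance in metres (> 0); vectorized.
#' @param k,p power-law constants.
#' @return Diagonal(s) in pixels.
#' @export
diagonalFromDistance <- function(D, k = 140.22, p = 1.14) {
  if (any(D <= 0)) stop("'D' must be > 0")
  (k / D)^(1 / p)
}

#' Refit the distance power law
#'
#' Ordinary least squares of log(D) on log(L): the power law is linear in
#' log-log space. Useful when deploying with a camera other than the one the
#' default constants were calibrated for.
#'
#' @param L diagonals (px).
#' @param D matching distances (m).
#' @return list(k, p, r2).
#' @export
fitDistanceModel <- function(L, D) {
  if (length(L) != length(D) || length(L) < 2L)
    stop("need at least two (L, D) pairs")
  if (any(L <= 0) || any(D <= 0)) stop("'L' and 'D' must be positive")
  fit <- stats::lm(log(D) ~ log(L))
  list(k = exp(unname(stats::coef(fit)[1])),
       p = -unname(stats::coef(fit)[2]),
       r2 = summary(fit)$r.squared)
}

#' Estimate subject distance from a detection
#'
#' Convenience composition: pose-correct the diagonal, then apply the power
#' law.
#'
#' @param det a [FaceDetection-class].
#' @param k,p power-law constants, see [distanceFromDiagonal()].
#' @return list(dM, lPx, lCorrectedPx): the distance in metres, the raw and
#'   the pose-corrected diagonal in pixels.
#' @export
estimateDistance <- function(det, k = 140.22, p = 1.14) {
  lRaw <- sqrt(det@box@w^2 + det@box@h^2)
  lCor <- correctedDiagonal(det)
  list(dM = distanceFromDiagonal(lCor, k, p), lPx = lRaw, lCorrectedPx = lCor)
}

# Is `roi` contained in a frame of nrow x ncol pixels?
roiInFrame <- function(roi, nRow, nCol)
  roi@x0 >= 0 && roi@y0 >= 0 && roi@x1 <= nCol && roi@y1 <= nRow

# Pixel values of a frame (matrix, [row, col]) inside a half-open ROI.
roiPixels <- function(frame, roi) {
  if (!roiInFrame(roi, nrow(frame), ncol(frame)))
    stop(sprintf("ROI [%g,%g)x[%g,%g) lies outside the %d x %d frame",
                 roi@x0, roi@x1, roi@y0, roi@y1, nrow(frame), ncol(frame)))
  frame[(roi@y0 + 1):roi@y1, (roi@x0 + 1):roi@x1, drop = FALSE]
}
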