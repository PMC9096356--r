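test_that("forehead ROI spans the box width from its top to the eye line", {
  det <- faceDetection(x = 10, y = 20, w = 100, h = 120, yEye = 60)
  roi <- foreheadROI(det)
  expect_equal(c(roi@x0, roi@y0, roi@x1, roi@y1), c(10, 20, 110, 60))

  # minimal valid box: area 1 px
  tiny <- foreheadROI(faceDetection(x = 0, y = 0, w = 1, h = 2, yEye = 1))
  expect_equal(c(tiny@x0, tiny@y0, tiny@x1, tiny@y1), c(0, 0, 1, 1))

  # eye line at the box top leaves an empty forehead
  expect_error(faceDetection(x = 10, y = 20, w = 100, h = 120, yEye = 20),
               "yEye")
})

test_that("mask ROI applies the 0.1/0.5/0.9/1.0 box fractions with rounding", {
  roi <- maskROI(faceDetection(x = 0, y = 0, w = 100, h = 100, yEye = 40))
  expect_equal(c(roi@x0, roi@y0, roi@x1, roi@y1), c(10, 50, 90, 100))

  small <- maskROI(faceDetection(x = 0, y = 0, w = 10, h = 10, yEye = 4))
  expect_equal(c(small@x0, small@y0, small@x1, small@y1), c(1, 5, 9, 10))

  expect_error(maskROI(faceDetection(x = 0, y = 0, w = 2, h = 4, yEye = 1)),
               "too small")
})

test_that("ROIs are translation-equivariant and vertically disjoint", {
  set.seed(71)
  for (i in 1:20) {
    x <- runif(1, 0, 50); y <- runif(1, 0, 50)
    w <- runif(1, 20, 120); h <- runif(1, 20, 120)
    yEye <- y + runif(1, 0.2, 0.45) * h
    det <- faceDetection(x = x, y = y, w = w, h = h, yEye = yEye)
    dx <- sample(-30:30, 1); dy <- sample(-30:30, 1)
    detShift <- faceDetection(x = x + dx, y = y + dy, w = w, h = h, yEye = yEye + dy)

    for (op in list(foreheadROI, maskROI)) {
      a <- op(det); b <- op(detShift)
      expect_equal(c(b@x0, b@x1), c(a@x0, a@x1) + dx)
      expect_equal(c(b@y0, b@y1), c(a@y0, a@y1) + dy)
    }
    # eye line above mid-face => forehead ends before the mask begins
    expect_lte(foreheadROI(det)@y1, maskROI(det)@y0)
  }
})

test_that("pose-corrected diagonal undoes cos foreshortening", {
  frontal <- faceDetection(x = 0, y = 0, w = 30, h = 40, yEye = 15)
  expect_equal(correctedDiagonal(frontal), 50)  # 3-4-5 triangle

  yawed <- faceDetection(x = 0, y = 0, w = 30, h = 40, yEye = 15, yaw = 60)
  expect_equal(correctedDiagonal(yawed), sqrt(60^2 + 40^2), tolerance = 1e-12)

  # strictly increasing in |yaw| for a fixed box
  yaws <- seq(0, 80, by = 10)
  ds <- vapply(yaws, function(a)
    correctedDiagonal(faceDetection(x = 0, y = 0, w = 30, h = 40, yEye = 15, yaw = a)),
    numeric(1))
  expect_true(all(diff(ds) > 0))

  expect_error(correctedDiagonal(faceDetection(x = 0, y = 0, w = 30, h = 40,
                                               yEye = 15, yaw = 89.999999)),
               NA)
  expect_error(faceDetection(x = 0, y = 0, w = 30, h = 40, yEye = 15, yaw = 90),
               "yaw")
})

test_that("distance power law maps diagonals to metres and is decreasing", {
  expect_equal(distanceFromDiagonal(76.41289), 1.0, tolerance = 1e-4)
  expect_equal(distanceFromDiagonal(50), 140.22 / 50^1.14, tolerance = 1e-12)
  expect_equal(distanceFromDiagonal(50), 1.6218, tolerance = 1e-4)

  Ls <- seq(20, 150, by = 5)
  expect_true(all(diff(distanceFromDiagonal(Ls)) < 0))
  expect_error(distanceFromDiagonal(0), "must be > 0")
})

test_that("detection fixtures and the distance model invert each other", {
  expect_equal(diagonalFromDistance(1.0), 76.4, tolerance = 1e-3)
  for (D in c(0.5, 1, 2, 3.3, 5)) {
    for (pose in list(c(0, 0), c(15, -20), c(-30, 25))) {
      det <- simulateDetection(D, pitch = pose[1], yaw = pose[2],
                               frameWidth = 400, frameHeight = 300)
      est <- estimateDistance(det)
      expect_equal(est$dM, D, tolerance = 1e-6)
      # pose inflates the corrected diagonal relative to the raw one
      if (any(pose != 0)) expect_gt(est$lCorrectedPx, est$lPx)
    }
  }
  # closer subject, larger diagonal
  d2 <- simulateDetection(2, frameWidth = 400, frameHeight = 300)
  d5 <- simulateDetection(5, frameWidth = 400, frameHeight = 300)
  expect_gt(correctedDiagonal(d2), correctedDiagonal(d5))
})

test_that("the power-law constants are recoverable from (L, D) samples", {
  Ls <- seq(20, 140, by = 10)
  fit <- fitDistanceModel(Ls, distanceFromDiagonal(Ls))
  expect_equal(fit$k, 140.22, tolerance = 1e-6)
  expect_equal(fit$p, 1.14, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})
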