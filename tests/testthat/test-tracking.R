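test_that("Gaussian fit recovers a noiseless symmetric spot center", {
  img <- renderSpot(25, cx = 10.00, cy = 12.50)
  loc <- fitPillarCenter(img, fullRoi(img))
  expect_true(loc$converged)
  expect_lt(abs(loc$center[1] - 10.00), 1e-6)
  expect_lt(abs(loc$center[2] - 12.50), 1e-6)
  expect_lt(loc$fit_residual, 1e-8)
})

test_that("a half-pixel spot shift is measured as exactly half a pixel", {
  a <- fitPillarCenter(renderSpot(25, 12.0, 12.0), fullRoi(renderSpot(25, 0, 0)))
  b <- fitPillarCenter(renderSpot(25, 12.5, 12.0), fullRoi(renderSpot(25, 0, 0)))
  expect_lt(abs((b$center[1] - a$center[1]) - 0.5), 1e-6)
  expect_lt(abs(b$center[2] - a$center[2]), 1e-6)
})

test_that("integer-pixel image translation shifts the fit exactly", {
  a <- fitPillarCenter(renderSpot(31, 13.3, 14.7), fullRoi(renderSpot(31, 0, 0)))
  b <- fitPillarCenter(renderSpot(31, 13.3 + 3, 14.7 + 2),
                       fullRoi(renderSpot(31, 0, 0)))
  expect_equal(b$center - a$center, c(3, 2), tolerance = 1e-6)
})

test_that("fit is invariant to adding a constant background", {
  img <- renderSpot(25, 11.3, 9.8)
  a <- fitPillarCenter(img, fullRoi(img))
  b <- fitPillarCenter(img + 500, fullRoi(img))
  expect_equal(a$center, b$center, tolerance = 1e-7)
  expect_equal(b$background - a$background, 500, tolerance = 1e-5)
})

test_that("Gaussian fit agrees with the intensity-centroid oracle", {
  # tight spot so ROI truncation does not bias the centroid
  img <- renderSpot(25, 12.37, 11.62, sigma = 2)
  loc <- fitPillarCenter(img, fullRoi(img))
  w <- img - min(img)
  grid <- expand.grid(x = 0:24, y = 0:24)
  z <- as.vector(t(w))
  centroid <- c(sum(grid$x * z), sum(grid$y * z)) / sum(z)
  expect_lt(max(abs(loc$center - centroid)), 1e-3)
})

test_that("failed fits are flagged, not silently returned", {
  flat <- matrix(100, 25, 25)
  loc <- fitPillarCenter(flat, fullRoi(flat))
  expect_false(loc$converged)
  expect_true(is.na(loc$center[1]))
})

test_that("pillar detection finds the full grid and nothing on blanks", {
  sc <- generatePillarScene(nGrid = 5, readNoiseSd = 0)
  rois <- detectPillars(frames(sc)$before)
  expect_equal(nrow(rois), 25)
  expect_equal(nrow(detectPillars(matrix(100, 60, 60))), 0)
  # threshold above the peak amplitude detects nothing
  noisy <- generatePillarScene(nGrid = 3, readNoiseSd = 10, seed = 1)
  expect_equal(nrow(detectPillars(frames(noisy)$before, k = 1e5)), 0)
})

test_that("deflection measurement follows the pixel-size conversion", {
  mk <- function(cx, cy) structure(
    list(center = c(cx, cy), amplitude = 1, sigma = 1, background = 0,
         fit_residual = 0, converged = TRUE, frame_role = NA),
    class = "PillarLocalization")
  same <- measureDeflection(mk(100, 100), mk(100, 100), mk(100, 100),
                            pixelSize = 161)
  expect_equal(same$d_magnitude, 0)
  expect_equal(same$recovery_residual, 0)
  one <- measureDeflection(mk(100, 100), mk(101, 100), mk(100, 100),
                           pixelSize = 161)
  expect_equal(one$d_magnitude, 161)
  expect_error(measureDeflection(
    structure(list(converged = FALSE), class = "PillarLocalization"),
    mk(1, 1), NULL, 161), "converge")
})

test_that("noiseless scenes are recovered to better than 0.01 nm", {
  sc <- generatePillarScene(trueDeflection = c(100, 0), readNoiseSd = 0,
                            nGrid = 3)
  tr <- trackPillarScene(sc)
  expect_lt(abs(tr$d_nm[tr$deflected] - 100), 0.01)
  expect_lt(max(tr$d_nm[!tr$deflected]), 0.01)
  expect_lt(max(tr$recovery_nm), 0.01)
})

test_that("localization error grows monotonically with read noise", {
  rmse <- vapply(c(5, 15, 45), function(ns) {
    errs <- vapply(1:25, function(i) {
      sc <- generatePillarScene(trueDeflection = c(120, 60),
                                readNoiseSd = ns, nGrid = 1,
                                frameRoles = c("before", "during"),
                                seed = 7000 + i)
      tr <- trackPillarScene(sc)
      tr$d_nm[tr$deflected] - sqrt(120^2 + 60^2)
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})

test_that("reference pillars remove rigid stage drift", {
  sc <- generatePillarScene(trueDeflection = c(100, 0), driftNm = c(50, 0),
                            readNoiseSd = 15, nGrid = 3, seed = 33)
  naive <- trackPillarScene(sc, useReferences = FALSE)
  corr <- trackPillarScene(sc, useReferences = TRUE)
  expect_gt(abs(naive$d_nm[naive$deflected] - 100), 20)   # drift-corrupted
  expect_lt(abs(corr$d_nm[corr$deflected] - 100), 7)
})

test_that("deflection is invariant to a constant intensity offset", {
  sc <- generatePillarScene(trueDeflection = c(150, 0), readNoiseSd = 0,
                            nGrid = 2)
  fr <- frames(sc)
  roi <- detectPillars(fr$before)[1, ]
  d1 <- fitPillarCenter(fr$during, roi)
  d2 <- fitPillarCenter(fr$during + 250, roi)
  expect_equal(d1$center, d2$center, tolerance = 1e-6)
})
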