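# Subpixel pillar localization. Coordinates are 0-based with the
# pixel-center convention: pixel [i, j] of the image matrix (row i = y,
# column j = x) has its center at (x, y) = (j - 1, i - 1). All nm
# conversions go through a single pixelSize constant.

#' Detect candidate pillar spots in a bright-field frame
#'
#' Local-maximum detection above background + k * noise, where background
#' and noise are estimated robustly (median / MAD) from the whole frame.
#' A light 3x3 box smoothing stabilizes maxima under read noise; maxima
#' closer together than \code{minDistance} are merged keeping the
#' brightest (ties broken toward the lowest row, then column index).
#'
#' @param image numeric matrix.
#' @param k noise multiplier for the detection threshold.
#' @param roiHalfWidth half-width of the square ROI returned around each
#'   detection, px.
#' @param minDistance minimal separation between detections, px.
#' @return data.frame with one row per detection: \code{x}, \code{y}
#'   (0-based integer peak position), ROI bounds \code{x0,x1,y0,y1}
#'   (0-based, clipped to the frame). Zero rows when nothing is detected.
#' @export
detectPillars <- function(image, k = 5, roiHalfWidth = 12,
                          minDistance = roiHalfWidth) {
  stopifnot(is.matrix(image))
  bg <- stats::median(image)
  noise <- stats::mad(image)
  thr <- bg + k * max(noise, .Machine$double.eps)
  # 3x3 box smoothing, edge-replicated
  sm <- image
  nr <- nrow(image); nc <- ncol(image)
  if (nr >= 3 && nc >= 3) {
    pad <- image[c(1, 1:nr, nr), c(1, 1:nc, nc)]
    sm <- matrix(0, nr, nc)
    for (di in 0:2) for (dj in 0:2)
      sm <- sm + pad[(1:nr) + di, (1:nc) + dj]
    sm <- sm / 9
  }
  cand <- which(sm > thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (q in seq_len(nrow(cand))) {
    i <- cand[q, 1]; j <- cand[q, 2]
    ii <- max(1, i - 1):min(nr, i + 1)
    jj <- max(1, j - 1):min(nc, j + 1)
    keep[q] <- sm[i, j] == max(sm[ii, jj])
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), x0 = numeric(0),
                      x1 = numeric(0), y0 = numeric(0), y1 = numeric(0)))
  o <- order(-sm[cand], cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]
  sel <- rep(TRUE, nrow(cand))
  for (q in seq_len(nrow(cand))) {
    if (!sel[q]) next
    if (q < nrow(cand)) {
      later <- (q + 1):nrow(cand)
      d2 <- (cand[later, 1] - cand[q, 1])^2 + (cand[later, 2] - cand[q, 2])^2
      sel[later][d2 < minDistance^2] <- FALSE
    }
  }
  cand <- cand[sel, , drop = FALSE]
  x <- cand[, 2] - 1; y <- cand[, 1] - 1
  data.frame(
    x = x, y = y,
    x0 = pmax(0, x - roiHalfWidth), x1 = pmin(nc - 1, x + roiHalfWidth),
    y0 = pmax(0, y - roiHalfWidth), y1 = pmin(nr - 1, y + roiHalfWidth))
}

#' Fit an isotropic 2D Gaussian to one pillar spot
#'
#' Least-squares fit of A exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2)) + B
#' over a rectangular ROI, initialized from the background-subtracted
#' intensity centroid. A fit that fails to converge or whose center
#' escapes the ROI is returned with \code{converged = FALSE} rather than
#' silently reporting a value.
#'
#' @param image numeric matrix.
#' @param roi list or one-row data.frame with 0-based inclusive bounds
#'   \code{x0}, \code{x1}, \code{y0}, \code{y1}.
#' @param frameRole optional label stored with the result.
#' @param anisotropic if TRUE, fit separate sigma_x / sigma_y (reported
#'   sigma is their geometric mean).
#' @return object of class \code{PillarLocalization}: list with
#'   \code{center} (x, y in 0-based px), \code{amplitude}, \code{sigma},
#'   \code{background}, \code{fit_residual} (RMS residual / amplitude),
#'   \code{converged}, \code{frame_role}.
#' @export
fitPillarCenter <- function(image, roi, frameRole = NA_character_,
                            anisotropic = FALSE) {
  stopifnot(is.matrix(image))
  x0 <- round(roi$x0); x1 <- round(roi$x1)
  y0 <- round(roi$y0); y1 <- round(roi$y1)
  stopifnot(x0 >= 0, y0 >= 0, x1 < ncol(image), y1 < nrow(image),
            x1 > x0, y1 > y0)
  sub <- image[(y0:y1) + 1, (x0:x1) + 1, drop = FALSE]
  xs <- x0:x1; ys <- y0:y1
  grid <- expand.grid(x = xs, y = ys)
  z <- as.vector(t(sub))                      # row-major: x fastest
  bg0 <- min(z); a0 <- max(z) - bg0
  w <- pmax(z - bg0, 0)
  cx0 <- sum(grid$x * w) / sum(w)
  cy0 <- sum(grid$y * w) / sum(w)
  s0 <- max((x1 - x0 + 1) / 6, 1)

  fail <- function() structure(
    list(center = c(NA_real_, NA_real_), amplitude = NA_real_,
         sigma = NA_real_, background = NA_real_, fit_residual = NA_real_,
         converged = FALSE, frame_role = frameRole),
    class = "PillarLocalization")

  fit <- tryCatch({
    if (anisotropic) {
      minpack.lm::nlsLM(
        z ~ A * exp(-((x - cx)^2 / (2 * sx^2) + (y - cy)^2 / (2 * sy^2))) + B,
        data = cbind(grid, z = z),
        start = list(A = a0, cx = cx0, cy = cy0, sx = s0, sy = s0, B = bg0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        z ~ A * exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)) + B,
        data = cbind(grid, z = z),
        start = list(A = a0, cx = cx0, cy = cy0, s = s0, B = bg0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(fail())
  p <- stats::coef(fit)
  sigma <- if (anisotropic) sqrt(abs(p["sx"] * p["sy"])) else abs(p[["s"]])
  if (p["cx"] < x0 || p["cx"] > x1 || p["cy"] < y0 || p["cy"] > y1 ||
      p["A"] <= 0 || sigma <= 0)
    return(fail())
  res <- sqrt(mean(stats::resid(fit)^2)) / p[["A"]]
  structure(
    list(center = c(p[["cx"]], p[["cy"]]), amplitude = p[["A"]],
         sigma = as.numeric(sigma), background = p[["B"]],
         fit_residual = res, converged = TRUE, frame_role = frameRole),
    class = "PillarLocalization")
}

#' @export
print.PillarLocalization <- function(x, ...) {
  if (x$converged)
    cat(sprintf("PillarLocalization [%s]: center (%.3f, %.3f) px, A %.1f, sigma %.2f px, B %.1f, rms %.3g\n",
                x$frame_role, x$center[1], x$center[2], x$amplitude,
                x$sigma, x$background, x$fit_residual))
  else cat(sprintf("PillarLocalization [%s]: fit failed\n", x$frame_role))
  invisible(x)
}

#' Deflection of one pilus from before/during/after localizations
#'
#' The deflection vector is (during - before) * pixelSize, optionally
#' corrected for rigid stage drift estimated as the componentwise median
#' displacement of non-stimulated reference pillars. The recovery
#' residual |after - before| * pixelSize checks that the pilus returned
#' to its rest position after stimulus release; a residual above
#' \code{recoveryLimit} flags the measurement as non-recovering.
#'
#' @param before,during,after \code{PillarLocalization} objects (as from
#'   [fitPillarCenter()]); \code{after} may be NULL when no release frame
#'   was recorded.
#' @param pixelSize nm/px.
#' @param referenceCenters optional list of before/during center pairs for
#'   reference pillars: each element a list with \code{before} and
#'   \code{during} 2-vectors (px).
#' @param recoveryLimit nm; default Inf (no flagging).
#' @param pilusId identifier.
#' @return list of class \code{DeflectionMeasurement}: \code{d_vector}
#'   (nm), \code{d_magnitude} (nm), \code{recovery_residual} (nm or NA),
#'   \code{reference_drift} (nm), \code{recovered} (logical),
#'   \code{pilus_id}.
#' @export
measureDeflection <- function(before, during, after = NULL, pixelSize,
                              referenceCenters = NULL,
                              recoveryLimit = Inf, pilusId = NA_character_) {
  stopifnot(pixelSize > 0)
  for (loc in list(before, during))
    if (!isTRUE(loc$converged)) stop("localization fit did not converge")
  drift <- c(0, 0)
  if (!is.null(referenceCenters) && length(referenceCenters)) {
    dx <- vapply(referenceCenters,
                 function(r) r$during[1] - r$before[1], numeric(1))
    dy <- vapply(referenceCenters,
                 function(r) r$during[2] - r$before[2], numeric(1))
    drift <- c(stats::median(dx), stats::median(dy)) * pixelSize
  }
  d <- (during$center - before$center) * pixelSize - drift
  rec <- NA_real_
  if (!is.null(after)) {
    if (!isTRUE(after$converged)) stop("localization fit did not converge")
    rec <- sqrt(sum(((after$center - before$center) * pixelSize)^2))
  }
  structure(
    list(d_vector = d, d_magnitude = sqrt(sum(d^2)),
         recovery_residual = rec, reference_drift = drift,
         recovered = if (is.na(rec)) NA else rec <= recoveryLimit,
         pilus_id = pilusId),
    class = "DeflectionMeasurement")
}

#' @export
print.DeflectionMeasurement <- function(x, ...) {
  cat(sprintf("Deflection [%s]: d = %.1f nm (%.1f, %.1f), recovery %.1f nm, drift (%.1f, %.1f) nm\n",
              x$pilus_id, x$d_magnitude, x$d_vector[1], x$d_vector[2],
              x$recovery_residual, x$reference_drift[1],
              x$reference_drift[2]))
  invisible(x)
}

#' Track all pili of a synthetic scene and measure deflections
#'
#' Detects pillars on the "before" frame, fits each spot in every frame,
#' matches detections to the scene's truth records by nearest rest-frame
#' center, and measures each pilus' deflection (optionally drift-corrected
#' using all non-stimulated pili as references).
#'
#' @param scene a [PillarScene-class].
#' @param useReferences correct for rigid drift using the non-stimulated
#'   pili.
#' @param k,roiHalfWidth detection parameters, see [detectPillars()].
#' @param recoveryLimit nm, see [measureDeflection()].
#' @return data.frame: one row per tracked pilus with fitted centers per
#'   frame (px), \code{d_nm}, \code{dx_nm}, \code{dy_nm},
#'   \code{recovery_nm}, \code{truth_d_nm} (from the scene truth),
#'   \code{deflected}.
#' @export
trackPillarScene <- function(scene, useReferences = FALSE, k = 5,
                             roiHalfWidth = 12, recoveryLimit = Inf) {
  stopifnot(is(scene, "PillarScene"))
  fr <- frames(scene)
  if (is.null(fr$before) || is.null(fr$during))
    stop("scene must contain before and during frames")
  rois <- detectPillars(fr$before, k = k, roiHalfWidth = roiHalfWidth)
  if (nrow(rois) == 0L) return(data.frame())
  tru <- sceneTruth(scene)
  truB <- tru[tru$role == "before", ]

  fits <- lapply(seq_len(nrow(rois)), function(i) {
    roi <- rois[i, ]
    lapply(fr, function(img) fitPillarCenter(img, roi))
  })
  ok <- vapply(fits, function(f)
    all(vapply(f, function(l) isTRUE(l$converged), logical(1))), logical(1))
  fits <- fits[ok]
  if (!length(fits)) return(data.frame())

  cB <- t(vapply(fits, function(f) f$before$center, numeric(2)))
  idx <- vapply(seq_len(nrow(cB)), function(i)
    which.min((truB$cx - cB[i, 1])^2 + (truB$cy - cB[i, 2])^2), integer(1))
  ids <- truB$pilus_id[idx]
  deflIds <- unique(tru$pilus_id[tru$deflected])

  refs <- NULL
  if (useReferences) {
    refIdx <- which(!ids %in% deflIds)
    refs <- lapply(refIdx, function(i)
      list(before = fits[[i]]$before$center,
           during = fits[[i]]$during$center))
  }
  # truth stimulus magnitude excludes any rigid stage drift: drift is a
  # nuisance the reference correction is meant to remove
  truthD <- sqrt(sum(scene@params$trueDeflection^2))
  out <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    m <- measureDeflection(f$before, f$during, f$after,
                           pixelSize = pixelSize(scene),
                           referenceCenters = if (ids[i] %in% deflIds) refs,
                           recoveryLimit = recoveryLimit,
                           pilusId = ids[i])
    td <- if (ids[i] %in% deflIds) truthD else 0
    data.frame(pilus_id = ids[i],
               before_x = f$before$center[1], before_y = f$before$center[2],
               during_x = f$during$center[1], during_y = f$during$center[2],
               dx_nm = m$d_vector[1], dy_nm = m$d_vector[2],
               d_nm = m$d_magnitude, recovery_nm = m$recovery_residual,
               truth_d_nm = td, deflected = ids[i] %in% deflIds,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
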