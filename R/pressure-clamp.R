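# High-speed pressure-clamp analysis: per-patch normalization, Boltzmann
# fitting of the pressure-response curve, P50 extraction and peak-current
# group summaries.

#' Normalize a pressure family to its maximal amplitude
#'
#' Each peak current is divided by the family's maximum magnitude, so the
#' normalized response saturates at 1 per patch. An all-zero family
#' cannot be normalized and is flagged non-responding (such patches are
#' excluded from fitting rather than guessed at).
#'
#' @param fam a [PressureFamily-class].
#' @return list: \code{pressures} (mmHg magnitudes), \code{normalized},
#'   \code{imax} (pA, the maximal magnitude), \code{responding}
#'   (logical), \code{patchId}.
#' @export
normalizeFamily <- function(fam) {
  stopifnot(is(fam, "PressureFamily"))
  y <- abs(peakCurrents(fam))
  imax <- max(y)
  if (imax == 0)
    return(list(pressures = abs(pressures(fam)), normalized = y,
                imax = 0, responding = FALSE, patchId = fam@patchId))
  list(pressures = abs(pressures(fam)), normalized = y / imax,
       imax = imax, responding = TRUE, patchId = fam@patchId)
}

#' Fit the Boltzmann pressure-response relation of one patch
#'
#' Least-squares fit of y(P) = A / (1 + exp((P50 - P) / slope)) to a
#' normalized pressure family. The slope is constrained positive (the
#' response grows with pressure). The free amplitude A (close to 1)
#' absorbs the fact that max-normalization pins the response to 1 at the
#' largest applied pressure, where the underlying Boltzmann has not yet
#' fully saturated; without it the P50 of a family that does not reach
#' saturation within the protocol would be biased low.
#'
#' @param norm a [normalizeFamily()] result (or a list with
#'   \code{pressures} and \code{normalized}).
#' @param p50Start,slopeStart optional starting values; defaults are the
#'   pressure nearest half-activation and a tenth of the pressure range.
#' @return a [BoltzmannFit-class]; \code{converged = FALSE} when the
#'   family could not be fitted (non-responding patch, < 4 points, or
#'   optimizer failure).
#' @export
fitBoltzmann <- function(norm, p50Start = NULL, slopeStart = NULL) {
  bad <- new("BoltzmannFit", p50 = NA_real_, slope = NA_real_,
             imax = if (is.null(norm$imax)) NA_real_ else norm$imax,
             fitQuality = NA_real_, converged = FALSE)
  if (isFALSE(norm$responding)) return(bad)
  P <- norm$pressures; y <- norm$normalized
  if (length(P) < 4L) return(bad)
  if (is.null(p50Start)) p50Start <- P[which.min(abs(y - 0.5))]
  if (is.null(slopeStart)) slopeStart <- diff(range(P)) / 10
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A / (1 + exp((p50 - P) / slope)),
                      start = list(A = 1, p50 = p50Start,
                                   slope = slopeStart),
                      lower = c(A = 0.1, p50 = 0, slope = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  p <- stats::coef(fit)
  if (p[["p50"]] > 10 * max(P)) return(bad)   # sanity bound
  new("BoltzmannFit", p50 = p[["p50"]], slope = p[["slope"]],
      imax = norm$imax,
      fitQuality = sqrt(mean(stats::resid(fit)^2)), converged = TRUE)
}

#' Per-patch Boltzmann fits and the group P50
#'
#' Normalizes and fits every family; the group P50 is the mean of the
#' individual patch P50s (not a pooled fit), reported with its s.e.m.
#' Non-responding or non-converging patches are excluded and listed.
#'
#' @param families list of [PressureFamily-class] objects.
#' @return list: \code{fits} data.frame (patch_id, p50, slope, imax_pA,
#'   fit_rms, converged), \code{p50_mean}, \code{p50_sem}, \code{n},
#'   \code{excluded} (patch ids).
#' @export
fitPressureFamilies <- function(families) {
  rows <- lapply(families, function(f) {
    nf <- normalizeFamily(f)
    bf <- fitBoltzmann(nf)
    data.frame(patch_id = f@patchId, p50 = bf@p50, slope = bf@slope,
               imax_pA = bf@imax, fit_rms = bf@fitQuality,
               converged = bf@converged, stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  ok <- fits$converged
  p50s <- fits$p50[ok]
  list(fits = fits,
       p50_mean = if (length(p50s)) mean(p50s) else NA_real_,
       p50_sem = if (length(p50s) > 1)
         stats::sd(p50s) / sqrt(length(p50s)) else NA_real_,
       n = sum(ok), excluded = fits$patch_id[!ok])
}

#' Peak stretch-activated current summaries and group comparisons
#'
#' Per-group mean maximal current with s.e.m., plus pairwise Mann-Whitney
#' comparisons between groups.
#'
#' @param groups named list; each element a list of
#'   [PressureFamily-class] objects (one per patch).
#' @return list: \code{summary} data.frame (group, mean_pA, sem_pA, n),
#'   \code{comparisons} data.frame (groupA, groupB, U, p).
#' @export
peakCurrentSummary <- function(groups) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  peaks <- lapply(groups, function(fams)
    vapply(fams, function(f) max(abs(peakCurrents(f))), numeric(1)))
  summ <- do.call(rbind, lapply(names(peaks), function(g) {
    v <- peaks[[g]]
    data.frame(group = g, mean_pA = mean(v),
               sem_pA = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                        else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  comp <- NULL
  gn <- names(peaks)
  if (length(gn) > 1) {
    pairs <- utils::combn(gn, 2)
    comp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      mw <- mannWhitneyTest(peaks[[a]], peaks[[b]])
      data.frame(groupA = a, groupB = b, U = mw$U, p = mw$p,
                 stringsAsFactors = FALSE)
    }))
  }
  list(summary = summ, comparisons = comp)
}
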