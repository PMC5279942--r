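# dF/F normalization and agonist-epoch response scoring for calcium
# imaging time series.

#' Baseline-normalized fluorescence change
#'
#' dF/F = (F - F0) / F0 per frame, with F0 the mean of the initial
#' baseline frames (the imaging protocol acquires background fluorescence
#' for the first cycles before any agonist).
#'
#' @param trace a [FluorescenceTrace-class].
#' @return numeric vector, one dF/F value per frame.
#' @export
deltaFOverF <- function(trace) {
  stopifnot(is(trace, "FluorescenceTrace"))
  f <- intensities(trace)
  f0 <- mean(f[seq_len(trace@nBaselineFrames)])
  if (f0 <= 0) stop("baseline fluorescence F0 must be > 0")
  (f - f0) / f0
}

#' Score one agonist epoch of a normalized trace
#'
#' A cell responds to an epoch when its peak dF/F within the epoch
#' (extended by a short post-application window, since indicator signals
#' peak slightly after short applications) exceeds the threshold. The
#' default threshold is max(0.1, 5 x the baseline dF/F noise sd) -- the
#' package's own operational criterion, configurable.
#'
#' @param dff dF/F series (from [deltaFOverF()]).
#' @param trace the [FluorescenceTrace-class] the series came from
#'   (supplies frame timing, baseline frames and epoch table).
#' @param epochLabel which epoch to score.
#' @param threshold response threshold on peak dF/F; NULL for the
#'   default.
#' @param postWindow s appended after the epoch end when searching for
#'   the peak.
#' @return list: \code{responder}, \code{peak_dff}, \code{threshold}.
#' @export
scoreEpoch <- function(dff, trace, epochLabel, threshold = NULL,
                       postWindow = 10) {
  ep <- epochs(trace)
  j <- match(epochLabel, ep$label)
  if (is.na(j)) stop("unknown epoch label: ", epochLabel)
  t <- (seq_along(dff) - 1) * trace@frameInterval
  idx <- which(t >= ep$start[j] &
                 t <= ep$start[j] + ep$duration[j] + postWindow)
  if (!length(idx)) stop("epoch lies outside the trace")
  if (is.null(threshold)) {
    blSd <- stats::sd(dff[seq_len(trace@nBaselineFrames)])
    if (is.na(blSd)) blSd <- 0
    threshold <- max(0.1, 5 * blSd)
  }
  peak <- max(dff[idx])
  list(responder = peak > threshold, peak_dff = peak,
       threshold = threshold)
}

#' Score a cohort of calcium traces across all agonist epochs
#'
#' Computes dF/F per cell, scores every epoch, and applies viability
#' gating: cells that fail the ATP epoch (label \code{viabilityLabel})
#' are excluded from the downstream epoch statistics, mirroring the
#' convention that only ATP-responsive cells enter the analysis.
#'
#' @param traces list of [FluorescenceTrace-class] objects.
#' @param viabilityLabel epoch label used for viability gating; NULL
#'   disables gating.
#' @param threshold passed to [scoreEpoch()].
#' @return list: \code{scores} data.frame (cell_id, epoch, responder,
#'   peak_dff, viable), \code{fractions} data.frame of responder
#'   fractions per epoch among viable cells, \code{n_viable},
#'   \code{population_dff} (mean dF/F trace across viable cells) and
#'   \code{population_sem}.
#' @export
scoreCalciumCohort <- function(traces, viabilityLabel = "ATP",
                               threshold = NULL) {
  stopifnot(length(traces) >= 1)
  dffs <- lapply(traces, deltaFOverF)
  labels <- epochs(traces[[1]])$label
  rows <- NULL
  viable <- logical(length(traces))
  for (i in seq_along(traces)) {
    sc <- lapply(labels, function(l)
      scoreEpoch(dffs[[i]], traces[[i]], l, threshold = threshold))
    v <- if (is.null(viabilityLabel)) TRUE
         else sc[[match(viabilityLabel, labels)]]$responder
    viable[i] <- v
    rows <- rbind(rows, data.frame(
      cell_id = traces[[i]]@cellId, epoch = labels,
      responder = vapply(sc, `[[`, logical(1), "responder"),
      peak_dff = vapply(sc, `[[`, numeric(1), "peak_dff"),
      viable = v, stringsAsFactors = FALSE))
  }
  gated <- rows[rows$viable, , drop = FALSE]
  fr <- do.call(rbind, lapply(labels, function(l) {
    s <- gated[gated$epoch == l, ]
    data.frame(epoch = l, fraction = mean(s$responder), n = nrow(s),
               stringsAsFactors = FALSE)
  }))
  nmin <- min(vapply(dffs[viable], length, integer(1)))
  mat <- do.call(rbind, lapply(dffs[viable], function(d) d[seq_len(nmin)]))
  list(scores = rows, fractions = fr, n_viable = sum(viable),
       population_dff = colMeans(mat),
       population_sem = apply(mat, 2, stats::sd) / sqrt(nrow(mat)))
}
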