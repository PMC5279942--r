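# Binned stimulus-response construction: per-cell bin averages, then
# across-cell means, per-cell thresholds and responder classification.

#' Deflection binning scheme
#'
#' Contiguous deflection bins over (0, 1000] nm. The default edges are
#' \{0, 10, 50, 100, 250, 500, 1000\}; intervals are half-open
#' (lower, upper], so a 0 nm deflection falls in no bin.
#'
#' @param edges strictly increasing numeric vector starting at 0 and
#'   ending at 1000.
#' @return object of class \code{BinningScheme}: list with \code{edges}
#'   and \code{labels} ("0-10", ...).
#' @export
binningScheme <- function(edges = c(0, 10, 50, 100, 250, 500, 1000)) {
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (edges[1] != 0) stop("first bin edge must be 0")
  if (edges[length(edges)] != 1000) stop("last bin edge must be 1000")
  structure(list(edges = edges,
                 labels = paste(edges[-length(edges)], edges[-1], sep = "-")),
            class = "BinningScheme")
}

#' Bin stimulus-response measurements with two-stage averaging
#'
#' Assigns every measurement to its deflection bin, averages current
#' amplitudes within each bin per cell, then averages those per-cell
#' means across cells. Non-responding sweeps enter their bin with
#' amplitude 0; a bin's across-cell mean is computed only over the cells
#' that contributed at least one measurement to it. Deflections outside
#' (0, 1000] nm are excluded (and counted in \code{n_excluded}).
#'
#' @param measurements data.frame with columns \code{cell_id},
#'   \code{deflection} (nm), \code{amplitude} (pA).
#' @param scheme a [binningScheme()].
#' @return list of class \code{BinnedStimulusResponse}:
#'   \code{per_cell_bin_means} (cells x bins matrix, NA where a cell has
#'   no measurement in a bin), \code{summary} data.frame (bin, mean, sem,
#'   n_cells, n_measurements), \code{n_cells}, \code{n_measurements},
#'   \code{n_excluded}, \code{scheme}.
#' @examples
#' m <- data.frame(cell_id = c("A", "A", "B"),
#'                 deflection = c(30, 40, 35), amplitude = c(10, 20, 60))
#' binResponses(m)$summary        # bin 10-50 mean 37.5
#' @export
binResponses <- function(measurements, scheme = binningScheme()) {
  stopifnot(all(c("cell_id", "deflection", "amplitude") %in%
                  names(measurements)))
  edges <- scheme$edges
  nb <- length(edges) - 1
  if (nrow(measurements) == 0L) {
    return(structure(list(
      per_cell_bin_means = matrix(NA_real_, 0, nb,
                                  dimnames = list(NULL, scheme$labels)),
      summary = data.frame(bin = scheme$labels, mean = NA_real_,
                           sem = NA_real_, n_cells = 0L,
                           n_measurements = 0L),
      n_cells = 0L, n_measurements = 0L, n_excluded = 0L, scheme = scheme),
      class = "BinnedStimulusResponse"))
  }
  inRange <- measurements$deflection > 0 & measurements$deflection <= 1000
  excl <- sum(!inRange)
  m <- measurements[inRange, , drop = FALSE]
  bin <- cut(m$deflection, breaks = edges, right = TRUE,
             include.lowest = FALSE, labels = scheme$labels)
  cells <- sort(unique(m$cell_id))
  pcm <- matrix(NA_real_, length(cells), nb,
                dimnames = list(cells, scheme$labels))
  counts <- integer(nb)
  for (bi in seq_len(nb)) {
    sel <- !is.na(bin) & bin == scheme$labels[bi]
    counts[bi] <- sum(sel)
    if (!counts[bi]) next
    ag <- tapply(m$amplitude[sel], m$cell_id[sel], mean)
    pcm[names(ag), bi] <- ag
  }
  means <- colMeans(pcm, na.rm = TRUE)
  means[colSums(!is.na(pcm)) == 0] <- NA_real_
  sems <- apply(pcm, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  })
  structure(list(
    per_cell_bin_means = pcm,
    summary = data.frame(bin = scheme$labels, mean = as.numeric(means),
                         sem = as.numeric(sems),
                         n_cells = as.integer(colSums(!is.na(pcm))),
                         n_measurements = counts),
    n_cells = length(cells), n_measurements = nrow(m),
    n_excluded = excl, scheme = scheme),
    class = "BinnedStimulusResponse")
}

#' @export
print.BinnedStimulusResponse <- function(x, ...) {
  cat(sprintf("BinnedStimulusResponse: %d cells, %d measurements (%d excluded)\n",
              x$n_cells, x$n_measurements, x$n_excluded))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Classify one cell as responder and extract its deflection threshold
#'
#' A cell is a responder when at least one sweep with a deflection in
#' (0, 1000] nm gated a current; its threshold is the smallest gating
#' deflection. Gating is taken from the \code{responded} column when
#' present, else from \code{amplitude > 0}.
#'
#' @param cellMeasurements data.frame for one cell: \code{deflection},
#'   \code{amplitude}, optionally \code{responded}, \code{cell_id}.
#' @return one-row data.frame of class-free CellSummary layout:
#'   \code{cell_id}, \code{responder}, \code{threshold} (nm, NA for
#'   non-responders), \code{n_measurements}.
#' @export
classifyResponder <- function(cellMeasurements) {
  stopifnot(nrow(cellMeasurements) >= 1)
  gated <- if ("responded" %in% names(cellMeasurements))
    cellMeasurements$responded else cellMeasurements$amplitude > 0
  inRange <- cellMeasurements$deflection > 0 &
    cellMeasurements$deflection <= 1000
  g <- gated & inRange
  data.frame(
    cell_id = if ("cell_id" %in% names(cellMeasurements))
      cellMeasurements$cell_id[1] else NA_character_,
    responder = any(g),
    threshold = if (any(g)) min(cellMeasurements$deflection[g]) else NA_real_,
    n_measurements = nrow(cellMeasurements),
    stringsAsFactors = FALSE)
}

#' Summarize every cell of a measurement table
#'
#' @param measurements data.frame with \code{cell_id}, \code{deflection},
#'   \code{amplitude}, optionally \code{responded}.
#' @return data.frame with one [classifyResponder()] row per cell.
#' @export
summarizeCells <- function(measurements) {
  out <- lapply(split(measurements, measurements$cell_id), classifyResponder)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare two groups' stimulus-response data
#'
#' Per-bin Mann-Whitney comparison of the per-cell bin means (a bin in
#' which every value of both groups is zero, or which one group never
#' sampled, is reported NA), Fisher's exact test on responder fractions,
#' and a Mann-Whitney comparison of per-cell thresholds.
#'
#' @param groupA,groupB lists with elements \code{binned} (a
#'   [binResponses()] result) and \code{cells} (a [summarizeCells()]
#'   result).
#' @return list: \code{per_bin} data.frame (bin, meanA, meanB, U, p),
#'   \code{responder} (fractions, Fisher p), \code{threshold} (means,
#'   Mann-Whitney p).
#' @export
compareGroups <- function(groupA, groupB) {
  la <- groupA$binned$scheme$labels
  stopifnot(identical(la, groupB$binned$scheme$labels))
  perBin <- lapply(seq_along(la), function(bi) {
    va <- groupA$binned$per_cell_bin_means[, bi]
    vb <- groupB$binned$per_cell_bin_means[, bi]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (!length(va) || !length(vb) || (all(va == 0) && all(vb == 0)))
      return(data.frame(bin = la[bi], meanA = NA_real_, meanB = NA_real_,
                        U = NA_real_, p = NA_real_))
    mw <- mannWhitneyTest(va, vb)
    data.frame(bin = la[bi], meanA = mean(va), meanB = mean(vb),
               U = mw$U, p = mw$p)
  })
  perBin <- do.call(rbind, perBin)

  ra <- sum(groupA$cells$responder); na <- nrow(groupA$cells)
  rb <- sum(groupB$cells$responder); nb <- nrow(groupB$cells)
  fish <- fisherExactTest(ra, na - ra, rb, nb - rb)

  ta <- groupA$cells$threshold[!is.na(groupA$cells$threshold)]
  tb <- groupB$cells$threshold[!is.na(groupB$cells$threshold)]
  thr <- if (length(ta) && length(tb)) {
    mw <- mannWhitneyTest(ta, tb)
    list(meanA = mean(ta), meanB = mean(tb), U = mw$U, p = mw$p)
  } else list(meanA = NA_real_, meanB = NA_real_, U = NA_real_,
              p = NA_real_)

  list(per_bin = perBin,
       responder = list(fractionA = ra / na, fractionB = rb / nb,
                        nA = na, nB = nb, fisher_p = fish$p),
       threshold = thr)
}
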