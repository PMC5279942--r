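# File interfaces: scenes as multi-page TIFF + JSON truth sidecar,
# traces and cohort tables as CSV with a JSON metadata header file.

#' Write a pillar scene to a multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per frame role; intensities are stored scaled to [0, 1]
#' (the scale factor, frame roles, generator parameters and the truth
#' table go into \code{<path>.json}) so the scene round-trips exactly in
#' 32-bit float.
#'
#' @param scene a [PillarScene-class].
#' @param path output TIFF path.
#' @return invisibly, the sidecar path.
#' @export
writePillarScene <- function(scene, path) {
  stopifnot(is(scene, "PillarScene"))
  fr <- frames(scene)
  scale <- max(vapply(fr, max, numeric(1)))
  tiff::writeTIFF(lapply(fr, function(m) pmax(m, 0) / scale), path,
                  bits.per.sample = 32L)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(roles = names(fr), scale = scale, pixel_size_nm = pixelSize(scene),
         params = scene@params, truth = sceneTruth(scene)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a pillar scene written by [writePillarScene()]
#'
#' @param path TIFF path (expects \code{<path>.json} alongside).
#' @return a [PillarScene-class].
#' @export
readPillarScene <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  fr <- lapply(pages, function(m) m * meta$scale)
  names(fr) <- meta$roles
  params <- meta$params
  # JSON round-trips length-2 vectors as lists of scalars
  for (k in c("trueDeflection", "driftNm"))
    if (!is.null(params[[k]])) params[[k]] <- as.numeric(unlist(params[[k]]))
  new("PillarScene", frames = fr, pixelSize = meta$pixel_size_nm,
      truth = as.data.frame(meta$truth), params = as.list(params))
}

#' Write a current trace as CSV plus JSON metadata
#'
#' CSV columns \code{time_ms}, \code{current_pA}; sampling rate, holding
#' potential, stimulus onset, ids and generator truth go to
#' \code{<path>.json}.
#'
#' @param trace a [CurrentTrace-class].
#' @param path output CSV path.
#' @return invisibly, the sidecar path.
#' @export
writeCurrentTrace <- function(trace, path) {
  stopifnot(is(trace, "CurrentTrace"))
  utils::write.csv(data.frame(time_ms = traceTime(trace),
                              current_pA = current(trace)),
                   path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  md <- trace@metadata
  md$truth <- NULL
  jsonlite::write_json(
    list(sampling_rate_hz = samplingRate(trace),
         holding_potential_mv = holdingPotential(trace),
         stimulus_onset_ms = stimulusOnset(trace),
         ids = as.list(trace@ids), metadata = md,
         truth = traceTruth(trace)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a current trace written by [writeCurrentTrace()]
#'
#' @param path CSV path (expects \code{<path>.json} alongside).
#' @return a [CurrentTrace-class].
#' @export
readCurrentTrace <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  md <- as.list(meta$metadata)
  md$truth <- if (length(meta$truth)) as.data.frame(meta$truth)
              else data.frame()
  ids <- unlist(meta$ids)
  if (is.null(ids)) ids <- character(0)
  new("CurrentTrace", current = d$current_pA,
      samplingRate = meta$sampling_rate_hz,
      holdingPotential = meta$holding_potential_mv,
      stimulusOnset = meta$stimulus_onset_ms,
      ids = ids, metadata = md)
}

#' Read a pressure family from a per-patch CSV
#'
#' Expected columns \code{pressure_mmHg}, \code{peak_pA}.
#'
#' @param path CSV path.
#' @param patchId,configuration,holdingPotential stored in the object.
#' @return a [PressureFamily-class].
#' @export
readPressureFamily <- function(path, patchId = basename(path),
                               configuration = "outside-out",
                               holdingPotential = -60) {
  d <- utils::read.csv(path)
  stopifnot(all(c("pressure_mmHg", "peak_pA") %in% names(d)))
  o <- order(abs(d$pressure_mmHg))
  new("PressureFamily", pressures = abs(d$pressure_mmHg)[o],
      peakCurrents = d$peak_pA[o], patchId = patchId,
      configuration = configuration, holdingPotential = holdingPotential,
      metadata = list(source = path))
}

#' Write a pressure family to CSV
#'
#' @param fam a [PressureFamily-class].
#' @param path CSV path.
#' @export
writePressureFamily <- function(fam, path) {
  utils::write.csv(data.frame(pressure_mmHg = pressures(fam),
                              peak_pA = peakCurrents(fam)),
                   path, row.names = FALSE)
  invisible(path)
}
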