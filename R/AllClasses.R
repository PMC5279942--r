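#' @import methods
NULL

#' Cylindrical pilus geometry
#'
#' Elastomer and cylinder parameters of one pilus in a pillar array:
#' Young's modulus of the cured elastomer and the radius and length of the
#' cylinder. These three numbers determine the bending spring constant of
#' the pilus (see [springConstant()]).
#'
#' @slot E Young's modulus of the elastomer, MPa. Note 1 MPa == 1 pN/nm^2
#'   exactly, which is what makes the pN/nm spring-constant unit fall out
#'   of the beam formula without any numerical fudge factor.
#' @slot r pilus radius, micrometres.
#' @slot L pilus length, micrometres.
#'
#' @examples
#' geom <- PillarGeometry(E = 2.1, r = 1.79, L = 5.87)
#' springConstant(geom)
#' @export
setClass("PillarGeometry",
  representation(E = "numeric", r = "numeric", L = "numeric"),
  prototype(E = 2.1, r = 1.79, L = 5.87))

setValidity("PillarGeometry", function(object) {
  msg <- character(0)
  for (s in c("E", "r", "L")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive finite number", s))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PillarGeometry-class Constructor.
#' @param E,r,L see slots.
#' @export
PillarGeometry <- function(E = 2.1, r = 1.79, L = 5.87) {
  new("PillarGeometry", E = as.numeric(E), r = as.numeric(r), L = as.numeric(L))
}

#' Synthetic bright-field pillar-array scene
#'
#' One simulated stimulation episode: a bright-field frame of the pillar
#' array taken before the stimulus, one during, and one after release,
#' together with the ground-truth spot centers used to render them.
#' Frames are numeric matrices in counts; truth centers are stored in
#' pixel units (0-based, pixel-center convention) so localization accuracy
#' can be scored exactly.
#'
#' @slot frames named list of numeric matrices, names from
#'   \code{c("before","during","after")}, identical dimensions.
#' @slot pixelSize nm per pixel.
#' @slot truth data.frame with one row per pilus per frame role:
#'   \code{pilus_id}, \code{role}, \code{cx}, \code{cy} (px),
#'   \code{deflected} (logical).
#' @slot params list echoing every generator parameter (including the seed),
#'   so a scene is self-describing and regenerable.
#' @export
setClass("PillarScene",
  representation(frames = "list", pixelSize = "numeric",
                 truth = "data.frame", params = "list"))

setValidity("PillarScene", function(object) {
  msg <- character(0)
  if (!all(names(object@frames) %in% c("before", "during", "after")))
    msg <- c(msg, "frame names must be among before/during/after")
  if (length(object@frames) == 0L)
    msg <- c(msg, "at least one frame required")
  dims <- lapply(object@frames, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) > 1L)
    msg <- c(msg, "all frames must share dimensions")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  need <- c("pilus_id", "role", "cx", "cy", "deflected")
  if (!all(need %in% names(object@truth)))
    msg <- c(msg, "truth must carry pilus_id, role, cx, cy, deflected")
  if (length(msg)) msg else TRUE
})

#' Statistical phenotype of a mechanically gated channel population
#'
#' Per-event kinetic parameter distributions (latency, activation tau1,
#' decay tau2, peak amplitude), the probability that a cell responds to at
#' least one deflection in the 1-1000 nm range, and the distribution of
#' per-cell gating thresholds. Event-level parameters are drawn log-normally
#' around the stated means (kinetic source data are right-skewed and all
#' quantities are positive); a zero sd collapses the draw to the mean.
#'
#' Presets for the cell types studied on pillar arrays are available via
#' [presetPhenotype()].
#'
#' @slot name label, e.g. "chondrocyte-WT".
#' @slot latencyMean,latencySd ms.
#' @slot tau1Mean,tau1Sd ms.
#' @slot tau2Mean,tau2Sd ms.
#' @slot peakAmpMean,peakAmpSd pA (magnitude of the inward current).
#' @slot responderProb probability a cell shows >= 1 gated current.
#' @slot thresholdMean,thresholdSd nm, per-cell smallest gating deflection.
#' @slot rectifyingTau2 logical; TRUE means the decay slows at positive
#'   holding potentials (PIEZO1-like), FALSE means decay and amplitude are
#'   potential-independent (TRPV4-like).
#' @export
setClass("ChannelPhenotype",
  representation(name = "character",
                 latencyMean = "numeric", latencySd = "numeric",
                 tau1Mean = "numeric", tau1Sd = "numeric",
                 tau2Mean = "numeric", tau2Sd = "numeric",
                 peakAmpMean = "numeric", peakAmpSd = "numeric",
                 responderProb = "numeric",
                 thresholdMean = "numeric", thresholdSd = "numeric",
                 rectifyingTau2 = "logical"))

setValidity("ChannelPhenotype", function(object) {
  msg <- character(0)
  pos <- c("latencyMean", "tau1Mean", "tau2Mean", "peakAmpMean", "thresholdMean")
  for (s in pos) if (slot(object, s) <= 0)
    msg <- c(msg, sprintf("'%s' must be > 0", s))
  nneg <- c("latencySd", "tau1Sd", "tau2Sd", "peakAmpSd", "thresholdSd")
  for (s in nneg) if (slot(object, s) < 0)
    msg <- c(msg, sprintf("'%s' must be >= 0", s))
  if (object@responderProb < 0 || object@responderProb > 1)
    msg <- c(msg, "responderProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Whole-cell current trace with stimulus annotation
#'
#' A sampled membrane-current recording. Currents are in pA with the
#' physiological sign convention: inward currents are negative deflections
#' from the baseline. The stimulus onset is annotated in ms from the start
#' of the trace.
#'
#' @slot current numeric vector, pA.
#' @slot samplingRate Hz.
#' @slot holdingPotential mV.
#' @slot stimulusOnset ms from trace start.
#' @slot ids named character vector (cell_id, stimulus_id, pilus_id -- any
#'   subset).
#' @slot metadata list; the synthetic generator stores the filter cutoff
#'   used during acquisition emulation and the ground-truth event kinetics
#'   here (element \code{truth}, a data.frame, empty if no event).
#' @export
setClass("CurrentTrace",
  representation(current = "numeric", samplingRate = "numeric",
                 holdingPotential = "numeric", stimulusOnset = "numeric",
                 ids = "character", metadata = "list"))

setValidity("CurrentTrace", function(object) {
  msg <- character(0)
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  dur <- length(object@current) / object@samplingRate * 1000
  if (length(object@stimulusOnset) != 1L ||
      object@stimulusOnset < 0 || object@stimulusOnset >= dur)
    msg <- c(msg, "stimulusOnset must lie within the trace")
  if (length(msg)) msg else TRUE
})

#' High-speed pressure-clamp step family
#'
#' Peak currents evoked by a family of pressure steps applied to one
#' membrane patch. Cell-attached protocols use negative pressures of the
#' same magnitudes as the outside-out positive steps; analysis operates on
#' pressure magnitudes throughout.
#'
#' @slot pressures mmHg, strictly increasing magnitudes.
#' @slot peakCurrents pA, one per step (magnitudes).
#' @slot patchId identifier.
#' @slot configuration "outside-out" or "cell-attached".
#' @slot holdingPotential mV.
#' @slot metadata list (generator truth etc.).
#' @export
setClass("PressureFamily",
  representation(pressures = "numeric", peakCurrents = "numeric",
                 patchId = "character", configuration = "character",
                 holdingPotential = "numeric", metadata = "list"),
  prototype(configuration = "outside-out", holdingPotential = -60,
            patchId = "patch1", metadata = list()))

setValidity("PressureFamily", function(object) {
  msg <- character(0)
  if (length(object@pressures) != length(object@peakCurrents))
    msg <- c(msg, "pressures and peakCurrents must have equal length")
  if (length(object@pressures) && any(diff(object@pressures) <= 0))
    msg <- c(msg, "pressures must be strictly increasing")
  if (!object@configuration %in% c("outside-out", "cell-attached"))
    msg <- c(msg, "configuration must be outside-out or cell-attached")
  if (length(msg)) msg else TRUE
})

#' Boltzmann fit of a normalized pressure-response curve
#'
#' Result of fitting y(P) = 1 / (1 + exp((P50 - P) / slope)) to the
#' normalized peak currents of one patch.
#'
#' @slot p50 mmHg, pressure of half-maximal activation.
#' @slot slope mmHg, positive (response grows with pressure).
#' @slot imax pA, the maximal current magnitude of the family before
#'   normalization.
#' @slot fitQuality normalized RMS residual of the fit.
#' @slot converged logical.
#' @export
setClass("BoltzmannFit",
  representation(p50 = "numeric", slope = "numeric", imax = "numeric",
                 fitQuality = "numeric", converged = "logical"))

setValidity("BoltzmannFit", function(object) {
  if (isTRUE(object@converged) && object@slope <= 0)
    "slope must be > 0 for a converged fit" else TRUE
})

#' Single-cell fluorescence time series with agonist epochs
#'
#' Raw fluorescence intensities of one cell sampled at a fixed frame
#' interval, with labeled agonist-application epochs. The first
#' \code{nBaselineFrames} frames precede all epochs and define F0 for
#' dF/F normalization.
#'
#' @slot intensities counts, > 0.
#' @slot frameInterval s between frames.
#' @slot nBaselineFrames frames used for F0.
#' @slot cellId identifier.
#' @slot epochs data.frame: \code{label}, \code{start} (s), \code{duration}
#'   (s), optionally \code{truth_amplitude} (counts) from the generator.
#' @export
setClass("FluorescenceTrace",
  representation(intensities = "numeric", frameInterval = "numeric",
                 nBaselineFrames = "integer", cellId = "character",
                 epochs = "data.frame"))

setValidity("FluorescenceTrace", function(object) {
  msg <- character(0)
  if (any(object@intensities <= 0))
    msg <- c(msg, "intensities must be > 0")
  if (object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be > 0")
  if (object@nBaselineFrames < 1L)
    msg <- c(msg, "need at least one baseline frame")
  if (nrow(object@epochs)) {
    baselineEnd <- object@nBaselineFrames * object@frameInterval
    if (any(object@epochs$start < baselineEnd))
      msg <- c(msg, "baseline frames must precede all epochs")
    ep <- object@epochs[order(object@epochs$start), , drop = FALSE]
    if (nrow(ep) > 1L &&
        any(ep$start[-1] < (ep$start + ep$duration)[-nrow(ep)]))
      msg <- c(msg, "epochs must not overlap")
  }
  if (length(msg)) msg else TRUE
})
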