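#' Accessors for mechanopillar S4 classes
#'
#' Slot access for the package's data containers; use these rather than
#' \code{@}.
#'
#' @name accessors
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setMethod("frames", "PillarScene", function(object) object@frames)

#' @rdname accessors
#' @export
setMethod("pixelSize", "PillarScene", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setMethod("sceneTruth", "PillarScene", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("current", "CurrentTrace", function(object) object@current)

#' @rdname accessors
#' @export
setMethod("samplingRate", "CurrentTrace", function(object) object@samplingRate)

#' @rdname accessors
#' @export
setMethod("stimulusOnset", "CurrentTrace", function(object) object@stimulusOnset)

#' @rdname accessors
#' @export
setMethod("holdingPotential", "CurrentTrace", function(object) object@holdingPotential)

#' @rdname accessors
#' @export
setMethod("holdingPotential", "PressureFamily", function(object) object@holdingPotential)

#' @rdname accessors
#' @export
setMethod("traceTime", "CurrentTrace", function(object)
  (seq_along(object@current) - 1) / object@samplingRate * 1000)

#' @rdname accessors
#' @export
setMethod("traceTruth", "CurrentTrace", function(object) {
  tr <- object@metadata$truth
  if (is.null(tr)) data.frame() else tr
})

#' @rdname accessors
#' @export
setMethod("pressures", "PressureFamily", function(object) object@pressures)

#' @rdname accessors
#' @export
setMethod("peakCurrents", "PressureFamily", function(object) object@peakCurrents)

#' @rdname accessors
#' @export
setMethod("intensities", "FluorescenceTrace", function(object) object@intensities)

#' @rdname accessors
#' @export
setMethod("epochs", "FluorescenceTrace", function(object) object@epochs)

setMethod("show", "PillarGeometry", function(object) {
  cat(sprintf("PillarGeometry: E = %g MPa, r = %g um, L = %g um  (k = %.1f pN/nm)\n",
              object@E, object@r, object@L, springConstant(object)))
})

setMethod("show", "PillarScene", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("PillarScene: %d frame(s) [%s], %dx%d px @ %g nm/px, %d pili\n",
              length(object@frames), paste(names(object@frames), collapse = ","),
              d[1], d[2], object@pixelSize,
              length(unique(object@truth$pilus_id))))
})

setMethod("show", "ChannelPhenotype", function(object) {
  cat(sprintf(paste0(
    "ChannelPhenotype '%s':\n",
    "  latency %.2g (sd %.2g) ms, tau1 %.2g (sd %.2g) ms, tau2 %.2g (sd %.2g) ms\n",
    "  peak amplitude %.3g (sd %.2g) pA, responder prob %.3g\n",
    "  threshold %.3g (sd %.2g) nm, rectifying tau2: %s\n"),
    object@name, object@latencyMean, object@latencySd, object@tau1Mean,
    object@tau1Sd, object@tau2Mean, object@tau2Sd, object@peakAmpMean,
    object@peakAmpSd, object@responderProb, object@thresholdMean,
    object@thresholdSd, object@rectifyingTau2))
})

setMethod("show", "CurrentTrace", function(object) {
  cat(sprintf(paste0("CurrentTrace: %d samples @ %g kHz (%.1f ms), Vh %g mV, ",
                     "stimulus at %g ms, %d truth event(s)\n"),
              length(object@current), object@samplingRate / 1000,
              length(object@current) / object@samplingRate * 1000,
              object@holdingPotential, object@stimulusOnset,
              nrow(traceTruth(object))))
})

setMethod("show", "PressureFamily", function(object) {
  cat(sprintf("PressureFamily '%s' (%s, Vh %g mV): %d steps %g..%g mmHg\n",
              object@patchId, object@configuration, object@holdingPotential,
              length(object@pressures), min(object@pressures),
              max(object@pressures)))
})

setMethod("show", "BoltzmannFit", function(object) {
  cat(sprintf("BoltzmannFit: P50 = %.2f mmHg, slope = %.2f mmHg, Imax = %.2f pA (rms %.2g, %s)\n",
              object@p50, object@slope, object@imax, object@fitQuality,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "FluorescenceTrace", function(object) {
  cat(sprintf("FluorescenceTrace '%s': %d frames @ %gs, %d baseline, epochs: %s\n",
              object@cellId, length(object@intensities), object@frameInterval,
              object@nBaselineFrames,
              paste(object@epochs$label, collapse = ", ")))
})
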