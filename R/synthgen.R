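# Seeded generators for every input class the pipeline consumes. All
# randomness is drawn inside withLocalSeed() so generators are pure
# functions of their arguments and do not disturb the caller's RNG.

withLocalSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

# log-normal draw parameterized by arithmetic mean and sd; sd 0 collapses
# to the mean (used for noiseless/deterministic generation)
rlnormMeanSd <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  sdlog <- sqrt(log1p((sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# moments of a log-normal truncated to (0, upper]
lnormTruncMoments <- function(meanlog, sdlog, upper) {
  lu <- log(upper)
  p <- stats::pnorm((lu - meanlog) / sdlog)
  m1 <- exp(meanlog + sdlog^2 / 2) *
    stats::pnorm((lu - meanlog - sdlog^2) / sdlog) / p
  m2 <- exp(2 * meanlog + 2 * sdlog^2) *
    stats::pnorm((lu - meanlog - 2 * sdlog^2) / sdlog) / p
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# draw from a log-normal truncated to (0, upper], with (meanlog, sdlog)
# solved so the TRUNCATED moments match the requested mean and sd: cohort
# threshold statistics are computed from observed (range-limited) values,
# so the generator must reproduce them after truncation, not before
rlnormMeanSdTrunc <- function(n, mean, sd, upper) {
  if (mean > upper) stop("truncated mean must lie below the upper bound")
  if (sd <= 0) return(rep(mean, n))
  sdlog0 <- sqrt(log1p((sd / mean)^2))
  start <- c(log(mean) - sdlog0^2 / 2, sdlog0)
  obj <- function(par) {
    if (par[2] <= 0) return(1e12)
    m <- lnormTruncMoments(par[1], par[2], upper)
    (m["mean"] / mean - 1)^2 + (m["sd"] / sd - 1)^2
  }
  par <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))$par
  pU <- stats::plnorm(upper, par[1], par[2])
  stats::qlnorm(stats::runif(n) * pU, par[1], par[2])
}

#' Generate a synthetic bright-field pillar-array scene
#'
#' Renders each frame as a square grid of isotropic 2D Gaussian spots on a
#' constant background (the pili act as light guides and image as bright
#' spots), with optional Gaussian read noise and Poisson shot noise. One
#' designated pilus is displaced by \code{trueDeflection} in the "during"
#' frame only; exact spot centers are stored in the truth table.
#'
#' @param gridPitch spot spacing, nm.
#' @param spotSigma Gaussian spot sigma, nm; must exceed half a pixel so
#'   spots are resolvable.
#' @param pixelSize nm per pixel.
#' @param peakAmplitude spot peak over background, counts.
#' @param background constant background, counts.
#' @param readNoiseSd Gaussian read noise sd, counts (0 = noiseless).
#' @param shotNoise logical, add Poisson noise with the pixel mean.
#' @param trueDeflection 2-vector (nm), applied to the designated pilus in
#'   the "during" frame. Magnitude above \code{gridPitch / 2} would walk
#'   the pilus into its neighbour and is rejected.
#' @param frameRoles subset of \code{c("before","during","after")}.
#' @param nGrid pili per side of the square grid.
#' @param deflectedPilus id of the displaced pilus (default: central one).
#' @param driftNm optional 2-vector (nm): rigid stage drift applied to all
#'   pili in the "during" frame (for testing reference-pillar correction).
#' @param seed integer or NULL.
#' @return a [PillarScene-class].
#' @examples
#' sc <- generatePillarScene(trueDeflection = c(100, 0), seed = 1)
#' sc
#' @export
generatePillarScene <- function(gridPitch = 4160, spotSigma = 600,
                                pixelSize = 161, peakAmplitude = 2000,
                                background = 200, readNoiseSd = 0,
                                shotNoise = FALSE,
                                trueDeflection = c(0, 0),
                                frameRoles = c("before", "during", "after"),
                                nGrid = 5, deflectedPilus = NULL,
                                driftNm = c(0, 0), seed = NULL) {
  stopifnot(pixelSize > 0, gridPitch > 0, peakAmplitude > 0)
  if (spotSigma <= pixelSize / 2)
    stop("spotSigma must exceed pixelSize/2 (spots unresolvable)")
  frameRoles <- match.arg(frameRoles, several.ok = TRUE)
  if (sqrt(sum(trueDeflection^2)) > gridPitch / 2)
    stop("deflection exceeds gridPitch/2: pillar collision")

  pitchPx <- gridPitch / pixelSize
  sigmaPx <- spotSigma / pixelSize
  margin <- ceiling(4 * sigmaPx + 4)
  side <- ceiling((nGrid - 1) * pitchPx + 2 * margin) + 1
  gx <- margin + (seq_len(nGrid) - 1) * pitchPx
  centers <- expand.grid(cx = gx, cy = gx)                 # x fastest
  centers$pilus_id <- sprintf("p%02d", seq_len(nrow(centers)))
  if (is.null(deflectedPilus))
    deflectedPilus <- centers$pilus_id[ceiling(nrow(centers) / 2)]
  if (!deflectedPilus %in% centers$pilus_id)
    stop("unknown deflectedPilus id")

  renderFrame <- function(cxs, cys) {
    img <- matrix(background, nrow = side, ncol = side)    # row = y, col = x
    half <- ceiling(5 * sigmaPx)
    for (i in seq_along(cxs)) {
      jx <- max(1, floor(cxs[i]) - half):min(side, ceiling(cxs[i]) + half)
      iy <- max(1, floor(cys[i]) - half):min(side, ceiling(cys[i]) + half)
      # pixel (iy, jx) has 0-based center (jx-1, iy-1)
      gxv <- exp(-((jx - 1 - cxs[i])^2) / (2 * sigmaPx^2))
      gyv <- exp(-((iy - 1 - cys[i])^2) / (2 * sigmaPx^2))
      img[iy, jx] <- img[iy, jx] + peakAmplitude * outer(gyv, gxv)
    }
    img
  }

  withLocalSeed(seed, {
    framesList <- list()
    truth <- NULL
    for (role in c("before", "during", "after")) {
      if (!role %in% frameRoles) next
      cxs <- centers$cx; cys <- centers$cy
      defl <- rep(FALSE, nrow(centers))
      if (role == "during") {
        cxs <- cxs + driftNm[1] / pixelSize
        cys <- cys + driftNm[2] / pixelSize
        k <- match(deflectedPilus, centers$pilus_id)
        cxs[k] <- cxs[k] + trueDeflection[1] / pixelSize
        cys[k] <- cys[k] + trueDeflection[2] / pixelSize
        defl[k] <- TRUE
      }
      img <- renderFrame(cxs, cys)
      if (shotNoise) img <- matrix(stats::rpois(length(img), img),
                                   nrow = side)
      if (readNoiseSd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, readNoiseSd),
                            nrow = side)
      framesList[[role]] <- img
      truth <- rbind(truth, data.frame(
        pilus_id = centers$pilus_id, role = role, cx = cxs, cy = cys,
        deflected = defl, stringsAsFactors = FALSE))
    }
    new("PillarScene", frames = framesList, pixelSize = pixelSize,
        truth = truth,
        params = list(gridPitch = gridPitch, spotSigma = spotSigma,
                      pixelSize = pixelSize, peakAmplitude = peakAmplitude,
                      background = background, readNoiseSd = readNoiseSd,
                      shotNoise = shotNoise, trueDeflection = trueDeflection,
                      nGrid = nGrid, deflectedPilus = deflectedPilus,
                      driftNm = driftNm, seed = seed))
  })
}

#' Generate a synthetic whole-cell current trace
#'
#' Simulates one stimulation sweep: baseline Gaussian current noise plus,
#' if the cell responds and the applied deflection reaches its gating
#' threshold, a mechanically gated current starting \code{latency} after
#' stimulus onset, rising as A(1 - exp(-t/tau1)) for five activation time
#' constants and decaying as A exp(-t/tau2). Inward currents are negative;
#' at positive holding potentials the current is outward (positive). The
#' whole trace is passed through a causal Bessel low-pass emulating the
#' acquisition filter. Drawn per-event parameters are recorded as ground
#' truth in the trace metadata.
#'
#' @param phenotype a [ChannelPhenotype-class].
#' @param deflection applied pilus deflection, nm (>= 0).
#' @param samplingRate Hz.
#' @param filterCutoff acquisition low-pass -3 dB frequency, Hz
#'   (must be < Nyquist); NA disables filtering.
#' @param filterOrder Bessel order.
#' @param duration trace length, ms.
#' @param baselineNoiseSd pA.
#' @param holdingPotential mV.
#' @param stimulusOnset ms.
#' @param ids named character vector of identifiers.
#' @param forceResponder logical or NULL; overrides the responder draw
#'   (and threshold gating) when not NULL.
#' @param seed integer or NULL.
#' @return a [CurrentTrace-class]; \code{traceTruth()} holds the drawn
#'   kinetics (zero rows when no event was generated).
#' @examples
#' ph <- channelPhenotype("demo", latencyMean = 3.6, tau1Mean = 1.7,
#'                        tau2Mean = 12.2, peakAmpMean = 50,
#'                        thresholdMean = 100)
#' tr <- generateCurrentTrace(ph, deflection = 300, baselineNoiseSd = 0)
#' traceTruth(tr)
#' @export
generateCurrentTrace <- function(phenotype, deflection,
                                 samplingRate = 10000, filterCutoff = 3000,
                                 filterOrder = 4, duration = 150,
                                 baselineNoiseSd = 1,
                                 holdingPotential = -40,
                                 stimulusOnset = 50,
                                 ids = c(cell_id = "cell1"),
                                 forceResponder = NULL, seed = NULL) {
  stopifnot(is(phenotype, "ChannelPhenotype"), deflection >= 0,
            stimulusOnset < duration)
  if (!is.na(filterCutoff) && filterCutoff >= samplingRate / 2)
    stop("filterCutoff must be below the Nyquist frequency")
  n <- round(duration / 1000 * samplingRate)
  dt_ms <- 1000 / samplingRate

  withLocalSeed(seed, {
    isResp <- if (is.null(forceResponder)) {
      resp <- stats::runif(1) < phenotype@responderProb
      thr <- rlnormMeanSd(1, phenotype@thresholdMean, phenotype@thresholdSd)
      resp && deflection >= thr
    } else isTRUE(forceResponder)

    sig <- numeric(n)
    truth <- data.frame()
    if (isResp) {
      latency <- rlnormMeanSd(1, phenotype@latencyMean, phenotype@latencySd)
      tau1 <- rlnormMeanSd(1, phenotype@tau1Mean, phenotype@tau1Sd)
      tau2m <- phenotype@tau2Mean
      if (phenotype@rectifyingTau2 && holdingPotential > 0)
        tau2m <- tau2m * 3          # decay slows at depolarized potentials
      tau2 <- rlnormMeanSd(1, tau2m, phenotype@tau2Sd)
      amp <- rlnormMeanSd(1, phenotype@peakAmpMean, phenotype@peakAmpSd)
      sgn <- if (holdingPotential > 0) 1 else -1
      t0 <- stimulusOnset + latency
      tEndRise <- t0 + 5 * tau1
      tms <- (seq_len(n) - 1) * dt_ms
      rise <- tms >= t0 & tms < tEndRise
      sig[rise] <- amp * (1 - exp(-(tms[rise] - t0) / tau1))
      peakVal <- amp * (1 - exp(-5))
      dec <- tms >= tEndRise
      sig[dec] <- peakVal * exp(-(tms[dec] - tEndRise) / tau2)
      sig <- sgn * sig
      truth <- data.frame(latency = latency, tau1 = tau1, tau2 = tau2,
                          amplitude = amp, peak = peakVal,
                          onset_ms = t0, peak_ms = tEndRise, sign = sgn)
    }
    if (baselineNoiseSd > 0)
      sig <- sig + stats::rnorm(n, 0, baselineNoiseSd)
    if (!is.na(filterCutoff))
      sig <- lowpassFilter(sig, filterCutoff, samplingRate, filterOrder)
    new("CurrentTrace", current = sig, samplingRate = samplingRate,
        holdingPotential = holdingPotential, stimulusOnset = stimulusOnset,
        ids = ids,
        metadata = list(truth = truth, filterCutoff = filterCutoff,
                        filterOrder = filterOrder,
                        baselineNoiseSd = baselineNoiseSd,
                        deflection = deflection, seed = seed))
  })
}

#' Generate a synthetic pressure-clamp step family
#'
#' Peak current at step pressure P follows the Boltzmann relation
#' imax / (1 + exp((p50 - P) / slope)) plus Gaussian noise. The default
#' protocol is 10 to 150 mmHg in 20 mmHg steps (600 ms steps at 0.1 Hz in
#' the emulated experiment; only peak currents are modeled here).
#'
#' @param p50 half-activation pressure, mmHg.
#' @param slope Boltzmann slope, mmHg; must be > 0.
#' @param imax saturating current, pA.
#' @param steps pressure magnitudes, strictly increasing, mmHg.
#' @param noiseSd pA.
#' @param patchId identifier.
#' @param configuration "outside-out" (positive steps) or "cell-attached"
#'   (negative steps of the same magnitudes; stored as magnitudes).
#' @param seed integer or NULL.
#' @return a [PressureFamily-class] with generator truth in metadata.
#' @examples
#' fam <- generatePressureFamily(87.1, 18, 45.2, seed = 1)
#' fitBoltzmann(normalizeFamily(fam))
#' @export
generatePressureFamily <- function(p50, slope, imax,
                                   steps = seq(10, 150, by = 20),
                                   noiseSd = 0, patchId = "patch1",
                                   configuration = "outside-out",
                                   seed = NULL) {
  if (slope <= 0) stop("slope must be > 0")
  if (any(diff(steps) <= 0)) stop("steps must be strictly increasing")
  withLocalSeed(seed, {
    mu <- imax / (1 + exp((p50 - steps) / slope))
    y <- mu + if (noiseSd > 0) stats::rnorm(length(steps), 0, noiseSd) else 0
    new("PressureFamily", pressures = as.numeric(steps),
        peakCurrents = as.numeric(y), patchId = patchId,
        configuration = configuration, holdingPotential = -60,
        metadata = list(truth = list(p50 = p50, slope = slope, imax = imax),
                        noiseSd = noiseSd, seed = seed))
  })
}

#' Generate a synthetic cell cohort with per-cell stimulus series
#'
#' Draws, per cell: a responder flag (Bernoulli with the phenotype's
#' responder probability) and, for responders, a gating threshold from a
#' log-normal truncated to the probed range (0, 1000] whose truncated
#' moments match the phenotype threshold mean and sd -- a responder is by
#' definition a cell whose threshold lies within the probed range, and
#' cohort threshold statistics are computed from such range-limited
#' observations. Each cell then receives a deflection series
#' emulating the ramp protocol: a fixed probe set spanning 1-1000 nm plus,
#' for responders, the threshold-crossing stimulus itself (the experiment
#' records the first deflection that gates the channel, which sits at the
#' cell's threshold). Sweeps at or above threshold in responders carry a
#' gated current whose amplitude is drawn around the phenotype amplitude
#' mean; all other sweeps have amplitude 0.
#'
#' @param phenotypes named list of [ChannelPhenotype-class] objects, one
#'   per group.
#' @param nCells named integer vector (same names), cells per group.
#' @param probeDeflections fixed stimulus set applied to every cell, nm.
#' @param seed integer or NULL.
#' @return list with \code{cells} (cell_id, group, responder, threshold)
#'   and \code{measurements} (cell_id, group, deflection, amplitude,
#'   responded).
#' @examples
#' pop <- generatePopulation(
#'   list(WT = presetPhenotype("chondrocyte-WT")), c(WT = 5), seed = 1)
#' head(pop$measurements)
#' @export
generatePopulation <- function(phenotypes, nCells,
                               probeDeflections = c(5, 10, 25, 50, 100,
                                                    175, 250, 375, 500,
                                                    750, 1000),
                               seed = NULL) {
  stopifnot(is.list(phenotypes), length(phenotypes) >= 1,
            all(names(phenotypes) %in% names(nCells)),
            all(nCells[names(phenotypes)] >= 1))
  withLocalSeed(seed, {
    cellRows <- list(); measRows <- list()
    for (g in names(phenotypes)) {
      ph <- phenotypes[[g]]
      nC <- nCells[[g]]
      # per-cell draws vectorized per group; the truncated-threshold
      # parameters are solved once per phenotype
      isResp <- stats::runif(nC) < ph@responderProb
      thrs <- rlnormMeanSdTrunc(nC, ph@thresholdMean, ph@thresholdSd, 1000)
      for (i in seq_len(nC)) {
        id <- sprintf("%s_c%03d", g, i)
        thr <- thrs[i]
        stim <- probeDeflections
        if (isResp[i]) stim <- sort(unique(c(stim, thr)))
        gated <- isResp[i] & stim >= thr
        amp <- ifelse(gated,
                      rlnormMeanSd(length(stim), ph@peakAmpMean,
                                   ph@peakAmpSd), 0)
        cellRows[[id]] <- data.frame(
          cell_id = id, group = g, responder = isResp[i],
          threshold = if (isResp[i]) thr else NA_real_,
          stringsAsFactors = FALSE)
        measRows[[id]] <- data.frame(
          cell_id = id, group = g, deflection = stim, amplitude = amp,
          responded = gated, stringsAsFactors = FALSE)
      }
    }
    cells <- do.call(rbind, cellRows)
    meas <- do.call(rbind, measRows)
    rownames(cells) <- rownames(meas) <- NULL
    list(cells = cells, measurements = meas)
  })
}

#' Generate a synthetic single-cell fluorescence trace
#'
#' Constant baseline fluorescence with a step-plus-decay calcium transient
#' in each agonist epoch: intensity jumps by the epoch amplitude for the
#' epoch duration and decays exponentially after washout. Gaussian noise
#' is added per frame; intensities are floored just above zero so the
#' trace remains a valid photon count series.
#'
#' @param baseline counts.
#' @param epochs data.frame with \code{label}, \code{start} (s),
#'   \code{duration} (s), \code{amplitude} (counts); non-overlapping, all
#'   after the baseline frames.
#' @param frameInterval s per frame (imaging cycle).
#' @param nBaselineFrames initial frames defining F0.
#' @param noiseSd counts.
#' @param decayTau washout decay time constant, s.
#' @param totalDuration s; default runs 120 s past the last epoch.
#' @param cellId identifier.
#' @param seed integer or NULL.
#' @return a [FluorescenceTrace-class].
#' @examples
#' ep <- data.frame(label = "Yoda1", start = 60, duration = 90,
#'                  amplitude = 80)
#' tr <- generateFluorescenceTrace(100, ep, seed = 1)
#' max(deltaFOverF(tr))
#' @export
generateFluorescenceTrace <- function(baseline, epochs, frameInterval = 5,
                                      nBaselineFrames = 10, noiseSd = 0,
                                      decayTau = 20, totalDuration = NULL,
                                      cellId = "cell1", seed = NULL) {
  stopifnot(baseline > 0, nrow(epochs) >= 1,
            all(c("label", "start", "duration", "amplitude") %in%
                  names(epochs)))
  ep <- epochs[order(epochs$start), , drop = FALSE]
  if (nrow(ep) > 1 && any(ep$start[-1] < (ep$start + ep$duration)[-nrow(ep)]))
    stop("epochs must not overlap")
  if (is.null(totalDuration))
    totalDuration <- max(ep$start + ep$duration) + 120
  withLocalSeed(seed, {
    t <- seq(0, totalDuration, by = frameInterval)
    f <- rep(baseline, length(t))
    for (j in seq_len(nrow(ep))) {
      on <- t >= ep$start[j] & t < ep$start[j] + ep$duration[j]
      f[on] <- f[on] + ep$amplitude[j]
      post <- t >= ep$start[j] + ep$duration[j]
      f[post] <- f[post] + ep$amplitude[j] *
        exp(-(t[post] - ep$start[j] - ep$duration[j]) / decayTau)
    }
    if (noiseSd > 0) f <- f + stats::rnorm(length(f), 0, noiseSd)
    f <- pmax(f, 1e-6)
    new("FluorescenceTrace", intensities = f, frameInterval = frameInterval,
        nBaselineFrames = as.integer(nBaselineFrames), cellId = cellId,
        epochs = data.frame(label = ep$label, start = ep$start,
                            duration = ep$duration,
                            truth_amplitude = ep$amplitude,
                            stringsAsFactors = FALSE))
  })
}

#' Default agonist epoch schedule for calcium-imaging simulations
#'
#' ATP viability test (60 s, an assumed duration: the published protocol
#' does not state it), 5 min washout, Yoda1 for 90 s (PIEZO1 agonist),
#' 5 min washout, then GSK1016790A for 15 s (TRPV4 agonist).
#'
#' @param atpAmp,yoda1Amp,gskAmp transient amplitudes in counts.
#' @return epochs data.frame for [generateFluorescenceTrace()].
#' @export
defaultCalciumEpochs <- function(atpAmp = 80, yoda1Amp = 60, gskAmp = 70) {
  data.frame(
    label = c("ATP", "Yoda1", "GSK101"),
    start = c(60, 60 + 60 + 300, 60 + 60 + 300 + 90 + 300),
    duration = c(60, 90, 15),
    amplitude = c(atpAmp, yoda1Amp, gskAmp),
    stringsAsFactors = FALSE)
}
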