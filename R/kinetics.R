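# Latency, peak amplitude and mono-exponential activation/decay time
# constants of mechanically gated currents. Amplitudes are reported as
# positive magnitudes with the event polarity stored separately; inward
# currents are negative in raw traces.

baselineStats <- function(trace, baselineWindow) {
  t <- traceTime(trace)
  on <- stimulusOnset(trace)
  idx <- which(t >= on - baselineWindow & t < on)
  if (length(idx) < 10L)
    stop("baseline window must contain at least 10 samples")
  x <- current(trace)[idx]
  list(mean = mean(x), sd = stats::sd(x), idx = idx)
}

#' Detect a mechanically gated current event
#'
#' Onset is the first time after stimulus onset at which the current
#' deviates from the baseline mean by more than \code{kSd} baseline
#' standard deviations, sustained for at least \code{sustainMs}. The
#' baseline is taken from the \code{baselineWindow} ms immediately
#' preceding the stimulus. This onset criterion is the package's own
#' operational definition (thresholds configurable); latency is onset
#' minus stimulus onset.
#'
#' @param trace a [CurrentTrace-class].
#' @param baselineWindow ms before stimulus used for baseline statistics
#'   (>= 10 samples).
#' @param kSd threshold multiplier (default 5).
#' @param sustainMs minimal sustained crossing, ms.
#' @param absFloor minimal absolute threshold, pA (guards against a
#'   zero-noise baseline).
#' @return list: \code{responded}, \code{onset_ms} (NA when not
#'   responded), \code{latency} (ms), \code{peak_ms}, \code{amplitude}
#'   (pA magnitude; 0 when not responded), \code{sign} (-1 inward / +1
#'   outward), \code{baseline_mean}, \code{baseline_sd}.
#' @export
detectEvent <- function(trace, baselineWindow = 20, kSd = 5,
                        sustainMs = 0.3, absFloor = 0) {
  bl <- baselineStats(trace, baselineWindow)
  t <- traceTime(trace)
  x <- current(trace) - bl$mean
  on <- stimulusOnset(trace)
  dt <- 1000 / samplingRate(trace)
  thr <- max(kSd * bl$sd, absFloor, .Machine$double.eps)
  nSus <- max(1L, ceiling(sustainMs / dt))
  post <- which(t >= on)
  dev <- abs(x[post]) > thr
  # first index where dev holds for nSus consecutive samples
  r <- rle(dev)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= nSus)
  if (!length(hit)) {
    return(list(responded = FALSE, onset_ms = NA_real_, latency = NA_real_,
                peak_ms = NA_real_, amplitude = 0, sign = NA_integer_,
                baseline_mean = bl$mean, baseline_sd = bl$sd))
  }
  i0 <- post[ends[hit[1]] - r$lengths[hit[1]] + 1]
  # locate the peak on a lightly smoothed deviation (1 ms boxcar): the
  # raw argmax rides on the largest noise excursion and biases both the
  # peak time and the amplitude upward; the amplitude itself is read
  # from the raw trace at the smoothed peak position
  w <- max(3L, round(1 / dt)); if (w %% 2 == 0) w <- w + 1L
  xs <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  ipk <- post[which.max(abs(xs[post]))]
  list(responded = TRUE, onset_ms = t[i0], latency = t[i0] - on,
       peak_ms = t[ipk], amplitude = abs(x[ipk]),
       sign = as.integer(sign(x[ipk])),
       baseline_mean = bl$mean, baseline_sd = bl$sd,
       smoothed_dev = xs)
}

#' Fit the mono-exponential activation of a gated current
#'
#' Least-squares fit of I(t) = A (1 - exp(-(t - t0) / tau1)) to the
#' baseline-subtracted, polarity-corrected current on the rise window.
#' With \code{freeOnset = TRUE} the onset t0 is a free parameter, giving
#' sub-sample onset estimates; otherwise t0 is fixed at \code{onset}.
#'
#' @param trace a [CurrentTrace-class].
#' @param onset rise start, ms (from [detectEvent()]).
#' @param peakTime rise end, ms.
#' @param freeOnset fit t0 as a free parameter.
#' @param settleMs with \code{freeOnset}, samples within this interval
#'   after the detected onset are excluded from the fit: the acquisition
#'   filter reshapes the waveform front over roughly its settling time,
#'   and the mono-exponential model only holds beyond it. One
#'   millisecond of pre-onset baseline (where the model is zero) stays
#'   in the window to anchor the free onset under noise.
#' @param baselineWindow ms, baseline statistics window.
#' @return list: \code{tau1} (ms), \code{A} (pA), \code{t0} (ms),
#'   \code{fit_quality} (RMS residual / A), \code{fittable} (FALSE when
#'   the window holds < 5 samples or the fit fails; tau1 is NA then).
#' @export
fitActivation <- function(trace, onset, peakTime, freeOnset = FALSE,
                          settleMs = 0.3, baselineWindow = 20) {
  stopifnot(onset < peakTime)
  bl <- baselineStats(trace, baselineWindow)
  t <- traceTime(trace)
  dt <- 1000 / samplingRate(trace)
  idx <- if (freeOnset)
    which((t >= onset - 1 & t < onset) |
            (t >= onset + settleMs & t <= peakTime))
  else which(t >= onset & t <= peakTime)
  bad <- list(tau1 = NA_real_, A = NA_real_, t0 = NA_real_,
              fit_quality = NA_real_, fittable = FALSE)
  if (length(idx) < 5L) return(bad)
  y <- current(trace)[idx] - bl$mean
  sgn <- sign(y[which.max(abs(y))])
  y <- y * sgn
  tt <- t[idx]
  a0 <- max(y); tau0 <- max((peakTime - onset) / 3, dt)
  fit <- tryCatch({
    if (freeOnset)
      minpack.lm::nlsLM(y ~ A * pmax(0, 1 - exp(-(tt - t0) / tau)),
                        start = list(A = a0, tau = tau0, t0 = onset),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ A * (1 - exp(-(tt - onset) / tau)),
                        start = list(A = a0, tau = tau0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) return(bad)
  p <- stats::coef(fit)
  if (p[["tau"]] <= 0 || p[["A"]] <= 0) return(bad)
  list(tau1 = p[["tau"]], A = p[["A"]],
       t0 = if (freeOnset) p[["t0"]] else onset,
       fit_quality = sqrt(mean(stats::resid(fit)^2)) / p[["A"]],
       fittable = TRUE)
}

#' Fit the mono-exponential decay of a gated current
#'
#' Least-squares fit of I(t) = A exp(-(t - peakTime) / tau2) + C to the
#' baseline-subtracted, polarity-corrected current on the decay window.
#'
#' @param trace a [CurrentTrace-class].
#' @param peakTime decay start, ms.
#' @param windowEnd decay end, ms.
#' @param baselineWindow ms.
#' @return list: \code{tau2} (ms), \code{A}, \code{C},
#'   \code{fit_quality}, \code{fittable}.
#' @export
fitDecay <- function(trace, peakTime, windowEnd, baselineWindow = 20) {
  stopifnot(peakTime < windowEnd)
  bl <- baselineStats(trace, baselineWindow)
  t <- traceTime(trace)
  idx <- which(t >= peakTime & t <= windowEnd)
  bad <- list(tau2 = NA_real_, A = NA_real_, C = NA_real_,
              fit_quality = NA_real_, fittable = FALSE)
  if (length(idx) < 5L) return(bad)
  y <- current(trace)[idx] - bl$mean
  sgn <- sign(y[which.max(abs(y))])
  y <- y * sgn
  tt <- t[idx] - peakTime
  a0 <- max(y)
  tau0 <- max((windowEnd - peakTime) / 3, 1000 / samplingRate(trace))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-tt / tau) + C,
                      start = list(A = a0, tau = tau0, C = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  p <- stats::coef(fit)
  if (p[["tau"]] <= 0 || p[["A"]] <= 0) return(bad)
  list(tau2 = p[["tau"]], A = p[["A"]], C = p[["C"]],
       fit_quality = sqrt(mean(stats::resid(fit)^2)) / p[["A"]],
       fittable = TRUE)
}

#' Classify a current as consistent with direct mechanical gating
#'
#' Directly gated mechanosensitive currents activate with latencies below
#' 5 ms; a stricter criterion additionally requires an activation time
#' constant under 1 ms. Both thresholds are strict inequalities and
#' configurable.
#'
#' @param kinetics data.frame with \code{latency} and (for the strict
#'   flag) \code{tau1} columns, as from [extractKinetics()]; or a numeric
#'   latency vector.
#' @param latencyMax ms, default 5.
#' @param tau1Max ms, default 1 (strict flag only).
#' @param strict also require tau1 < tau1Max.
#' @return logical vector.
#' @export
classifyRapid <- function(kinetics, latencyMax = 5, tau1Max = 1,
                          strict = FALSE) {
  if (is.numeric(kinetics)) kinetics <- data.frame(latency = kinetics)
  out <- kinetics$latency < latencyMax
  if (strict) out <- out & !is.na(kinetics$tau1) & kinetics$tau1 < tau1Max
  out
}

#' Extract the full kinetics of one trace
#'
#' Runs event detection, refines the onset sub-sample with a free-onset
#' activation fit, compensates the known group delay of the acquisition
#' filter recorded in the trace metadata (computed from the filter's
#' impulse response; set \code{compensateFilterDelay = FALSE} to skip),
#' and fits the activation and decay exponentials. The decay window runs
#' from the rise end to the point where the current has relaxed below 2%
#' of the peak, or to the trace end.
#'
#' @param trace a [CurrentTrace-class].
#' @param baselineWindow,kSd,sustainMs,absFloor see [detectEvent()].
#' @param latencyMax,tau1Max see [classifyRapid()].
#' @param compensateFilterDelay subtract the acquisition-filter group
#'   delay from the latency when the trace metadata records the filter.
#' @return one-row data.frame: \code{responded}, \code{latency},
#'   \code{tau1}, \code{tau2}, \code{amplitude}, \code{sign},
#'   \code{rapid_gating}, \code{rapid_strict}, \code{fittable},
#'   \code{fit_quality_act}, \code{fit_quality_dec}, \code{onset_ms},
#'   \code{peak_ms}. Non-responding traces carry amplitude 0 and NA
#'   kinetics; responding-but-unfittable traces keep latency and
#'   amplitude with NA taus.
#' @examples
#' ph <- channelPhenotype("demo", thresholdMean = 100)
#' tr <- generateCurrentTrace(ph, 300, baselineNoiseSd = 0.5, seed = 2)
#' extractKinetics(tr)
#' @export
extractKinetics <- function(trace, baselineWindow = 20, kSd = 5,
                            sustainMs = 0.3, absFloor = 0,
                            latencyMax = 5, tau1Max = 1,
                            compensateFilterDelay = TRUE) {
  ev <- detectEvent(trace, baselineWindow, kSd, sustainMs, absFloor)
  empty <- data.frame(responded = FALSE, latency = NA_real_,
                      tau1 = NA_real_, tau2 = NA_real_, amplitude = 0,
                      sign = NA_integer_, rapid_gating = NA,
                      rapid_strict = NA, fittable = NA,
                      fit_quality_act = NA_real_, fit_quality_dec = NA_real_,
                      onset_ms = NA_real_, peak_ms = NA_real_)
  if (!ev$responded) return(empty)

  act <- fitActivation(trace, ev$onset_ms, ev$peak_ms, freeOnset = TRUE,
                       baselineWindow = baselineWindow)
  onset <- if (act$fittable) act$t0 else ev$onset_ms
  latency <- onset - stimulusOnset(trace)
  if (compensateFilterDelay) {
    fc <- trace@metadata$filterCutoff
    if (!is.null(fc) && !is.na(fc)) {
      ord <- trace@metadata$filterOrder
      if (is.null(ord)) ord <- 4
      latency <- latency -
        besselLowpass(fc, samplingRate(trace), ord)$groupDelay * 1000
    }
  }
  latency <- max(latency, 0)

  t <- traceTime(trace)
  # decay window from the smoothed deviation: the raw trace recrosses
  # baseline on noise excursions long before the current has decayed
  x <- abs(ev$smoothed_dev)
  post <- which(t > ev$peak_ms)
  below <- post[x[post] < 0.02 * ev$amplitude]
  windowEnd <- if (length(below)) t[below[1]] else t[length(t)]
  # a short margin after the peak keeps the rise/decay transition (and
  # residual filter curvature) out of the mono-exponential decay fit
  decStart <- ev$peak_ms + 0.5
  dec <- if (windowEnd > decStart)
    fitDecay(trace, decStart, windowEnd, baselineWindow)
  else list(tau2 = NA_real_, fit_quality = NA_real_, fittable = FALSE)

  data.frame(responded = TRUE, latency = latency,
             tau1 = if (act$fittable) act$tau1 else NA_real_,
             tau2 = if (dec$fittable) dec$tau2 else NA_real_,
             amplitude = ev$amplitude, sign = ev$sign,
             rapid_gating = latency < latencyMax,
             rapid_strict = latency < latencyMax &
               isTRUE(act$fittable) && !is.na(act$tau1) && act$tau1 < tau1Max,
             fittable = act$fittable && dec$fittable,
             fit_quality_act = act$fit_quality,
             fit_quality_dec = dec$fit_quality,
             onset_ms = onset, peak_ms = ev$peak_ms)
}

#' Compare gated-current amplitude and decay across holding potentials
#'
#' Group means with s.e.m. and Mann-Whitney comparisons of peak amplitude
#' and decay time constant between events recorded at negative and
#' positive holding potentials (outward-rectification check).
#'
#' @param eventsNeg,eventsPos data.frames of per-event kinetics (columns
#'   \code{amplitude}, \code{tau2}), e.g. rbind-ed [extractKinetics()]
#'   rows; >= 3 events per potential required.
#' @return data.frame with one row per quantity (amplitude, tau2): group
#'   means, s.e.m.s, n, Mann-Whitney U and p.
#' @export
rectificationSummary <- function(eventsNeg, eventsPos) {
  if (nrow(eventsNeg) < 3L || nrow(eventsPos) < 3L)
    stop("need at least 3 events per holding potential")
  one <- function(col) {
    x <- eventsNeg[[col]]; y <- eventsPos[[col]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mw <- mannWhitneyTest(x, y)
    data.frame(quantity = col,
               mean_neg = mean(x), sem_neg = stats::sd(x) / sqrt(length(x)),
               n_neg = length(x),
               mean_pos = mean(y), sem_pos = stats::sd(y) / sqrt(length(y)),
               n_pos = length(y),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  }
  rbind(one("amplitude"), one("tau2"))
}
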