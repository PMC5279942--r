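# Causal low-pass emulating the patch-clamp amplifier's acquisition
# filter. Bessel response chosen for its flat group delay (the standard
# choice in electrophysiology hardware); order configurable.

# Reverse Bessel polynomial theta_n, coefficients in ascending powers,
# via the recurrence theta_n = (2n-1) theta_{n-1} + s^2 theta_{n-2}.
besselPolyCoef <- function(n) {
  a <- 1; b <- c(1, 1)
  if (n == 0) return(a)
  if (n == 1) return(b)
  for (k in 2:n) {
    nb <- (2 * k - 1) * c(b, 0) + c(0, 0, a)
    a <- b; b <- nb
  }
  b
}

# polynomial coefficients (descending is unnecessary; keep ascending,
# constant term first) from roots
polyFromRoots <- function(r) {
  co <- 1 + 0i
  for (ri in r) co <- c(co, 0) - c(0, ri * co)
  co
}

#' Design a digital Bessel low-pass filter
#'
#' Analog Bessel prototype (roots of the reverse Bessel polynomial),
#' frequency-scaled so the -3 dB point sits at \code{cutoff}, then
#' discretized by the prewarped bilinear transform. Returns transfer
#' function coefficients normalized to unit DC gain.
#'
#' @param cutoff -3 dB frequency, Hz.
#' @param samplingRate Hz; \code{cutoff} must be below Nyquist.
#' @param order filter order (poles), default 4.
#' @return list with \code{b}, \code{a} (descending powers of z^-1) and
#'   \code{groupDelay} (s, impulse-response centroid).
#' @export
besselLowpass <- function(cutoff, samplingRate, order = 4) {
  if (cutoff >= samplingRate / 2)
    stop("filter cutoff must be below the Nyquist frequency")
  co <- besselPolyCoef(order)     # ascending powers, constant term first
  poles <- polyroot(co)
  # -3 dB frequency of the unit-delay prototype, found numerically
  mag <- function(w) {
    s <- (0+1i) * w
    abs(co[1] / sum(co * s^(seq_along(co) - 1)))
  }
  w3 <- stats::uniroot(function(w) mag(w) - 1 / sqrt(2),
                       c(1e-3, 10 * order))$root
  fs <- samplingRate
  wc <- 2 * fs * tan(pi * cutoff / fs)      # prewarp
  p <- poles * wc / w3
  zp <- (2 * fs + p) / (2 * fs - p)         # bilinear: poles
  a <- Re(polyFromRoots(zp))
  b <- Re(polyFromRoots(rep(-1 + 0i, order)))  # zeros at Nyquist
  b <- b * sum(a) / sum(b)                  # unit DC gain
  h <- filterApply(b, a, c(1, numeric(255)))
  list(b = b, a = a, groupDelay = sum((seq_along(h) - 1) * h) / sum(h) / fs)
}

# direct-form I IIR, causal, zero initial state; front-padding makes
# stats::filter's sides=1 convolution start cleanly at sample 1
filterApply <- function(b, a, x) {
  n <- length(x)
  pad <- length(b) - 1
  xp <- c(numeric(pad), x)
  fir <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
  fir <- fir[(pad + 1):(pad + n)]
  as.numeric(stats::filter(fir, -a[-1], method = "recursive"))
}

#' Apply a causal low-pass filter to a sampled signal
#'
#' @param x numeric signal.
#' @param cutoff -3 dB frequency, Hz.
#' @param samplingRate Hz.
#' @param order Bessel order, default 4.
#' @return filtered signal, same length.
#' @export
lowpassFilter <- function(x, cutoff, samplingRate, order = 4) {
  flt <- besselLowpass(cutoff, samplingRate, order)
  filterApply(flt$b, flt$a, x)
}
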