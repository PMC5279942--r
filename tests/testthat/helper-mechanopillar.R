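# shared fixtures, built in code at test time

# independent single-spot renderer (deliberately separate from the
# package's scene generator so it can serve as an oracle)
renderSpot <- function(side, cx, cy, A = 1000, sigma = 3, B = 100) {
  xs <- 0:(side - 1)
  gx <- exp(-((xs - cx)^2) / (2 * sigma^2))
  gy <- exp(-((xs - cy)^2) / (2 * sigma^2))
  B + A * outer(gy, gx)
}

fullRoi <- function(img) list(x0 = 0, x1 = ncol(img) - 1,
                              y0 = 0, y1 = nrow(img) - 1)

# bare trace container without any acquisition filter metadata, for
# tests that feed hand-built sample vectors to the fitters
rawTrace <- function(samples, samplingRate = 10000, stimulusOnset = 50,
                     holdingPotential = -40) {
  new("CurrentTrace", current = samples, samplingRate = samplingRate,
      holdingPotential = holdingPotential, stimulusOnset = stimulusOnset,
      ids = c(cell_id = "test"), metadata = list())
}

# piecewise rise/decay event waveform on a time grid (ms), no filter
eventWave <- function(t, onset, A, tau1, tau2, riseTaus = 5) {
  tEnd <- onset + riseTaus * tau1
  y <- numeric(length(t))
  r <- t >= onset & t < tEnd
  y[r] <- A * (1 - exp(-(t[r] - onset) / tau1))
  pk <- A * (1 - exp(-riseTaus))
  d <- t >= tEnd
  y[d] <- pk * exp(-(t[d] - tEnd) / tau2)
  y
}

wtPhenotype <- function(...) {
  channelPhenotype("wt-like", latencyMean = 3.6, tau1Mean = 1.7,
                   tau2Mean = 12.2, peakAmpMean = 50,
                   thresholdMean = 100, ...)
}
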