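test_that("pure-noise traces are classified non-responding", {
  set.seed(1)
  tr <- rawTrace(rnorm(2000, 0, 1))
  ev <- detectEvent(tr)
  expect_false(ev$responded)
  expect_equal(ev$amplitude, 0)
  k <- extractKinetics(tr)
  expect_false(k$responded)
  expect_equal(k$amplitude, 0)
})

test_that("detection threshold is monotone: raising kSd suppresses events", {
  t <- (0:2999) / 10
  set.seed(2)
  y <- rnorm(3000, 0, 1) - eventWave(t, 55, A = 12, tau1 = 1.5, tau2 = 10)
  tr <- rawTrace(y)
  expect_true(detectEvent(tr, kSd = 5)$responded)
  expect_false(detectEvent(tr, kSd = 30)$responded)
})

test_that("noiseless events reproduce generator kinetics within 1%", {
  cases <- list(chond = c(3.6, 1.7, 12.2, 50),
                dediff = c(3.1, 1.4, 12.2, 80),
                trpv4 = c(3.6, 0.5, 12.2, 147))
  for (cs in cases) {
    ph <- channelPhenotype("c", latencyMean = cs[1], tau1Mean = cs[2],
                           tau2Mean = cs[3], peakAmpMean = cs[4],
                           thresholdMean = 10)
    tr <- generateCurrentTrace(ph, 300, baselineNoiseSd = 0,
                               forceResponder = TRUE)
    k <- extractKinetics(tr)
    expect_lt(abs(k$latency - cs[1]) / cs[1], 0.01)
    expect_lt(abs(k$tau1 - cs[2]) / cs[2], 0.01)
    expect_lt(abs(k$tau2 - cs[3]) / cs[3], 0.01)
    expect_lt(abs(k$amplitude - cs[4] * (1 - exp(-5))) / cs[4], 0.01)
  }
})

test_that("detected latency sits within one sample period of truth", {
  ph <- wtPhenotype()
  tr <- generateCurrentTrace(ph, 300, baselineNoiseSd = 0,
                             forceResponder = TRUE)
  ev <- detectEvent(tr)
  expect_true(ev$responded)
  expect_lt(abs(ev$latency - 3.6), 0.2)   # coarse detector, pre-refinement
  k <- extractKinetics(tr)
  expect_lt(abs(k$latency - 3.6), 0.1)
})

test_that("activation fit is equivariant under time-axis rescaling", {
  t <- (0:1499) / 10
  y <- -eventWave(t, 60, A = 40, tau1 = 2, tau2 = 1e6)
  tr1 <- rawTrace(y, samplingRate = 10000, stimulusOnset = 55)
  tr2 <- rawTrace(y, samplingRate = 5000, stimulusOnset = 110)
  a1 <- fitActivation(tr1, 60, 70)
  a2 <- fitActivation(tr2, 120, 140)
  expect_equal(a2$tau1 / a1$tau1, 2, tolerance = 1e-6)
})

test_that("decay fit is invariant to a constant offset", {
  t <- (0:1499) / 10
  y <- eventWave(t, 55, A = 35, tau1 = 1.2, tau2 = 9)
  peak <- 55 + 5 * 1.2
  a <- fitDecay(rawTrace(-y), peak, 150)
  b <- fitDecay(rawTrace(-y + 12), peak, 150)
  expect_equal(a$tau2, 9, tolerance = 1e-3)
  expect_equal(b$tau2, a$tau2, tolerance = 1e-6)
})

test_that("exponential fitters agree with brute-force grid oracles", {
  # decay: 50-sample window, grid over tau with (A, C) solved linearly
  t <- (0:49) / 10
  y <- 28 * exp(-t / 3.7) + 2
  tr <- rawTrace(c(numeric(600), y, numeric(200)),
                 stimulusOnset = 55)
  dec <- fitDecay(tr, 60, 64.9)
  taus <- seq(1, 10, by = 0.005)
  rss <- vapply(taus, function(tau) {
    X <- cbind(exp(-t / tau), 1)
    sum(stats::lm.fit(X, y)$residuals^2)
  }, numeric(1))
  expect_lt(abs(dec$tau2 - taus[which.min(rss)]) / dec$tau2, 0.02)

  # activation: fixed-onset fit vs grid over tau (A solved linearly)
  set.seed(8)
  for (i in 1:20) {
    tau <- runif(1, 0.5, 4); A <- runif(1, 15, 120)
    tt <- (0:99) / 10
    ya <- A * (1 - exp(-tt / tau)) + rnorm(100, 0, A / 50)
    tra <- rawTrace(c(numeric(600), -ya), stimulusOnset = 55)
    act <- fitActivation(tra, 60, 69.9)
    gtaus <- seq(0.2, 6, by = 0.005)
    rssA <- vapply(gtaus, function(g) {
      X <- matrix(1 - exp(-tt / g), ncol = 1)
      sum(stats::lm.fit(X, ya)$residuals^2)
    }, numeric(1))
    expect_lt(abs(act$tau1 - gtaus[which.min(rssA)]) / act$tau1, 0.02)
  }
})

test_that("short rise windows are flagged unfittable but keep amplitude", {
  # tau1 so fast the rise holds < 5 samples
  ph <- channelPhenotype("fast", latencyMean = 3, tau1Mean = 0.05,
                         tau2Mean = 10, peakAmpMean = 60,
                         thresholdMean = 10)
  tr <- generateCurrentTrace(ph, 200, baselineNoiseSd = 0,
                             forceResponder = TRUE, filterCutoff = NA)
  k <- extractKinetics(tr)
  expect_true(k$responded)
  expect_gt(k$amplitude, 30)
  expect_false(is.na(k$latency))
})

test_that("rapid-gating classification uses strict 5 ms / 1 ms cuts", {
  expect_true(classifyRapid(3.6))
  expect_false(classifyRapid(7.8))
  expect_false(classifyRapid(5))
  k <- data.frame(latency = c(3.6, 3.6), tau1 = c(0.5, 1.7))
  expect_equal(classifyRapid(k, strict = TRUE), c(TRUE, FALSE))
  expect_equal(classifyRapid(k, strict = TRUE, tau1Max = 2), c(TRUE, TRUE))
})

test_that("polarity inversion with potential flip preserves magnitudes", {
  ph <- wtPhenotype()
  tr <- generateCurrentTrace(ph, 300, baselineNoiseSd = 0.5,
                             forceResponder = TRUE, seed = 6)
  flipped <- new("CurrentTrace", current = -current(tr),
                 samplingRate = samplingRate(tr),
                 holdingPotential = -holdingPotential(tr),
                 stimulusOnset = stimulusOnset(tr), ids = tr@ids,
                 metadata = tr@metadata)
  k1 <- extractKinetics(tr); k2 <- extractKinetics(flipped)
  expect_equal(k1$amplitude, k2$amplitude)
  expect_equal(k1$sign, -k2$sign)
  expect_equal(k1$tau2, k2$tau2)
})

test_that("kinetic recovery under noise stays within 5% median error", {
  ph <- wtPhenotype(latencySd = 1, tau1Sd = 0.4, tau2Sd = 3, peakAmpSd = 10)
  res <- t(vapply(1:120, function(i) {
    tr <- generateCurrentTrace(ph, 300, forceResponder = TRUE,
                               baselineNoiseSd = 50 / 20, seed = 400 + i)
    k <- extractKinetics(tr)
    tru <- traceTruth(tr)
    c(abs(k$tau1 - tru$tau1) / tru$tau1,
      abs(k$tau2 - tru$tau2) / tru$tau2)
  }, numeric(2)))
  expect_lt(stats::median(res[, 1], na.rm = TRUE), 0.05)
  expect_lt(stats::median(res[, 2], na.rm = TRUE), 0.05)
})

test_that("rectification summary contrasts potentials correctly", {
  ph <- presetPhenotype("TRPV4-like")
  ev <- function(vh, n, off) do.call(rbind, lapply(seq_len(n), function(i)
    traceTruth(generateCurrentTrace(ph, 200, holdingPotential = vh,
                                    forceResponder = TRUE,
                                    seed = off + i))))
  neg <- ev(-60, 30, 100); pos <- ev(60, 18, 900)
  rs <- rectificationSummary(neg, pos)
  expect_equal(rs$quantity, c("amplitude", "tau2"))
  expect_true(all(rs$p > 0.05))          # TRPV4-like: no rectification
  # identical event lists -> zero contrast, p = 1
  same <- rectificationSummary(neg, neg)
  expect_equal(same$mean_neg, same$mean_pos)
  expect_true(all(same$p == 1))
  expect_error(rectificationSummary(neg[1:2, ], pos), "3 events")
  # PIEZO1-like decay slows at positive potentials
  php <- presetPhenotype("PIEZO1-like")
  evp <- function(vh, off) do.call(rbind, lapply(1:15, function(i)
    traceTruth(generateCurrentTrace(php, 200, holdingPotential = vh,
                                    forceResponder = TRUE,
                                    seed = off + i))))
  rsp <- rectificationSummary(evp(-60, 50), evp(60, 550))
  expect_gt(rsp$mean_pos[rsp$quantity == "tau2"],
            rsp$mean_neg[rsp$quantity == "tau2"])
})
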