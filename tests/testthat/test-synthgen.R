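test_that("noiseless scene with zero deflection has identical frames", {
  sc <- generatePillarScene(trueDeflection = c(0, 0), readNoiseSd = 0,
                            nGrid = 2)
  fr <- frames(sc)
  expect_identical(fr$before, fr$during)
  expect_identical(fr$before, fr$after)
})

test_that("during-frame truth shifts by deflection / pixel size", {
  sc <- generatePillarScene(trueDeflection = c(100, 0), pixelSize = 161,
                            nGrid = 2, deflectedPilus = "p01")
  tru <- sceneTruth(sc)
  b <- tru[tru$role == "before" & tru$pilus_id == "p01", ]
  d <- tru[tru$role == "during" & tru$pilus_id == "p01", ]
  expect_equal(d$cx - b$cx, 100 / 161)
  expect_equal(d$cy - b$cy, 0)
  expect_true(d$deflected)
  # all other pili unmoved
  o <- tru[tru$pilus_id != "p01", ]
  expect_true(all(!o$deflected))
})

test_that("scene generation is bit-identical under a fixed seed", {
  a <- generatePillarScene(readNoiseSd = 15, shotNoise = TRUE,
                           trueDeflection = c(70, -30), nGrid = 2, seed = 11)
  b <- generatePillarScene(readNoiseSd = 15, shotNoise = TRUE,
                           trueDeflection = c(70, -30), nGrid = 2, seed = 11)
  expect_identical(frames(a), frames(b))
  expect_identical(sceneTruth(a), sceneTruth(b))
})

test_that("scene generator rejects colliding and unresolvable spots", {
  expect_error(generatePillarScene(trueDeflection = c(3000, 0),
                                   gridPitch = 4160), "collision")
  expect_error(generatePillarScene(spotSigma = 50, pixelSize = 161),
               "unresolvable")
})

test_that("non-responder traces contain no event", {
  ph <- wtPhenotype(responderProb = 0)
  tr <- generateCurrentTrace(ph, 500, baselineNoiseSd = 0, seed = 1)
  expect_equal(nrow(traceTruth(tr)), 0)
  expect_true(all(current(tr) == 0))
})

test_that("trace generation is deterministic under a fixed seed", {
  ph <- wtPhenotype(latencySd = 1, tau1Sd = 0.5, tau2Sd = 3, peakAmpSd = 20)
  a <- generateCurrentTrace(ph, 300, seed = 5)
  b <- generateCurrentTrace(ph, 300, seed = 5)
  expect_identical(current(a), current(b))
  expect_identical(traceTruth(a), traceTruth(b))
})

test_that("trace generator enforces the Nyquist bound on the filter", {
  expect_error(generateCurrentTrace(wtPhenotype(), 300,
                                    filterCutoff = 6000), "Nyquist")
})

test_that("inward events are negative at negative holding potentials", {
  tr <- generateCurrentTrace(wtPhenotype(), 300, baselineNoiseSd = 0,
                             forceResponder = TRUE, holdingPotential = -40)
  expect_lt(min(current(tr)), 0)
  expect_equal(traceTruth(tr)$sign, -1)
  trp <- generateCurrentTrace(wtPhenotype(), 300, baselineNoiseSd = 0,
                              forceResponder = TRUE, holdingPotential = 60)
  expect_gt(max(current(trp)), 0)
})

test_that("pressure family hits the Boltzmann midpoint and saturation", {
  fam <- generatePressureFamily(p50 = 80, slope = 12, imax = 40,
                                steps = c(20, 50, 80, 110, 5000))
  y <- peakCurrents(fam)
  expect_equal(y[3], 20)                       # P = p50 -> imax/2
  expect_equal(y[5], 40, tolerance = 1e-6)     # saturation -> imax
  expect_error(generatePressureFamily(80, -3, 40), "slope")
  expect_error(generatePressureFamily(80, 12, 40, steps = c(50, 30)),
               "increasing")
})

test_that("population is reproducible and respects degenerate spreads", {
  ph <- wtPhenotype(responderProb = 1, thresholdSd = 0)
  a <- generatePopulation(list(g = ph), c(g = 6), seed = 2)
  b <- generatePopulation(list(g = ph), c(g = 6), seed = 2)
  expect_identical(a, b)
  expect_true(all(a$cells$threshold == 100))
})

test_that("responder fraction converges to the WT 24/27 rate", {
  pop <- generatePopulation(
    list(WT = presetPhenotype("chondrocyte-WT")), c(WT = 2700), seed = 17)
  p0 <- 24 / 27
  se <- sqrt(p0 * (1 - p0) / 2700)
  expect_lt(abs(mean(pop$cells$responder) - p0), 3 * se)
})

test_that("observed thresholds converge to the phenotype mean (LLN)", {
  pop <- generatePopulation(
    list(WT = presetPhenotype("chondrocyte-WT")), c(WT = 10000), seed = 4)
  cells <- summarizeCells(pop$measurements)
  thr <- cells$threshold[!is.na(cells$threshold)]
  se <- stats::sd(thr) / sqrt(length(thr))
  expect_lt(abs(mean(thr) - 252), 3 * se)
  # every observed threshold within the probed range
  expect_true(all(thr > 0 & thr <= 1000))
})

test_that("fluorescence generator reproduces the dF/F formula limits", {
  ep <- data.frame(label = "Yoda1", start = 60, duration = 90,
                   amplitude = 100)
  tr <- generateFluorescenceTrace(100, ep, noiseSd = 0, seed = 1)
  dff <- deltaFOverF(tr)
  expect_equal(max(dff), 1)                  # amplitude == baseline
  flat <- generateFluorescenceTrace(
    100, data.frame(label = "Yoda1", start = 60, duration = 90,
                    amplitude = 0), noiseSd = 3, seed = 2)
  d2 <- deltaFOverF(flat)
  expect_lt(abs(mean(d2)), 0.02)
  expect_lt(abs(stats::sd(d2) - 3 / 100), 0.01)
  expect_error(generateFluorescenceTrace(
    100, data.frame(label = c("a", "b"), start = c(60, 100),
                    duration = c(90, 20), amplitude = c(1, 1))),
    "overlap")
})

test_that("rectifying phenotypes slow tau2 only at positive potentials", {
  ph <- presetPhenotype("PIEZO1-like")
  neg <- traceTruth(generateCurrentTrace(ph, 300, holdingPotential = -60,
                                         forceResponder = TRUE, seed = 3))
  pos <- traceTruth(generateCurrentTrace(ph, 300, holdingPotential = 60,
                                         forceResponder = TRUE, seed = 3))
  expect_gt(pos$tau2, neg$tau2)
  phT <- presetPhenotype("TRPV4-like")
  negT <- traceTruth(generateCurrentTrace(phT, 300, holdingPotential = -60,
                                          forceResponder = TRUE, seed = 3))
  posT <- traceTruth(generateCurrentTrace(phT, 300, holdingPotential = 60,
                                          forceResponder = TRUE, seed = 3))
  expect_equal(posT$tau2, negT$tau2)
})
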