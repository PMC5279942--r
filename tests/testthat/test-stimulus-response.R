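test_that("two-stage averaging matches the hand-computed example", {
  m <- data.frame(cell_id = c("A", "A", "B"),
                  deflection = c(30, 40, 35),
                  amplitude = c(10, 20, 60))
  br <- binResponses(m)
  row <- br$summary[br$summary$bin == "10-50", ]
  expect_equal(row$mean, 37.5)     # ((10+20)/2 + 60) / 2
  expect_equal(row$n_cells, 2L)
  expect_equal(row$n_measurements, 3L)
})

test_that("a single measurement yields its own mean and no s.e.m.", {
  br <- binResponses(data.frame(cell_id = "A", deflection = 200,
                                amplitude = 42))
  row <- br$summary[br$summary$bin == "100-250", ]
  expect_equal(row$mean, 42)
  expect_true(is.na(row$sem))
})

test_that("binning is invariant to measurement order", {
  set.seed(3)
  m <- data.frame(cell_id = sample(LETTERS[1:6], 80, TRUE),
                  deflection = runif(80, 1, 1000),
                  amplitude = rexp(80, 1 / 40))
  a <- binResponses(m)
  b <- binResponses(m[sample(nrow(m)), ])
  expect_equal(a$summary, b$summary)
  expect_equal(a$per_cell_bin_means[order(rownames(a$per_cell_bin_means)), ],
               b$per_cell_bin_means[order(rownames(b$per_cell_bin_means)), ])
})

test_that("every in-range measurement lands in exactly one bin", {
  set.seed(4)
  m <- data.frame(cell_id = sample(LETTERS[1:8], 200, TRUE),
                  deflection = runif(200, -50, 1200),
                  amplitude = rexp(200, 1 / 30))
  br <- binResponses(m)
  inRange <- sum(m$deflection > 0 & m$deflection <= 1000)
  expect_equal(sum(br$summary$n_measurements), inRange)
  expect_equal(br$n_measurements, inRange)
  expect_equal(br$n_excluded, nrow(m) - inRange)
  # boundary values: 0 excluded, exact edges fall in the lower bin
  edge <- binResponses(data.frame(cell_id = "A",
                                  deflection = c(0, 10, 10.0001, 1000),
                                  amplitude = 1))
  expect_equal(edge$n_excluded, 1L)
  expect_equal(edge$summary$n_measurements[edge$summary$bin == "0-10"], 1L)
  expect_equal(edge$summary$n_measurements[edge$summary$bin == "10-50"], 1L)
  expect_equal(edge$summary$n_measurements[edge$summary$bin == "500-1000"], 1L)
})

test_that("two-stage mean equals plain mean at one measurement per cell", {
  m <- data.frame(cell_id = letters[1:5], deflection = rep(150, 5),
                  amplitude = c(5, 10, 20, 40, 80))
  br <- binResponses(m)
  expect_equal(br$summary$mean[br$summary$bin == "100-250"], mean(m$amplitude))
})

test_that("non-default bin edges are validated", {
  expect_error(binningScheme(c(0, 50, 10, 1000)), "increasing")
  expect_error(binningScheme(c(5, 50, 1000)), "first")
  expect_error(binningScheme(c(0, 50, 900)), "last")
  expect_equal(binningScheme()$labels,
               c("0-10", "10-50", "50-100", "100-250", "250-500",
                 "500-1000"))
})

test_that("responder classification takes the smallest gating deflection", {
  m <- data.frame(cell_id = "c1",
                  deflection = c(300, 150, 800),
                  amplitude = c(12, 8, 30))
  cs <- classifyResponder(m)
  expect_true(cs$responder)
  expect_equal(cs$threshold, 150)
  none <- classifyResponder(data.frame(cell_id = "c2",
                                       deflection = c(100, 500),
                                       amplitude = c(0, 0)))
  expect_false(none$responder)
  expect_true(is.na(none$threshold))
  # gating outside (0, 1000] does not count
  out <- classifyResponder(data.frame(cell_id = "c3",
                                      deflection = c(1200, 400),
                                      amplitude = c(50, 0)))
  expect_false(out$responder)
})

test_that("identical groups compare as indistinguishable", {
  set.seed(5)
  m <- data.frame(cell_id = rep(letters[1:6], each = 6),
                  deflection = runif(36, 1, 1000),
                  amplitude = rexp(36, 1 / 25))
  g <- list(binned = binResponses(m), cells = summarizeCells(m))
  cmp <- compareGroups(g, g)
  expect_true(all(cmp$per_bin$p[!is.na(cmp$per_bin$p)] == 1))
  expect_equal(cmp$responder$fisher_p, 1)
  expect_equal(cmp$threshold$p, 1)
})

test_that("responder-fraction comparison reproduces the printed Fisher p", {
  mkGroup <- function(nResp, nTot, thrMean) {
    m <- do.call(rbind, lapply(seq_len(nTot), function(i) {
      resp <- i <= nResp
      data.frame(cell_id = sprintf("c%02d", i),
                 deflection = c(100, 500),
                 amplitude = if (resp) c(0, 20) else c(0, 0))
    }))
    list(binned = binResponses(m), cells = summarizeCells(m))
  }
  cmp <- compareGroups(mkGroup(6, 12), mkGroup(19, 22))
  expect_equal(cmp$responder$fisher_p, 0.04, tolerance = 0.01)
})

test_that("adding a non-responder cell never raises the responder fraction", {
  set.seed(6)
  pop <- generatePopulation(list(g = presetPhenotype("chondrocyte-WT")),
                            c(g = 12), seed = 9)
  cells <- summarizeCells(pop$measurements)
  f0 <- mean(cells$responder)
  extra <- rbind(pop$measurements,
                 data.frame(cell_id = "extra", group = "g",
                            deflection = 500, amplitude = 0,
                            responded = FALSE))
  f1 <- mean(summarizeCells(extra)$responder)
  expect_lte(f1, f0)
})

test_that("WT-like cohorts recover the 252 nm mean threshold", {
  pop <- generatePopulation(list(WT = presetPhenotype("chondrocyte-WT")),
                            c(WT = 24), seed = 21)
  cells <- summarizeCells(pop$measurements)
  thr <- cells$threshold[!is.na(cells$threshold)]
  se <- stats::sd(thr) / sqrt(length(thr))
  expect_lt(abs(mean(thr) - 252), 2 * se)
})

test_that("empty input produces an empty summary, not an error", {
  br <- binResponses(data.frame(cell_id = character(0),
                                deflection = numeric(0),
                                amplitude = numeric(0)))
  expect_equal(br$n_cells, 0L)
  expect_equal(sum(br$summary$n_measurements), 0L)
})
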