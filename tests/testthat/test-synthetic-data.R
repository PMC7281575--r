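test_that("a noiseless planted peak samples the closed-form Gaussian", {
  pk <- plantedPeaks(mz = 300.15, rtApex = 100, rtSigma = 5, height = 1e4)
  run <- simulateRun(pk, rtGrid = c(0, 200, 1), seed = 1)
  rts <- scanTimes(run)
  eic <- vapply(scans(run), function(s) {
    i <- which(abs(s$mz - 300.15) < 1e-6)
    if (length(i)) s$intensity[i] else 0
  }, numeric(1))
  expected <- 1e4 * exp(-(rts - 100)^2 / (2 * 25))
  expected[expected <= pmax(1e-6 * 1e4, 1e-3)] <- 0
  expect_equal(eic, expected, tolerance = 1e-12)
})

test_that("simulation is a pure function of the seed", {
  pk <- plantedPeaks(mz = sort(runif(50, 100, 900)), rtApex = runif(50, 10, 290),
                     rtSigma = 4, height = 1e4, isotopePartner = TRUE)
  a <- simulateRun(pk, noise = list(baseline = 20, sd = 10, spikeRate = 30),
                   rtGrid = c(0, 300, 1), mzJitterPpm = 3, seed = 7)
  b <- simulateRun(pk, noise = list(baseline = 20, sd = 10, spikeRate = 30),
                   rtGrid = c(0, 300, 1), mzJitterPpm = 3, seed = 7)
  expect_identical(scans(a), scans(b))
  expect_identical(runMeta(a)$truth, runMeta(b)$truth)
})

test_that("identical (mz, rt) plants are rejected as ambiguous", {
  pk <- plantedPeaks(mz = c(200, 200), rtApex = c(50, 50))
  expect_error(simulateRun(pk), "ambiguous")
})

test_that("dilution series scales planted heights but not noise", {
  pk <- plantedPeaks(mz = 300, rtApex = 50, rtSigma = 4, height = 1000)
  runs <- simulateDilutionSeries(pk, factors = c(1, 0.5), rtGrid = c(0, 100, 1))
  apex <- vapply(runs, function(r) {
    max(vapply(scans(r), function(s)
      if (length(s$intensity)) max(s$intensity) else 0, numeric(1)))
  }, numeric(1))
  expect_equal(apex, c(1000, 500), tolerance = 1e-9)

  # the serum-series factor set gives one run per factor per replicate
  runs5 <- simulateDilutionSeries(pk, factors = c(1, 0.2, 0.1, 0.05, 0.025),
                                  replicates = 2, rtGrid = c(0, 100, 2))
  expect_length(runs5, 10)
  expect_error(simulateDilutionSeries(pk, factors = numeric()), "non-empty")

  # noiseless recovered apexes regress on the factor with a tiny p-value
  f <- vapply(runs5, function(r) r@meta$dilutionFactor, numeric(1))
  a <- vapply(runs5, function(r) {
    max(vapply(scans(r), function(s)
      if (length(s$intensity)) max(s$intensity) else 0, numeric(1)))
  }, numeric(1))
  p <- suppressWarnings(summary(lm(a ~ f))$coefficients[2, 4])
  expect_lt(p, 1e-12)
})

test_that("batched table: clean when unshifted, ratio ~2 under a x2 shift, deterministic", {
  z <- simulateBatchedTable(nFeatures = 50, nSamples = 20, nBatches = 2,
                            batchShift = c(1, 1), seed = 2)
  expect_equal(z$intensity, z$clean, tolerance = 1e-12)

  s <- simulateBatchedTable(nFeatures = 100, nSamples = 40, nBatches = 2,
                            batchShift = c(1, 2), seed = 2)
  b <- batchOf(s$design)
  ratio <- rowMeans(s$intensity[, b == "b2"]) / rowMeans(s$intensity[, b == "b1"])
  expect_equal(median(ratio), 2, tolerance = 0.25)

  s2 <- simulateBatchedTable(nFeatures = 100, nSamples = 40, nBatches = 2,
                             batchShift = c(1, 2), seed = 2)
  expect_identical(s$intensity, s2$intensity)

  # QCs are near the all-sample mean profile
  q <- simulateBatchedTable(nFeatures = 60, nSamples = 24, nBatches = 2,
                            batchShift = c(1, 1), qcEvery = 6, seed = 3)
  qc <- q$intensity[, isQC(q$design), drop = FALSE]
  bio <- q$clean[, !isQC(q$design), drop = FALSE]
  expect_equal(rowMeans(qc), rowMeans(bio), tolerance = 0.2)
})

test_that("pathway data emits mode-consistent ion forms with co-eluting features", {
  s <- simulatePathwayData(effect = 0.5, mode = "positive", seed = 4)
  expect_true(all(s$features$form %in% ionForms("positive")$name))
  expect_setequal(s$truth$sigCompounds,
                  s$library$pathway_01[seq_along(s$truth$sigCompounds)])
  # features of one compound share a narrow RT window
  spans <- tapply(s$features$rt, s$features$compound, function(x) diff(range(x)))
  expect_lt(max(spans), 10)
  sn <- simulatePathwayData(mode = "negative", seed = 4)
  expect_true(all(sn$features$form %in% ionForms("negative")$name))
})
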