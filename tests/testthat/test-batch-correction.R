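test_that("ComBat: identity on one batch, removes a x2 shift, gentle on clean data", {
  one <- simulateBatchedTable(nFeatures = 40, nSamples = 12, nBatches = 1,
                              batchShift = 1, seed = 1)
  expect_warning(out <- correctCombat(one$intensity, one$design), "single batch")
  expect_identical(out, one$intensity)

  s <- simulateBatchedTable(nFeatures = 80, nSamples = 30, nBatches = 2,
                            batchShift = c(1, 2), seed = 2)
  corrected <- correctCombat(s$intensity, s$design)
  b <- batchOf(s$design)
  logRatio <- rowMeans(log(corrected[, b == "b2"])) -
    rowMeans(log(corrected[, b == "b1"]))
  rawRatio <- rowMeans(log(s$intensity[, b == "b2"])) -
    rowMeans(log(s$intensity[, b == "b1"]))
  expect_lt(mean(abs(logRatio)), 0.1 * mean(abs(rawRatio)))

  clean <- simulateBatchedTable(nFeatures = 80, nSamples = 30, nBatches = 2,
                                batchShift = c(1, 1), seed = 3)
  cc <- correctCombat(clean$intensity, clean$design)
  relChange <- norm(log(cc) - log(clean$intensity), "F") /
    norm(log(clean$intensity), "F")
  expect_lt(relChange, 0.05)
})

test_that("EigenMS removes a planted rank-1 drift and preserves group effects", {
  s <- simulateBatchedTable(nFeatures = 100, nSamples = 40, nBatches = 2,
                            batchShift = c(1, 1), drift = 0.02,
                            groupEffect = 2, nAffected = 20, seed = 4)
  corrected <- correctEigenms(s$intensity, s$design, seed = 1)
  expect_gte(attr(corrected, "trendsRemoved"), 1L)
  # drift variance: per-feature regression slope on injection order
  driftVar <- function(m) {
    ord <- injectionOrder(s$design)
    mean(apply(log(m), 1, function(v) summary(lm(v ~ ord))$r.squared))
  }
  expect_lt(driftVar(corrected), 0.2 * driftVar(s$intensity))
  # group fold-changes on affected features preserved within 5%
  g <- groupOf(s$design)
  fc <- function(m) rowMeans(log(m[1:20, g == "B"])) - rowMeans(log(m[1:20, g == "A"]))
  expect_equal(mean(fc(corrected)), mean(fc(s$clean)), tolerance = 0.05)
})

test_that("EigenMS on pure noise removes no more than alpha-level trends", {
  hits <- vapply(1:6, function(i) {
    s <- simulateBatchedTable(nFeatures = 60, nSamples = 24, nBatches = 2,
                              batchShift = c(1, 1), seed = 100 + i)
    attr(correctEigenms(s$intensity, s$design, seed = i), "trendsRemoved")
  }, integer(1))
  expect_lte(mean(hits > 0), 0.5)  # alpha-level false positives allowed
  expect_true(all(hits <= 2))
})

test_that("QC-RLSC flattens drift on QCs and enforces its preconditions", {
  s <- simulateBatchedTable(nFeatures = 60, nSamples = 40, nBatches = 2,
                            batchShift = c(1, 1), drift = 0.01, qcEvery = 5,
                            seed = 5)
  corrected <- correctQcrlsc(s$intensity, s$design)
  qc <- isQC(s$design)
  cvOf <- function(m) median(apply(m[, qc], 1, function(v) sd(v) / mean(v)))
  expect_lt(cvOf(corrected), 0.5 * cvOf(s$intensity))
  expect_true(all(corrected > 0))

  # flat QC trace: feature stays untouched (constant factor 1)
  flat <- s$intensity
  flat[1, ] <- 1000
  out <- correctQcrlsc(flat, s$design)
  expect_equal(unname(out[1, ]), rep(1000, ncol(flat)))

  two <- BatchDesign(sprintf("s%d", 1:6), batch = rep("b1", 6),
                     isQC = c(TRUE, TRUE, rep(FALSE, 4)))
  expect_error(correctQcrlsc(s$intensity[, 1:6], two), ">= 3 QC")
})

test_that("gradient length separates long unimodal turnover from compact clouds", {
  # unimodal species turnover along a long gradient
  set.seed(6)
  nS <- 40; nF <- 60
  grad <- seq(0, 10, length.out = nS)
  opt <- runif(nF, 0, 10)
  turnover <- t(vapply(opt, function(o) 200 * exp(-(grad - o)^2 / (2 * 0.8^2)),
                       numeric(nS))) + 0.1
  glLong <- gradientLength(t(turnover))
  expect_gt(glLong, 3)

  compact <- exp(matrix(rnorm(40 * 60, 5, 0.1), 40, 60))
  expect_lt(gradientLength(compact), 3)

  identical_rows <- matrix(rep(c(5, 1, 3, 8, 2), each = 10), nrow = 10)
  expect_lt(suppressWarnings(gradientLength(identical_rows)), 0.1)
  expect_error(gradientLength(rbind(c(1, 2), c(0, 0))), "all-zero")
})

test_that("the ordination chooser flips exactly at gradient length 3", {
  expect_equal(chooseOrdination(3), "CCA")
  expect_equal(chooseOrdination(3 + 1e-9), "PCA")
  expect_equal(chooseOrdination(0.5), "CCA")
})

test_that("a stronger planted batch shift scores strictly worse", {
  sc <- vapply(c(1.5, 3), function(shift) {
    s <- simulateBatchedTable(nFeatures = 80, nSamples = 30, nBatches = 2,
                              batchShift = c(1, shift), qcEvery = 5, seed = 7)
    evaluateCorrection(s$intensity, s$design)$score
  }, numeric(1))
  expect_lt(sc[1], sc[2])
})

test_that("the selector skips infeasible candidates and preserves shape/positivity", {
  noQc <- simulateBatchedTable(nFeatures = 60, nSamples = 24, nBatches = 2,
                               batchShift = c(1, 2), qcEvery = 0, seed = 8)
  sel <- suppressWarnings(selectBestCorrection(noQc$intensity, noQc$design))
  expect_match(sel$log$qc_rlsc, "skipped")
  expect_equal(dim(sel$corrected), dim(noQc$intensity))
  expect_true(all(sel$corrected > 0))
  noneScore <- evaluateCorrection(noQc$intensity, noQc$design)$score
  expect_lte(sel$score, noneScore + 1e-12)
})
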