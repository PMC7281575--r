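test_that("reference matching honors the ppm and RT gates", {
  ref <- data.frame(id = "r1", mz = 300.15, rt = 120, expectedRatio = 2)
  exact <- matchTruePeaks(data.frame(mz = 300.15, rt = 120), ref)
  expect_equal(nrow(exact$matched), 1L)
  off <- matchTruePeaks(data.frame(mz = 300.15 * (1 + 11e-6), rt = 120), ref)
  expect_equal(nrow(off$matched), 0L)
  expect_equal(off$unmatched, "r1")
  lateRt <- matchTruePeaks(data.frame(mz = 300.15, rt = 120 + 20), ref)
  expect_equal(nrow(lateRt$matched), 0L)
})

test_that("greedy matching equals the brute-force optimal assignment on a decoy toy", {
  set.seed(17)
  refMz <- seq(200, 600, by = 100) + runif(5, 0, 0.01)
  refRt <- seq(50, 250, by = 50)
  ref <- data.frame(id = sprintf("r%d", 1:5), mz = refMz, rt = refRt)
  feats <- data.frame(
    mz = c(refMz * (1 + runif(5, -3e-6, 3e-6)),  # 5 planted
           refMz + 0.5),                          # 5 decoys far in mass
    rt = c(refRt + runif(5, -2, 2), refRt))
  got <- matchTruePeaks(feats, ref)
  expect_equal(nrow(got$matched), 5L)
  expect_true(all(got$matched$feature %in% 1:5))
  # brute force: best one-to-one assignment among tolerance-passing pairs,
  # enumerated over all feature permutations of the references
  ppmOf <- function(f, r) abs(feats$mz[f] - ref$mz[r]) / ref$mz[r] * 1e6
  ok <- function(f, r) ppmOf(f, r) < 10 && abs(feats$rt[f] - ref$rt[r]) < 18
  perms <- expand.grid(rep(list(1:10), 5))
  valid <- apply(perms, 1, function(fs)
    !anyDuplicated(fs) && all(mapply(ok, fs, 1:5)))
  expect_true(any(valid))
  best <- perms[which(valid)[which.min(apply(perms[valid, , drop = FALSE], 1,
    function(fs) sum(mapply(ppmOf, fs, 1:5))))], ]
  expect_equal(sort(got$matched$feature), sort(unname(unlist(best))))
})

test_that("consensus quantification applies the 50% relative-error rule", {
  ref <- data.frame(id = c("a", "b", "c"), mz = 1:3, rt = 1:3,
                    expectedRatio = c(2, 2, 2))
  matched <- data.frame(refId = c("a", "b", "c"), feature = 1:3,
                        ppm = 0, dRt = 0)
  intensA <- c(4, 6.2, 5)   # ratios 2.0, 3.1, Inf-guard
  intensB <- c(2, 2, 0)
  out <- consensusQuantified(matched, ref, intensA, intensB)
  expect_equal(out$count, 1L)    # 2.0 counted; 3.1 is 55% off; c skipped
  expect_equal(out$skipped, 1L)
})

test_that("linearity counting matches a closed-form OLS oracle and calibrates", {
  factors <- rep(c(1, 0.2, 0.1, 0.05, 0.025), 2)
  linear <- matrix(rep(1000 * factors, 3), nrow = 3, byrow = TRUE)
  out <- countLinearPeaks(linear, factors)
  expect_equal(out$nLinear, 3L)

  # hand-computed OLS slope t-test on a printed 5-point toy
  x <- c(1, 0.5, 0.25, 0.1, 0.05)
  y <- c(980, 530, 260, 120, 40)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  res <- y - mean(y) - beta * (x - mean(x))
  se <- sqrt(sum(res^2) / 3 / sum((x - mean(x))^2))
  pHand <- 2 * pt(-abs(beta / se), 3)
  one <- countLinearPeaks(matrix(y, 1), x, alpha = pHand * 1.01)
  expect_equal(one$nLinear, 1L)
  one2 <- countLinearPeaks(matrix(y, 1), x, alpha = pHand * 0.99)
  expect_equal(one2$nLinear, 0L)

  # null calibration: pure-noise features pass at ~alpha
  set.seed(18)
  noise <- matrix(rnorm(4000 * 10, 1000, 50), nrow = 4000)
  cal <- countLinearPeaks(noise, factors, alpha = 0.05)
  expect_gt(cal$fraction, 0.05 / 4)   # two-sided slope>0 halves the rate
  expect_lt(cal$fraction, 0.05)

  # constant features are not counted
  const <- matrix(rep(c(500, 500, 500, 500, 500), 2), 1)
  expect_equal(countLinearPeaks(const, factors)$nLinear, 0L)
  expect_error(countLinearPeaks(linear[, 1:4], rep(c(1, 0.5), 2)), "3 distinct")
})

test_that("the Gaussian peak ratio counts the non-strict boundary and hand examples", {
  allG <- data.frame(gaussCor = c(0.95, 0.99), gaussP = c(0.01, 0.001))
  expect_equal(gaussianPeakRatio(allG), 1)
  straddle <- data.frame(gaussCor = c(0.9, 0.8999999, 0.95, NA),
                         gaussP = c(0.05, 0.01, 0.04, 0.01))
  expect_equal(gaussianPeakRatio(straddle), 2 / 4)
  expect_error(gaussianPeakRatio(data.frame(gaussCor = numeric(),
                                            gaussP = numeric())), "empty")
})
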