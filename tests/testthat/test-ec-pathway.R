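test_that("m/z matching reproduces hand arithmetic and the ppm gate", {
  params <- mummichogParams(ppm = 5, mode = "positive")
  cmpds <- data.frame(id = "hexose", mass = 180.0634)
  # M+H: (180.0634 + 1.007276) / 1 = 181.070676
  hit <- matchMz(data.frame(mz = 181.0707, rt = 100), cmpds, params)
  expect_true(any(hit$compound == "hexose" & hit$form == "M+H[1+]"))
  off <- matchMz(data.frame(mz = 181.0707 * (1 + 10e-6), rt = 100), cmpds, params)
  expect_false(any(off$form == "M+H[1+]"))
})

test_that("m/z matching equals the exhaustive triple enumeration on a toy", {
  set.seed(12)
  params <- mummichogParams(ppm = 8, mode = "positive")
  cmpds <- data.frame(id = sprintf("C%02d", 1:10), mass = runif(10, 100, 500))
  forms <- ionForms("positive")
  mzs <- c(
    (cmpds$mass[1:5] + 1.007276466),            # M+H hits
    (cmpds$mass[6:8] + 22.989218) * (1 + 3e-6), # M+Na, 3 ppm off
    runif(12, 100, 900))                        # mostly misses
  feats <- data.frame(mz = mzs, rt = runif(length(mzs), 10, 590))
  got <- matchMz(feats, cmpds, params)[, c("feature", "compound", "form")]
  want <- bruteForceMatch(feats, cmpds, params)
  key <- function(d) sort(paste(d$feature, d$compound, d$form))
  expect_equal(key(got), key(want))
})

test_that("the default RT window is 2% of the maximum retention time", {
  feats <- data.frame(mz = c(181.0707, 203.0526), rt = c(100, 600))
  cmpds <- data.frame(id = "hexose", mass = 180.0634)
  params <- mummichogParams(ppm = 10, mode = "positive")
  ecs <- buildEmpiricalCompounds(matchMz(feats, cmpds, params), feats, params)
  expect_equal(ecs$window, 600 * 0.02)
  # explicit rtTol overrides the fraction
  p2 <- mummichogParams(ppm = 10, rtTol = 30)
  ecs2 <- buildEmpiricalCompounds(matchMz(feats, cmpds, params), feats, p2)
  expect_equal(ecs2$window, 30)
})

test_that("features far apart in RT split into separate initial ECs", {
  cmpds <- data.frame(id = "X", mass = 300)
  feats <- data.frame(mz = rep(300 + 1.007276466, 2), rt = c(100, 200))
  params <- mummichogParams(ppm = 10, rtTol = 12)
  ecs <- buildEmpiricalCompounds(matchMz(feats, cmpds, params), feats, params)
  expect_length(ecs$initial, 2L)
  expect_length(ecs$final, 2L)
})

test_that("three-stage EC construction matches brute-force rule enumeration", {
  # 8 features over 3 compounds; A and B are isomers (identical mass), so
  # their shared M+H feature triggers the cross-compound merge rule
  PR <- 1.007276466
  cmpds <- data.frame(id = c("A", "B", "C"), mass = c(200.0, 200.0, 400.1))
  feats <- data.frame(
    mz = c(200 + PR,            # A & B M+H        rt 100
           200 + 22.989218,     # A & B M+Na       rt 101
           200 + 22.989218,     # same, far in RT  rt 400
           400.1 + PR,          # C M+H            rt 250
           400.1 + 18.033823,   # C M+NH4          rt 252
           150.5, 600.9, 700.1),# unmatched
    rt = c(100, 101, 400, 250, 252, 50, 60, 70))
  params <- mummichogParams(ppm = 5, rtTol = 12, mode = "positive")
  m <- matchMz(feats, cmpds, params)
  ecs <- buildEmpiricalCompounds(m, feats, params)

  # brute-force the three rules
  # rule 1: per compound, single-linkage RT clusters at threshold 12
  bfInitial <- list()
  for (cmp in unique(m$compound)) {
    sub <- m[m$compound == cmp, ]
    sub <- sub[order(sub$rt), ]
    cl <- cumsum(c(1, as.integer(diff(sub$rt) > 12)))
    for (g in split(seq_len(nrow(sub)), cl))
      bfInitial[[length(bfInitial) + 1]] <- sub[g, ]
  }
  expect_length(ecs$initial, length(bfInitial))
  # rule 2: merge on shared (form, mz within ppm, rt within window) member
  sharesMember <- function(x, y) {
    for (a in seq_len(nrow(x)))
      for (b in seq_len(nrow(y)))
        if (x$form[a] == y$form[b] &&
            abs(x$mz[a] - y$mz[b]) <= 5e-6 * x$mz[a] &&
            abs(x$rt[a] - y$rt[b]) <= 12) return(TRUE)
    FALSE
  }
  n <- length(bfInitial)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- i != j && sharesMember(bfInitial[[i]], bfInitial[[j]])
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n))
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    if (!changed) break
  }
  expect_length(ecs$merged, length(unique(comp)))
  # rule 3: primary-ion filter
  prim <- normalizeIonName(ionForms("positive")$name[ionForms("positive")$isPrimary])
  bfFinal <- sum(vapply(split(seq_len(n), comp), function(idx) {
    any(normalizeIonName(unlist(lapply(bfInitial[idx], `[[`, "form"))) %in% prim)
  }, logical(1)))
  expect_length(ecs$final, bfFinal)
  # the A M+Na / B M+H coincidence at rt 100-101 merged two compounds
  cmpdSets <- lapply(ecs$merged, `[[`, "compoundIds")
  expect_true(any(vapply(cmpdSets, function(s) all(c("A", "B") %in% s), logical(1))))
})

test_that("stage containment and primary-ion enforcement hold on simulated data", {
  s <- simulatePathwayData(effect = 0.3, seed = 14)
  params <- mummichogParams(ppm = 10, mode = "positive")
  ecs <- buildEmpiricalCompounds(matchMz(s$features, s$compounds, params),
                                 s$features, params)
  expect_lte(length(ecs$final), length(ecs$merged))
  expect_lte(length(ecs$merged), length(ecs$initial))
  expect_true(all(vapply(ecs$final, `[[`, logical(1), "hasPrimary")))
  # RT span of initial ECs never exceeds the window
  spans <- vapply(ecs$initial, function(e) diff(e$rtSpan), numeric(1))
  expect_true(all(spans <= ecs$window + 1e-9))
})

test_that("whitespace and sign variants of primary-ion names normalize identically", {
  variants <- c("M+H [1+]", "M+H[1+]", "M−H[−]", "M-H [1-]",
                "M-H2O+H [1+]", "M−2H [2−]")
  normalized <- normalizeIonName(variants)
  expect_equal(normalized[1], normalized[2])
  expect_equal(normalized[3], normalized[4])
  expect_equal(normalized[3], "M-H[1-]")
  expect_equal(normalized[5], "M-H2O+H[1+]")
  expect_equal(normalized[6], "M-2H[2-]")
})

test_that("library conversion is exact set algebra and drops empty pathways", {
  ecs <- list(list(ecId = "e1", compoundIds = c("c1", "c2")),
              list(ecId = "e2", compoundIds = "c3"),
              list(ecId = "e3", compoundIds = "c2"))
  lib <- list(p1 = c("c1"), p2 = c("c2", "c9"), p3 = "c7", p4 = c("c2", "c3"))
  conv <- convertLibrary(lib, ecs)
  expect_equal(conv$p1, 1L)
  expect_equal(conv$p2, c(1L, 3L))       # EC with two compounds is in both
  expect_equal(conv$p4, c(1L, 2L, 3L))
  expect_false("p3" %in% names(conv))    # no matched compound -> dropped
})

test_that("the raw enrichment p equals the hand hypergeometric with EASE shift", {
  # tiny universe: 10 ECs, 4 significant, pathway holds 5 of which 3 significant
  pEase <- metaboflow:::easeP(k = 3, m = 5, N = 10, n = 4)
  expect_equal(pEase, phyper(1, 5, 5, 4, lower.tail = FALSE))
  # cross-check against fisher.test on the EASE-shifted table
  ft <- fisher.test(matrix(c(2, 2, 3, 3), 2), alternative = "greater")
  expect_equal(pEase, ft$p.value, tolerance = 1e-12)
  expect_equal(metaboflow:::easeP(0, 5, 10, 4), 1)
  expect_equal(metaboflow:::easeP(1, 5, 10, 4), 1)  # single hit: EASE kills it
})

test_that("enrichment output is invariant to feature row order and pRaw to the seed", {
  s <- simulatePathwayData(effect = 1, seed = 15)
  params <- mummichogParams(ppm = 10, pCutoff = 0.01, nPerm = 30, seed = 1)
  r1 <- enrichMummichog(s$features, s$library, s$compounds, params)
  perm <- sample(nrow(s$features))
  r2 <- enrichMummichog(s$features[perm, ], s$library, s$compounds, params)
  expect_equal(r1[order(r1$pathway), c("pathway", "totalEcs", "hitsSig", "pRaw")],
               r2[order(r2$pathway), c("pathway", "totalEcs", "hitsSig", "pRaw")],
               ignore_attr = TRUE)
  params2 <- mummichogParams(ppm = 10, pCutoff = 0.01, nPerm = 30, seed = 99)
  r3 <- enrichMummichog(s$features, s$library, s$compounds, params2)
  expect_equal(r1[order(r1$pathway), "pRaw"], r3[order(r3$pathway), "pRaw"])
  # determinism under the same seed
  r4 <- enrichMummichog(s$features, s$library, s$compounds, params)
  expect_equal(r1, r4)
})

test_that("degenerate significance lists are rejected", {
  s <- simulatePathwayData(effect = 0, seed = 16)
  params <- mummichogParams(pCutoff = 2, nPerm = 10)   # everything significant
  expect_error(enrichMummichog(s$features, s$library, s$compounds, params),
               "degenerate")
  params0 <- mummichogParams(pCutoff = 1e-12, nPerm = 10)
  expect_error(enrichMummichog(s$features, s$library, s$compounds, params0),
               "no significant")
})
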