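# Retention-time-aware pathway activity prediction: m/z annotation
# against ion-form tables, empirical-compound (EC) construction in three
# stages (RT splitting, cross-compound merging, primary-ion enforcement),
# pathway library conversion to EC space, and permutation-calibrated
# enrichment with a Gamma-fitted null.

#' Parameters for empirical-compound pathway analysis
#'
#' @param ppm instrument m/z tolerance (parts per million).
#' @param mode ionization mode.
#' @param rtFrac retention-time window as a fraction of the maximum RT in
#'   the feature list (default 0.02); ignored when `rtTol` is given.
#' @param rtTol absolute retention-time window, seconds (overrides
#'   `rtFrac`).
#' @param forcePrimaryIon keep only ECs containing at least one primary
#'   ion (default TRUE).
#' @param pCutoff feature significance threshold.
#' @param nPerm permutations for the Gamma null (default 100).
#' @param seed integer seed for the permutation draw.
#' @param ecSignificance `"any"` (an EC is significant when any member
#'   feature is) or `"primary"` (only primary-ion members count).
#' @return list of class `MummichogParams`.
#' @export
mummichogParams <- function(ppm = 10, mode = c("positive", "negative"),
                            rtFrac = 0.02, rtTol = NULL,
                            forcePrimaryIon = TRUE, pCutoff = 0.05,
                            nPerm = 100L, seed = 1L,
                            ecSignificance = c("any", "primary")) {
  mode <- match.arg(mode)
  stopifnot(ppm > 0, rtFrac > 0, is.null(rtTol) || rtTol > 0)
  structure(list(ppm = ppm, mode = mode, rtFrac = rtFrac, rtTol = rtTol,
                 forcePrimaryIon = forcePrimaryIon, pCutoff = pCutoff,
                 nPerm = as.integer(nPerm), seed = as.integer(seed),
                 ecSignificance = match.arg(ecSignificance)),
            class = "MummichogParams")
}

#' Match m/z features to compounds over all ion forms
#'
#' A feature matches a (compound, form) pair when
#' `|observed - theoretical| / theoretical <= ppm * 1e-6`, with
#' `theoretical = (multiplier * M + massShift) / |charge|`. One feature
#' may match many pairs.
#'
#' @param features data.frame with columns `mz`, `rt`.
#' @param compounds data.frame with columns `id`, `mass` (neutral
#'   monoisotopic, Da).
#' @param params a [mummichogParams()].
#' @return data.frame with `feature` (row index into `features`), `mz`,
#'   `rt`, `compound`, `form`.
#' @export
matchMz <- function(features, compounds, params = mummichogParams()) {
  empty <- data.frame(feature = integer(), mz = numeric(), rt = numeric(),
                      compound = character(), form = character(),
                      stringsAsFactors = FALSE)
  if (nrow(compounds) == 0L || nrow(features) == 0L) return(empty)
  forms <- ionForms(params$mode)
  out <- list()
  for (f in seq_len(nrow(forms))) {
    theo <- theoreticalMz(compounds$mass, forms[f, ])
    for (i in seq_len(nrow(features))) {
      hit <- which(abs(features$mz[i] - theo) / theo <= params$ppm * 1e-6)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          feature = i, mz = features$mz[i], rt = features$rt[i],
          compound = compounds$id[hit], form = forms$name[f],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$compound, res$form, res$feature), ]
  rownames(res) <- NULL
  res
}

#' Build empirical compounds in three stages
#'
#' Stage 1 (initial): per compound, matched features are split by
#' single-linkage clustering on retention time with the RT window as the
#' linkage threshold (window = `rtTol` if set, else
#' `max(rt over the feature list) * rtFrac`). Stage 2 (merged): ECs of
#' different compounds are unified when they share a member with the same
#' ion form, the same m/z (within ppm) and retention time within the
#' window. Stage 3 (final): when `forcePrimaryIon`, only ECs containing
#' at least one primary-ion member are kept.
#'
#' @param matches output of [matchMz()].
#' @param features the feature data.frame the matches refer to (must
#'   carry `rt`).
#' @param params a [mummichogParams()].
#' @return list with `initial`, `merged`, `final` (each a list of ECs:
#'   `ecId`, `compoundIds`, `members` data.frame, `rtSpan`,
#'   `hasPrimary`) and `window` (the applied RT window, seconds).
#' @export
buildEmpiricalCompounds <- function(matches, features, params = mummichogParams()) {
  if (is.null(features$rt) || all(is.na(features$rt)))
    stop("no retention times on the feature list; RT-aware EC construction ",
         "requires them (compound-space analysis without RT is out of scope)")
  window <- if (!is.null(params$rtTol)) params$rtTol else max(features$rt) * params$rtFrac
  primSet <- normalizeIonName(ionForms(params$mode)$name[ionForms(params$mode)$isPrimary])
  if (nrow(matches)) matches$formN <- normalizeIonName(matches$form)
  mkEc <- function(id, sub) {
    list(ecId = id, compoundIds = unique(sub$compound), members = sub,
         rtSpan = range(sub$rt),
         hasPrimary = any(sub$formN %in% primSet))
  }
  initial <- list()
  if (nrow(matches)) {
    for (sub in split(matches, matches$compound)) {
      sub <- sub[order(sub$rt), , drop = FALSE]
      cl <- cumsum(c(1L, as.integer(diff(sub$rt) > window)))
      for (g in split(seq_len(nrow(sub)), cl)) {
        initial[[length(initial) + 1L]] <-
          mkEc(sprintf("EC%04d", length(initial) + 1L), sub[g, , drop = FALSE])
      }
    }
  }
  # stage 2: union-find over ECs sharing an identical (mz, form) member
  nEc <- length(initial)
  parent <- seq_len(nEc)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nEc > 1L) {
    memMz <- lapply(initial, function(e) e$members$mz)
    memRt <- lapply(initial, function(e) e$members$rt)
    memForm <- lapply(initial, function(e) e$members$formN)
    for (i in seq_len(nEc - 1L)) {
      mzI <- memMz[[i]]; rtI <- memRt[[i]]; fI <- memForm[[i]]
      tolI <- params$ppm * 1e-6 * mzI
      for (j in (i + 1L):nEc) {
        mzJ <- memMz[[j]]; rtJ <- memRt[[j]]; fJ <- memForm[[j]]
        linked <- FALSE
        for (a in seq_along(mzI)) {
          if (any(fJ == fI[a] & abs(mzJ - mzI[a]) <= tolI[a] &
                  abs(rtJ - rtI[a]) <= window)) { linked <- TRUE; break }
        }
        if (linked) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(nEc), find, integer(1))
  merged <- list()
  for (r in unique(roots)) {
    idx <- which(roots == r)
    mem <- unique(do.call(rbind, lapply(initial[idx], `[[`, "members")))
    merged[[length(merged) + 1L]] <- mkEc(sprintf("MEC%04d", length(merged) + 1L), mem)
  }
  final <- if (params$forcePrimaryIon) {
    Filter(function(e) isTRUE(e$hasPrimary), merged)
  } else merged
  list(initial = initial, merged = merged, final = final, window = window)
}

#' Convert a pathway library from compound to EC space
#'
#' An EC belongs to a pathway iff its compound ids intersect the
#' pathway's compound set; pathways matching no EC are dropped.
#'
#' @param library named list: pathway -> character vector of compound
#'   ids.
#' @param finalEcs the `final` element of [buildEmpiricalCompounds()].
#' @return named list: pathway -> integer indices into `finalEcs`.
#' @export
convertLibrary <- function(library, finalEcs) {
  ecCmpds <- lapply(finalEcs, `[[`, "compoundIds")
  out <- lapply(library, function(cmpds) {
    which(vapply(ecCmpds, function(cc) any(cc %in% cmpds), logical(1)))
  })
  out[vapply(out, length, integer(1)) > 0L]
}

# EASE-corrected one-sided Fisher p: hypergeometric upper tail of
# (hits - 1) successes among pathway ECs. k hits, m pathway ECs, N total
# ECs, n significant ECs.
easeP <- function(k, m, N, n) {
  if (k <= 0) return(1)
  stats::phyper(k - 2, m, N - m, n, lower.tail = FALSE)
}

#' Pathway activity prediction from m/z features (mummichog v2)
#'
#' Runs annotation ([matchMz()]), EC construction
#' ([buildEmpiricalCompounds()]) and library conversion
#' ([convertLibrary()]), maps the significant feature list (p <=
#' `pCutoff`) to significant ECs (any-member rule by default), and tests
#' each pathway with a one-sided Fisher exact test with EASE correction
#' (hits - 1). The null model draws `nPerm` feature lists of the observed
#' significant size from the reference features, recomputes the
#' per-pathway EASE scores, fits a Gamma distribution by maximum
#' likelihood to the pooled null `-ln p`, and reports the upper-tail
#' Gamma probability of each observed `-ln p`. Deterministic under the
#' seed.
#'
#' @param featureTable data.frame with `mz`, `rt`, `p` (and optionally a
#'   statistic column).
#' @param library named list: pathway -> compound ids.
#' @param compounds data.frame with `id`, `mass`.
#' @param params a [mummichogParams()].
#' @return data.frame sorted by `pGamma`: `pathway`, `totalEcs`,
#'   `hitsSig`, `pRaw`, `pGamma`; attributes `nEcs` (universe size),
#'   `nSigEcs`, `window`.
#' @export
enrichMummichog <- function(featureTable, library, compounds,
                            params = mummichogParams()) {
  stopifnot(all(c("mz", "rt", "p") %in% names(featureTable)))
  sig <- which(featureTable$p <= params$pCutoff)
  if (length(sig) == 0L) stop("no significant features at pCutoff = ", params$pCutoff)
  if (length(sig) == nrow(featureTable))
    stop("all features significant: the 2x2 table is degenerate")
  matches <- matchMz(featureTable, compounds, params)
  ecs <- buildEmpiricalCompounds(matches, featureTable, params)
  ecLib <- convertLibrary(library, ecs$final)
  if (!length(ecLib)) stop("no pathway maps to any empirical compound")
  N <- length(ecs$final)
  # feature -> ECs incidence
  ecFeat <- lapply(ecs$final, function(e) {
    if (params$ecSignificance == "primary") {
      prim <- normalizeIonName(ionForms(params$mode)$name[ionForms(params$mode)$isPrimary])
      unique(e$members$feature[normalizeIonName(e$members$form) %in% prim])
    } else unique(e$members$feature)
  })
  sigEcsOf <- function(sigFeatures) {
    which(vapply(ecFeat, function(ff) any(ff %in% sigFeatures), logical(1)))
  }
  obsSigEcs <- sigEcsOf(sig)
  n <- length(obsSigEcs)
  pathNames <- names(ecLib)
  obs <- vapply(pathNames, function(pw) {
    m <- length(ecLib[[pw]])
    k <- length(intersect(ecLib[[pw]], obsSigEcs))
    c(m = m, k = k, p = easeP(k, m, N, n))
  }, numeric(3))
  # permutation null: resample |sig| features from the reference
  nullP <- withSeed(params$seed, {
    vapply(seq_len(params$nPerm), function(b) {
      fs <- sample(nrow(featureTable), length(sig))
      se <- sigEcsOf(fs)
      ns <- length(se)
      vapply(pathNames, function(pw) {
        easeP(length(intersect(ecLib[[pw]], se)), length(ecLib[[pw]]), N, ns)
      }, numeric(1))
    }, numeric(length(pathNames)))
  })
  # null scores: -ln p per pathway per permutation. The null depends
  # strongly on the pathway's EC count (both scale and shape), so the
  # Gamma is fitted per pathway to its own permutation null; pathways
  # whose null is degenerate (almost all permutations give p = 1) fall
  # back to the raw Fisher/EASE p
  nullX <- matrix(pmax(-log(pmin(pmax(as.numeric(nullP), 1e-300), 1)), 1e-8),
                  nrow = length(pathNames))
  obsX <- pmax(-log(pmin(pmax(obs["p", ], 1e-300), 1)), 1e-8)
  pGamma <- vapply(seq_along(pathNames), function(i) {
    x <- nullX[i, ]
    if (obsX[i] <= 1e-6) return(1)  # zero hits can never be enriched
    pos <- x[x > 1e-6]
    if (length(pos) < 10L || stats::sd(pos) <= 0) return(obs["p", i])
    # zero-inflated Gamma: the p = 1 permutations form an atom at zero;
    # the Gamma models the positive part and the tail is weighted by the
    # positive fraction, P(X >= obs) = prop * P(Gamma >= obs)
    prop <- length(pos) / length(x)
    gfit <- tryCatch(
      suppressWarnings(fitdistrplus::fitdist(pos, "gamma", method = "mle",
                                             lower = c(1e-6, 1e-6))),
      error = function(e) NULL)
    tail <- if (is.null(gfit)) {
      k <- (mean(pos) / stats::sd(pos))^2  # moment fallback
      stats::pgamma(obsX[i], shape = k, rate = k / mean(pos), lower.tail = FALSE)
    } else {
      stats::pgamma(obsX[i], shape = gfit$estimate[["shape"]],
                    rate = gfit$estimate[["rate"]], lower.tail = FALSE)
    }
    min(1, prop * tail)
  }, numeric(1))
  res <- data.frame(pathway = pathNames,
                    totalEcs = as.integer(obs["m", ]),
                    hitsSig = as.integer(obs["k", ]),
                    pRaw = obs["p", ], pGamma = pGamma,
                    stringsAsFactors = FALSE)
  res <- res[order(res$pGamma, res$pRaw, -res$hitsSig), ]
  rownames(res) <- NULL
  attr(res, "nEcs") <- N
  attr(res, "nSigEcs") <- n
  attr(res, "window") <- ecs$window
  res
}
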