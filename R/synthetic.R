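# Synthetic primary/confirmatory screen pairs with known ground truth.
# The generator emulates the statistical structure of a screening
# benchmark: a large library with sparse binary fingerprint-like features,
# a low hit rate, truly active compounds driven by a compact set of causal
# ("pharmacophore") features, feature-linked assay interferents whose
# inflated readouts make them primary hits that fail confirmation, a
# tunable admixture of purely random fluctuation false positives, and
# forced false negatives for dark-chemical-matter mining.

#' Specification of a simulated screen
#'
#' Defaults are the package's reference study conditions: 20,000
#' compounds with 1,024 sparse binary features, a 1 percent hit rate, a
#' 40 percent false-positive fraction among hits, 8 strong causal
#' features versus 64 diffuse interference features, a readout shift of 8
#' noise SDs for actives and a heterogeneous shift of 9 +/- 2 for
#' interferents - interferent readouts overlap the active cluster with an
#' outlier tail above it, and both effect clusters sit clear of the
#' inactive background so composition targets are met by construction -
#' a quarter of false positives being feature-free statistical flukes,
#' and 2 forced false negatives.
#'
#' @param nCompounds library size.
#' @param nFeatures binary feature count (hashed-fingerprint-like).
#' @param nCausal number of causal (true pharmacophore) features.
#' @param nInterference number of interference-linked features (disjoint
#'   from the causal set).
#' @param hitRate target primary hit rate in (0, 0.5).
#' @param fpFraction target false-positive fraction among hits, in
#'   [0, 1).
#' @param noiseFpFraction fraction of the false positives that are pure
#'   statistical flukes (no feature signal).
#' @param fnCount truly active compounds whose readout is forced below
#'   the hit threshold (false negatives).
#' @param activityEffect readout shift of truly active compounds, in
#'   noise SD units.
#' @param interferenceEffect mean readout shift of interferents, in noise
#'   SD units.
#' @param interferenceSpread per-compound SD of the interferent readout
#'   shift: interference mechanisms are heterogeneous, so interferent
#'   readouts overlap the active cluster while an outlier tail exceeds
#'   it.
#' @param readoutNoiseSd readout noise standard deviation.
#' @param seed default RNG seed for \code{\link{simulateScreen}}.
#' @return validated specification list.
#' @export
syntheticSpec <- function(nCompounds = 20000L, nFeatures = 1024L,
                          nCausal = 8L, nInterference = 64L,
                          hitRate = 0.01, fpFraction = 0.4,
                          noiseFpFraction = 0.25, fnCount = 2L,
                          activityEffect = 8, interferenceEffect = 9,
                          interferenceSpread = 2,
                          readoutNoiseSd = 1, seed = 0L) {
  if (hitRate <= 0 || hitRate >= 0.5)
    stop("hitRate must be in (0, 0.5)", call. = FALSE)
  if (fpFraction < 0 || fpFraction >= 1)
    stop("fpFraction target outside [0, 1) rejected", call. = FALSE)
  if (noiseFpFraction < 0 || noiseFpFraction > 1)
    stop("noiseFpFraction must be in [0, 1]", call. = FALSE)
  if (nCausal + nInterference > nFeatures)
    stop("feature groups must be disjoint and fit in nFeatures",
         call. = FALSE)
  if (activityEffect <= 0 || readoutNoiseSd <= 0)
    stop("effects and noise must be positive", call. = FALSE)
  if (interferenceSpread < 0)
    stop("interferenceSpread must be nonnegative", call. = FALSE)
  list(nCompounds = as.integer(nCompounds),
       nFeatures = as.integer(nFeatures),
       nCausal = as.integer(nCausal),
       nInterference = as.integer(nInterference),
       hitRate = hitRate, fpFraction = fpFraction,
       noiseFpFraction = noiseFpFraction, fnCount = as.integer(fnCount),
       activityEffect = activityEffect,
       interferenceEffect = interferenceEffect,
       interferenceSpread = interferenceSpread,
       readoutNoiseSd = readoutNoiseSd, seed = as.integer(seed))
}

# Solve the logistic intercept b so that mean(plogis(eta + b)) = target.
.calibrateIntercept <- function(eta, target) {
  f <- function(b) mean(stats::plogis(eta + b)) - target
  stats::uniroot(f, c(-40, 40), tol = 1e-10)$root
}

#' Simulate a primary/confirmatory screen pair
#'
#' Draws sparse binary features with per-feature Bernoulli rates sampled
#' log-uniformly; truly active compounds are drawn without replacement
#' with probability following a logistic propensity on the causal
#' features (intercept calibrated to the target active rate, counts
#' matching the target exactly), interferents likewise from a logistic
#' propensity on the interference features.
#' The readout is the sum of the activity effect (if truly active), the
#' interference effect (if interferent), an equal-size boost for the
#' fluke false positives, and Gaussian noise; the primary hit call takes
#' the top \code{hitRate} quantile. Confirmatory outcomes exist for hits
#' only: truly active hits confirm, all others are false positives
#' (a third of them reported "inconclusive" rather than "inactive").
#' \code{fnCount} truly active hits then have their readout forced below
#' the threshold. Realized composition targets are met within binomial
#' tolerance; a spec whose effect sizes cannot realize them raises an
#' error with a diagnostic.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param seed RNG seed (default: the spec's).
#' @return list with \code{screen} (a structure-free
#'   \linkS4class{ScreenSet}), \code{features}
#'   (a sparse \linkS4class{FeatureMatrix}), \code{truth} (data.frame of
#'   per-compound ground-truth flags) and \code{summary} (realized
#'   counts).
#' @export
simulateScreen <- function(spec = syntheticSpec(), seed = spec$seed) {
  n <- spec$nCompounds
  d <- spec$nFeatures
  .withSeed(seed, {
    rates <- exp(stats::runif(d, log(0.002), log(0.1)))
    nzPerFeat <- stats::rbinom(d, n, rates)
    jj <- rep(seq_len(d), nzPerFeat)
    ii <- unlist(lapply(nzPerFeat, function(k) sample.int(n, k)),
                 use.names = FALSE)
    X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, d))
    causalIdx <- seq_len(spec$nCausal)
    interIdx <- spec$nCausal + seq_len(spec$nInterference)
    nh <- round(n * spec$hitRate)
    targetActive <- (1 - spec$fpFraction) * spec$hitRate +
      spec$fnCount / n
    targetInterf <- spec$fpFraction * (1 - spec$noiseFpFraction) *
      spec$hitRate
    nFluke <- round(spec$fpFraction * spec$noiseFpFraction * nh)

    # exact-count weighted sampling: inclusion probability is monotone in
    # the logistic propensity, but group sizes hit the targets exactly so
    # the top-quantile hit cut stays inside the effect clusters
    wAct <- stats::runif(spec$nCausal, 3, 5)
    etaAct <- as.numeric(X[, causalIdx, drop = FALSE] %*% wAct)
    bAct <- .calibrateIntercept(etaAct, targetActive)
    kAct <- round(targetActive * n)
    trulyActive <- rep(FALSE, n)
    trulyActive[sample.int(n, kAct,
                           prob = stats::plogis(etaAct + bAct))] <- TRUE

    interferent <- rep(FALSE, n)
    if (targetInterf > 0) {
      wInt <- stats::runif(spec$nInterference, 0.5, 1.5)
      etaInt <- as.numeric(X[, interIdx, drop = FALSE] %*% wInt)
      bInt <- .calibrateIntercept(etaInt, targetInterf)
      kInt <- round(targetInterf * n)
      interferent[sample.int(n, kInt,
                             prob = stats::plogis(etaInt + bInt))] <- TRUE
    }
    fluke <- rep(FALSE, n)
    if (nFluke > 0) {
      pool <- which(!trulyActive & !interferent)
      fluke[sample(pool, min(nFluke, length(pool)))] <- TRUE
    }

    interferenceShift <- stats::rnorm(n, spec$interferenceEffect,
                                      spec$interferenceSpread)
    readout <- spec$activityEffect * trulyActive +
      interferenceShift * (interferent & !trulyActive) +
      spec$activityEffect * fluke +
      stats::rnorm(n, 0, spec$readoutNoiseSd)
    thr <- sort(readout, decreasing = TRUE)[nh]
    primaryActive <- readout >= thr

    forcedFN <- rep(FALSE, n)
    if (spec$fnCount > 0) {
      cand <- which(trulyActive & primaryActive)
      pick <- cand[seq_len(min(spec$fnCount, length(cand)))]
      forcedFN[pick] <- TRUE
      readout[pick] <- thr - abs(stats::rnorm(length(pick), 1, 0.25))
      primaryActive[pick] <- FALSE
    }

    outcome <- rep("untested", n)
    hitIdx <- which(primaryActive)
    confirms <- trulyActive[hitIdx]
    outcome[hitIdx[confirms]] <- "active"
    fpHits <- hitIdx[!confirms]
    inconc <- fpHits[seq_along(fpHits) %% 3L == 0L]
    outcome[fpHits] <- "inactive"
    outcome[inconc] <- "inconclusive"

    realizedFp <- length(fpHits) / length(hitIdx)
    tol <- 4 * sqrt(max(spec$fpFraction * (1 - spec$fpFraction), 0.01) /
                    length(hitIdx)) + 0.02
    if (abs(realizedFp - spec$fpFraction) > tol)
      stop(sprintf(paste0("infeasible targets: realized FP fraction %.3f ",
                          "vs target %.3f (|diff| > %.3f); increase effect ",
                          "sizes or lower noise"),
                   realizedFp, spec$fpFraction, tol), call. = FALSE)

    ids <- sprintf("CPD%06d", seq_len(n))
    screen <- ScreenSet(compoundId = ids, smiles = NA_character_,
                        readout = readout, primaryActive = primaryActive,
                        confirmatoryOutcome = outcome,
                        name = sprintf("simulated_fp%.2f_seed%d",
                                       spec$fpFraction, seed),
                        metadata = list(syntheticSpec = spec, seed = seed))
    rownames(X) <- ids
    features <- FeatureMatrix(X, rowIds = ids, featureKind = "custom",
                              params = list(kind = "simulated_binary",
                                            rates = "loguniform(0.002,0.1)"))
    truth <- data.frame(compoundId = ids, trulyActive = trulyActive,
                        interferent = interferent, fluke = fluke,
                        forcedFN = forcedFN, stringsAsFactors = FALSE)
    list(screen = screen, features = features, truth = truth,
         summary = list(nHits = length(hitIdx),
                        realizedFpFraction = realizedFp,
                        nTrulyActive = sum(trulyActive),
                        nInterferent = sum(interferent),
                        nFluke = sum(fluke),
                        nForcedFN = sum(forcedFN),
                        seed = seed))
  })
}

.FIXTURE_CORES <- c(benzene = "c1ccccc1", pyridine = "c1ccncc1",
                    cyclohexane = "C1CCCCC1", furan = "c1ccoc1",
                    thiophene = "c1ccsc1", pyrimidine = "c1cncnc1",
                    naphthalene = "c1ccc2ccccc2c1",
                    cyclopentane = "C1CCCC1")
.FIXTURE_SUBS <- c("C", "CC", "CCC", "CCCC", "CC(C)", "N", "O", "CO",
                   "CCO", "Cl", "F", "CCN")

#' Deterministic SMILES fixtures from a scaffold/substituent grammar
#'
#' Assembles valid structures by prepending a substituent chain to a ring
#' scaffold, cycling through \code{scaffoldClasses} distinct scaffolds so
#' the Murcko scaffold diversity of the emitted set is exactly
#' \code{min(n, scaffoldClasses) / n}. Strings are emitted in canonical
#' form, so they survive standardization unchanged. Reproducible per
#' seed (the seed shuffles substituent assignment only, never scaffold
#' multiplicity).
#'
#' @param n number of structures (at most the template capacity,
#'   \code{scaffoldClasses * 12}).
#' @param seed RNG seed.
#' @param scaffoldClasses number of distinct ring scaffolds to cycle
#'   (1 to 8).
#' @return character vector of canonical SMILES.
#' @export
#' @examples
#' fixtureSmiles(10, seed = 1, scaffoldClasses = 6)
fixtureSmiles <- function(n, seed = 0L, scaffoldClasses = 6L) {
  if (scaffoldClasses < 1L || scaffoldClasses > length(.FIXTURE_CORES))
    stop("scaffoldClasses must be in 1..", length(.FIXTURE_CORES),
         call. = FALSE)
  capacity <- scaffoldClasses * length(.FIXTURE_SUBS)
  if (n > capacity)
    stop(sprintf("n too large: template capacity is %d", capacity),
         call. = FALSE)
  cores <- .FIXTURE_CORES[seq_len(scaffoldClasses)]
  subsOrder <- .withSeed(seed, sample(.FIXTURE_SUBS))
  smi <- character(n)
  for (i in seq_len(n)) {
    core <- cores[(i - 1L) %% scaffoldClasses + 1L]
    sub <- subsOrder[(i - 1L) %/% scaffoldClasses + 1L]
    smi[i] <- paste0(sub, core)
  }
  canonicalSmiles(smi)
}
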