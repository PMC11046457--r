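# MVS-A core: boosting trace, influence math, triage and false-negative
# mining.

test_that("trace starts at the prevalence log-odds and reconstructs margins", {
  d <- makeNoisyData(n = 120, d = 4, seed = 2)
  cfg <- boostingConfig(nIterations = 25, maxDepth = 3,
                        minChildSamples = 5, seed = 1)
  tr <- fitBoostingTrace(d$X, d$y, cfg)
  m <- traceMargins(tr)
  expect_identical(dim(m), c(26L, 120L))
  expect_equal(unname(m[1, 1]), qlogis(mean(d$y)))
  expect_identical(diff(range(m[1, ])), 0)
  # staged reconstruction agrees with the trainer's own staged predictions
  dtr <- xgboost::xgb.DMatrix(d$X, label = d$y, nthread = 1)
  params <- list(objective = "binary:logistic", eta = 0.1, max_depth = 3,
                 min_child_weight = cfg$minChildSamples * mean(d$y) *
                   (1 - mean(d$y)),
                 base_score = mean(d$y), nthread = 1, seed = 1,
                 tree_method = "hist")
  bst <- xgboost::xgb.train(params, dtr, nrounds = 25, verbose = 0)
  for (t in c(1, 7, 25)) {
    staged <- predict(bst, dtr, outputmargin = TRUE,
                      iterationrange = c(1, t))
    expect_equal(unname(m[t + 1, ]), staged, tolerance = 1e-5)
  }
})

test_that("training log-loss is non-increasing along the trace", {
  d <- makeNoisyData(n = 100, d = 3, seed = 5)
  tr <- fitBoostingTrace(d$X, d$y,
                         boostingConfig(nIterations = 40, maxDepth = 3,
                                        minChildSamples = 5, seed = 2))
  m <- traceMargins(tr)
  ll <- apply(m, 1, function(f) {
    p <- plogis(f)
    -mean(d$y * log(p) + (1 - d$y) * log(1 - p))
  })
  expect_true(all(diff(ll) <= 1e-10))
})

test_that("a separable two-cluster toy reaches perfect training accuracy", {
  d <- makeTwoClusterData(nActive = 10, nInactive = 10, nFlip = 0,
                          mu = 3, seed = 4)
  tr <- fitBoostingTrace(d$X, d$y,
                         boostingConfig(nIterations = 10, maxDepth = 2,
                                        minChildSamples = 2, seed = 1))
  pred <- as.numeric(traceMargins(tr)[11, ] > 0)
  expect_identical(pred, d$y)
})

test_that("degenerate inputs are rejected with informative errors", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fitBoostingTrace(X, rep(1, 20), boostingConfig()),
               "degenerate labels")
  expect_error(fitBoostingTrace(X, c(rep(1, 10), rep(0, 10)),
                                boostingConfig(minChildSamples = 50)),
               "below minChildSamples")
  expect_error(boostingConfig(nIterations = 0), "nIterations")
  expect_error(boostingConfig(learningRate = 0), "learningRate")
})

test_that("gradient and hessian follow the log-loss closed forms", {
  gh <- loglossGradHess(0, 1)
  expect_identical(gh$g, -0.5)
  expect_identical(gh$h, 0.25)
  gh0 <- loglossGradHess(0, 0)
  expect_identical(gh0$g, 0.5)
  # saturation: a perfectly fit positive has vanishing g and h
  ghInf <- loglossGradHess(30, 1)
  expect_lt(abs(ghInf$g), 1e-12)
  expect_lt(ghInf$h, 1e-12)
  grid <- expand.grid(F = seq(-10, 10, by = 0.25), y = c(0, 1))
  gh <- loglossGradHess(grid$F, grid$y)
  p <- 1 / (1 + exp(-grid$F))
  expect_lt(max(abs(gh$g - (p - grid$y))), 1e-12)
  expect_lt(max(abs(gh$h - p * (1 - p))), 1e-12)
  expect_true(all(gh$g > -1 & gh$g < 1))
  expect_true(all(gh$h > 0 & gh$h <= 0.25))
})

test_that("influence reduces to its closed forms at the edges", {
  # single-iteration trace at F = 0, y = 1, lambda = 1
  m <- matrix(0, 2, 1, dimnames = list(NULL, "a"))
  tr <- new("BoostingTrace", margins = m, config = list(nIterations = 1L))
  s <- influenceValues(mvsaInfluence(tr, 1, lambda = 1))
  expect_equal(unname(s), sqrt(0.3125), tolerance = 1e-15)
  # lambda = 0 reduces exactly to the summed absolute gradients
  d <- makeNoisyData(n = 80, seed = 3)
  trace <- fitBoostingTrace(d$X, d$y,
                            boostingConfig(nIterations = 15, maxDepth = 2,
                                           minChildSamples = 5, seed = 1))
  s0 <- influenceValues(mvsaInfluence(trace, d$y, lambda = 0))
  mm <- traceMargins(trace)
  gAbs <- rowSums(vapply(1:15, function(t)
    abs(loglossGradHess(mm[t, ], d$y)$g), numeric(80)))
  expect_equal(unname(s0), unname(gAbs), tolerance = 1e-12)
  # mean aggregation is the sum divided by T
  sMean <- influenceValues(mvsaInfluence(trace, d$y, aggregation = "mean"))
  sSum <- influenceValues(mvsaInfluence(trace, d$y))
  expect_equal(sMean, sSum / 15, tolerance = 1e-12)
  expect_error(mvsaInfluence(trace, d$y, lambda = -1), "nonnegative")
})

test_that("scores are bounded and vanish for perfectly fit samples", {
  d <- makeTwoClusterData(nActive = 20, nInactive = 20, nFlip = 2,
                          mu = 3, seed = 6)
  T <- 60
  trace <- fitBoostingTrace(d$X, d$y,
                            boostingConfig(nIterations = T, maxDepth = 2,
                                           minChildSamples = 2, seed = 1))
  lambda <- 1
  s <- influenceValues(mvsaInfluence(trace, d$y, lambda = lambda))
  expect_true(all(s >= 0))
  expect_true(all(s <= T * sqrt(1 + 0.0625 * lambda)))
  # per-iteration contribution of a saturated sample tends to zero
  m <- traceMargins(trace)
  clean <- setdiff(names(s)[d$y == 1], d$flipped)
  best <- clean[which.max(m[T + 1, clean])]
  gh <- loglossGradHess(m[T + 1, best], 1)
  expect_lt(sqrt(gh$g^2 + lambda * gh$h^2), 0.05)
})

test_that("flipped actives dominate the influence ranking of the hits", {
  d <- makeTwoClusterData(nActive = 30, nInactive = 30, nFlip = 3, seed = 42)
  trace <- fitBoostingTrace(d$X, d$y,
                            boostingConfig(nIterations = 50, maxDepth = 3,
                                           minChildSamples = 5, seed = 1))
  s <- influenceValues(mvsaInfluence(trace, d$y))
  hitScores <- s[d$y == 1]
  top3 <- names(sort(hitScores, decreasing = TRUE))[1:3]
  expect_setequal(top3, d$flipped)
})

test_that("label flip recovery: flipping a low-score sample raises its score", {
  d <- makeTwoClusterData(nActive = 25, nInactive = 25, nFlip = 0, seed = 8)
  cfg <- boostingConfig(nIterations = 40, maxDepth = 2,
                        minChildSamples = 2, seed = 3)
  s1 <- influenceValues(mvsaInfluence(fitBoostingTrace(d$X, d$y, cfg), d$y))
  j <- which(d$y == 0)[which.min(s1[d$y == 0])]
  y2 <- d$y
  y2[j] <- 1
  s2 <- influenceValues(mvsaInfluence(fitBoostingTrace(d$X, y2, cfg), y2))
  expect_gt(s2[j], s1[j])
})

test_that("influence is deterministic bit-for-bit for identical inputs", {
  d <- makeNoisyData(n = 150, d = 6, seed = 10)
  cfg <- boostingConfig(nIterations = 30, maxDepth = 4,
                        minChildSamples = 5, seed = 7)
  s1 <- influenceValues(mvsaInfluence(fitBoostingTrace(d$X, d$y, cfg), d$y))
  s2 <- influenceValues(mvsaInfluence(fitBoostingTrace(d$X, d$y, cfg), d$y))
  expect_identical(s1, s2)
})

test_that("triage flags use ceiling arithmetic and handle ties", {
  mkScores <- function(v) {
    names(v) <- sprintf("h%04d", seq_along(v))
    new("InfluenceScores", scores = v, lambda = 1, aggregation = "sum",
        config = list())
  }
  # hit count from a large public-campaign scale: ceil(0.1 * 2625) = 263
  s <- mkScores(runif(3000))
  y <- c(rep(1, 2625), rep(0, 375))
  tri <- triageHits(s, y, 0.1)
  expect_length(likelyFalsePositives(tri), 263L)
  expect_length(likelyTruePositives(tri), 263L)
  # ceiling guarantees non-empty flags for tiny hit sets
  s5 <- mkScores(runif(10))
  tri5 <- triageHits(s5, c(rep(1, 5), rep(0, 5)), 0.1)
  expect_length(likelyFalsePositives(tri5), 1L)
  expect_length(likelyTruePositives(tri5), 1L)
  expect_length(intersect(likelyFalsePositives(tri5),
                          likelyTruePositives(tri5)), 0L)
  # all-equal scores: stable order, flags still assigned, warning emitted
  sEq <- mkScores(rep(1, 10))
  expect_warning(triEq <- triageHits(sEq, rep(1, 10), 0.2), "equal")
  expect_identical(triageTable(triEq)$compoundId, sprintf("h%04d", 1:10))
  expect_length(likelyFalsePositives(triEq), 2L)
  expect_error(triageHits(s5, rep(0, 10)), "no actives")
  expect_error(triageHits(s5, c(1, rep(0, 9)), fraction = 0.6), "fraction")
})

test_that("false-negative mining ranks a flipped inactive first", {
  # one truly-active compound mislabeled inactive, drawn from the active
  # cluster
  set.seed(13)
  nA <- 25; nI <- 25
  X <- rbind(matrix(rnorm(nA * 2, 2), nA, 2),
             matrix(rnorm(nI * 2, -2), nI, 2))
  y <- c(rep(1, nA), rep(0, nI))
  X[nA + 1, ] <- rnorm(2, 2)  # inactive record sitting among actives
  rownames(X) <- sprintf("s%02d", 1:50)
  trace <- fitBoostingTrace(X, y,
                            boostingConfig(nIterations = 50, maxDepth = 3,
                                           minChildSamples = 5, seed = 2))
  fn <- rankFalseNegativeCandidates(mvsaInfluence(trace, y), y)
  expect_identical(fn$compoundId[1], "s26")
  expect_identical(fn$rank, seq_len(nI))
})

test_that("false-negative ranking is permutation invariant with no flips", {
  d <- makeTwoClusterData(nActive = 20, nInactive = 30, nFlip = 0, seed = 21)
  trace <- fitBoostingTrace(d$X, d$y,
                            boostingConfig(nIterations = 30, maxDepth = 2,
                                           minChildSamples = 5, seed = 4))
  s <- mvsaInfluence(trace, d$y)
  fn <- rankFalseNegativeCandidates(s, d$y)
  # no extreme outlier among inactives when no flip was injected
  inScores <- influenceValues(s)[d$y == 0]
  expect_lt(fn$score[1], 2 * quantile(inScores, 0.999))
  # permuting the input order leaves the ranked id sequence unchanged
  # (distinct scores; ties would fall back to stable input order)
  set.seed(77)
  v <- runif(40)
  names(v) <- sprintf("q%02d", 1:40)
  yq <- rep_len(c(0, 0, 1), 40)
  mk <- function(scores) new("InfluenceScores", scores = scores,
                             lambda = 1, aggregation = "sum",
                             config = list())
  ref <- rankFalseNegativeCandidates(mk(v), yq)
  perm <- sample(40)
  permuted <- rankFalseNegativeCandidates(mk(v[perm]), yq[perm])
  expect_identical(permuted$compoundId, ref$compoundId)
})
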