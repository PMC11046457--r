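# Independent oracles kept deliberately separate from the package's own
# computation paths.

# Brute-force leave-one-out self-influence: retrain without sample i and
# measure the log-loss increase at sample i itself. High values mark
# samples the model can only fit by memorizing them (mislabeled or
# atypical) - the quantity MVS-A approximates from the training dynamics.
looSelfInfluenceOracle <- function(X, y, nIterations = 20, maxDepth = 2,
                                   eta = 0.1, seed = 0) {
  n <- nrow(X)
  fitPredict <- function(rows, newX) {
    pbar <- mean(y[rows])
    params <- list(objective = "binary:logistic", eta = eta,
                   max_depth = maxDepth, base_score = pbar,
                   nthread = 1, seed = seed, tree_method = "hist")
    bst <- xgboost::xgb.train(
      params, xgboost::xgb.DMatrix(X[rows, , drop = FALSE],
                                   label = y[rows], nthread = 1),
      nrounds = nIterations, verbose = 0)
    stats::predict(bst, xgboost::xgb.DMatrix(newX, nthread = 1))
  }
  eps <- 1e-12
  ll <- function(p, yy) -(yy * log(p + eps) + (1 - yy) * log(1 - p + eps))
  pFull <- fitPredict(seq_len(n), X)
  vapply(seq_len(n), function(i) {
    pNoI <- fitPredict(setdiff(seq_len(n), i), X[i, , drop = FALSE])
    ll(pNoI, y[i]) - ll(pFull[i], y[i])
  }, numeric(1))
}

# BEDROC by direct min-max scaling of the rank-exponential enrichment
# (RIE): RIE of the observed positive ranks, linearly rescaled between the
# worst-possible and best-possible RIE for the same N, n, alpha. Shares
# only the RIE definition with the closed form under test, not its
# hyperbolic normalization constants.
bedrocMinMaxOracle <- function(posRanks, N, alpha) {
  n <- length(posRanks)
  rie <- function(r) {
    mean(exp(-alpha * r / N)) /
      ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  }
  (rie(posRanks) - rie(seq(N - n + 1, N))) /
    (rie(seq_len(n)) - rie(seq(N - n + 1, N)))
}

# Literal recount of precision within the top k of a ranking.
precisionBruteForce <- function(ranking, positives, k) {
  hits <- 0
  for (i in seq_len(k)) if (ranking[i] %in% positives) hits <- hits + 1
  hits / k
}

# Exact one-tailed signed-rank p by enumerating all 2^n sign assignments.
signedRankExactOracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wAll <- signs %*% r
  mean(wAll >= wObs)
}
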