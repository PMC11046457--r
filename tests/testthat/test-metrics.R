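# Early-recognition metric suite against independent oracles.

test_that("precision at k counts top-k positives", {
  rk <- c("a", "b", "c", "d", "e")
  pos <- c("a", "b", "d")  # labels 1,1,0,1,0 down the ranking
  expect_equal(precisionAtK(rk, pos, 3), 2 / 3)
  expect_equal(precisionAtK(rk, pos, 5), 3 / 5)
  # all positives first -> 1.0 at k = n_pos
  expect_equal(precisionAtK(c("a", "b", "d", "c", "e"), pos, 3), 1)
  expect_error(precisionAtK(rk, pos, 0), "out of range")
  expect_error(precisionAtK(rk, pos, 6), "out of range")
})

test_that("relative precision is zero at prevalence and floors at -1", {
  expect_equal(relativePrecision(0.29, 0.29), 0)
  expect_equal(relativePrecision(1, 0.29), 1 / 0.29 - 1)
  expect_equal(relativePrecision(0, 0.4), -1)
  expect_error(relativePrecision(0.5, 0), "prevalence")
  expect_error(relativePrecision(0.5, 1), "prevalence")
})

test_that("random rankings have expected precision equal to prevalence", {
  ids <- sprintf("c%03d", 1:50)
  pos <- ids[1:15]
  prev <- 0.3
  pk <- vapply(1:10000, function(s)
    precisionAtK(rankRandom(ids, seed = s), pos, 10), numeric(1))
  se <- sd(pk) / sqrt(length(pk))
  expect_lt(abs(mean(pk) - prev), 3 * se)
})

test_that("enrichment factor matches a brute-force recount", {
  set.seed(7)
  ids <- sprintf("c%02d", 1:20)
  pos <- sample(ids, 6)
  rk <- sample(ids)
  k <- ceiling(0.25 * 20)
  expect_equal(enrichmentFactor(rk, pos, 0.25),
               precisionBruteForce(rk, pos, k) / (6 / 20))
  # a perfectly front-loaded decile reaches the prevalence ceiling
  ids100 <- sprintf("d%03d", 1:100)
  pos10 <- ids100[1:10]
  expect_equal(enrichmentFactor(ids100, pos10, 0.1), 10)
  # random expectation is 1.0
  ef <- vapply(1:2000, function(s)
    enrichmentFactor(rankRandom(ids100, seed = s), pos10, 0.1), numeric(1))
  expect_lt(abs(mean(ef) - 1), 3 * sd(ef) / sqrt(length(ef)))
})

test_that("BEDROC hits its endpoints and matches the min-max RIE oracle", {
  ids <- sprintf("x%03d", 1:100)
  pos <- ids[1:5]
  expect_equal(bedroc(ids, pos, alpha = 20), 1, tolerance = 1e-9)
  worst <- c(ids[6:100], ids[1:5])
  expect_lt(bedroc(worst, pos, alpha = 20), 1e-6)
  # dual-formula check on a small instance: N = 10, n = 2, ranks {1, 5}
  ids10 <- letters[1:10]
  pos2 <- c("a", "e")
  expect_equal(bedroc(ids10, pos2, alpha = 20),
               bedrocMinMaxOracle(c(1, 5), 10, 20), tolerance = 1e-9)
  # and across random instances and alphas
  set.seed(31)
  for (rep in 1:20) {
    N <- sample(8:60, 1)
    n <- sample(2:(N - 2), 1)
    alpha <- runif(1, 2, 60)
    r <- sort(sample.int(N, n))
    rk <- character(N)
    rk[r] <- sprintf("p%d", seq_len(n))
    rk[rk == ""] <- sprintf("n%d", seq_len(N - n))
    expect_equal(bedroc(rk, sprintf("p%d", seq_len(n)), alpha),
                 bedrocMinMaxOracle(r, N, alpha), tolerance = 1e-9)
  }
  expect_error(bedroc(ids, ids, 20), "degenerate")
  expect_error(bedroc(ids, character(0), 20), "degenerate")
  expect_error(bedroc(ids, pos, 0), "alpha")
})

test_that("BEDROC never decreases when a positive moves up one rank", {
  set.seed(17)
  ids <- sprintf("y%02d", 1:12)
  for (rep in 1:10) {
    pos <- sample(ids, sample(2:6, 1))
    rk <- sample(ids)
    for (i in 2:12) {
      if (rk[i] %in% pos && !(rk[i - 1] %in% pos)) {
        swapped <- rk
        swapped[c(i - 1, i)] <- rk[c(i, i - 1)]
        expect_gte(bedroc(swapped, pos, 20), bedroc(rk, pos, 20))
      }
    }
  }
})

test_that("metrics are invariant under compound-id relabeling", {
  set.seed(23)
  ids <- sprintf("z%02d", 1:30)
  pos <- sample(ids, 9)
  rk <- sample(ids)
  relabel <- setNames(sprintf("w%02d", 1:30), ids)
  expect_equal(enrichmentFactor(rk, pos, 0.2),
               enrichmentFactor(unname(relabel[rk]), unname(relabel[pos]),
                                0.2))
  expect_equal(bedroc(rk, pos, 20),
               bedroc(unname(relabel[rk]), unname(relabel[pos]), 20))
})

test_that("scaffold diversity counts unique Murcko frameworks", {
  tol <- c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1", "CCCCc1ccccc1")
  expect_equal(scaffoldDiversity(tol), 0.25)
  distinct <- fixtureSmiles(6, seed = 2, scaffoldClasses = 6)
  expect_equal(scaffoldDiversity(distinct), 1)
  mixed <- fixtureSmiles(10, seed = 6, scaffoldClasses = 6)
  expect_equal(scaffoldDiversity(mixed), 0.6)
  expect_error(scaffoldDiversity(character(0)), "empty")
})

test_that("signed-rank p is exact for small n and Bonferroni caps at 1", {
  # 17 all-positive paired differences: one-tailed p = 2^-17
  a <- 1:17 + 0.5
  b <- rep(0.25, 17)
  expect_equal(pairedSignedRank(a, b), 2^-17, tolerance = 1e-15)
  expect_error(pairedSignedRank(a, a), "all paired differences are zero")
  expect_error(pairedSignedRank(1:3, 3:1), "at least 5")
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(c(0.5, 0.9), m = 3), c(1, 1))
})

test_that("signed-rank agrees with exhaustive sign enumeration", {
  set.seed(9)
  for (rep in 1:5) {
    d <- round(rnorm(8, 0.3), 3)
    d <- d[d != 0]
    if (any(duplicated(abs(d)))) next
    expect_equal(pairedSignedRank(d, rep(0, length(d))),
                 signedRankExactOracle(d), tolerance = 1e-12)
  }
})

test_that("evaluation reports the metric suite with the EF identity", {
  sim <- simulateScreen(syntheticSpec(nCompounds = 6000, hitRate = 0.02,
                                      fpFraction = 0.4, fnCount = 0),
                        seed = 11)
  ss <- sim$screen
  hitIds <- compoundIds(ss)[isHit(ss)]
  rks <- list(readout = rankByPrimaryReadout(ss),
              random = rankRandom(hitIds, seed = 1))
  for (task in c("fp_detection", "tp_detection")) {
    ev <- evaluateRankings(ss, rks, task = task)
    expect_identical(nrow(ev), 8L)
    wide <- split(ev$value, ev$metric)
    expect_equal(wide$enrichment_factor, wide$relative_precision + 1,
                 tolerance = 1e-12)
    expect_true(all(wide$bedroc >= 0 & wide$bedroc <= 1))
  }
  # the oracle ranking attains the relative-precision ceiling
  fpIds <- compoundIds(ss)[isFalsePositive(ss)]
  oracleRk <- c(fpIds, setdiff(hitIds, fpIds))
  evo <- evaluateRankings(ss, list(oracle = oracleRk),
                          task = "fp_detection")
  prev <- length(fpIds) / length(hitIds)
  rp <- evo$value[evo$metric == "relative_precision"]
  expect_equal(rp, 1 / prev - 1, tolerance = 1e-12)
})
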