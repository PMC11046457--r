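# Fixtures built in code: two-cluster classification toys with injected
# label noise, and small paired primary/confirmatory screens.

# Two Gaussian clusters in `d` dimensions; actives at +mu, inactives at -mu.
# The first `nFlip` "actives" are drawn from the inactive cluster, i.e. they
# carry a flipped label the model should flag as high influence.
makeTwoClusterData <- function(nActive = 30, nInactive = 30, nFlip = 3,
                               d = 2, mu = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(nActive * d, mu), nActive, d),
             matrix(rnorm(nInactive * d, -mu), nInactive, d))
  if (nFlip > 0)
    X[seq_len(nFlip), ] <- matrix(rnorm(nFlip * d, -mu), nFlip, d)
  rownames(X) <- sprintf("s%02d", seq_len(nrow(X)))
  list(X = X, y = c(rep(1, nActive), rep(0, nInactive)),
       flipped = rownames(X)[seq_len(nFlip)])
}

# Mildly noisy linearly-separable-ish data for LOO oracle comparisons:
# labels follow the first feature's sign with a fraction flipped at random.
makeNoisyData <- function(n = 60, d = 2, flipFrac = 0.15, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- as.numeric(X[, 1] > 0)
  nf <- max(1L, round(flipFrac * n))
  fl <- sample.int(n, nf)
  y[fl] <- 1 - y[fl]
  rownames(X) <- sprintf("s%02d", seq_len(n))
  list(X = X, y = y, flipped = rownames(X)[fl])
}

# A tiny structured screen with known confirmatory outcomes.
makeToyScreen <- function() {
  smi <- fixtureSmiles(12, seed = 3, scaffoldClasses = 6)
  readout <- c(5, 4.5, 4, 3.5, 3, 2.5, 1, 0.8, 0.5, 0.3, 0.2, 0.1)
  hit <- readout >= 2.5
  outcome <- rep("untested", 12)
  outcome[hit] <- c("active", "inactive", "active", "inconclusive",
                    "active", "inactive")
  ScreenSet(compoundId = sprintf("T%02d", 1:12), smiles = smi,
            readout = readout, primaryActive = hit,
            confirmatoryOutcome = outcome, name = "toy")
}

# Write a screen + features pair to a temp dir in the CLI dialect.
writeSimToDir <- function(spec, seed, dir = tempfile("sim")) {
  sim <- cmdSimulate(spec, outDir = dir, seed = seed)
  sim
}
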