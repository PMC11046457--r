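# Reference ranking strategies for head-to-head evaluation. Every baseline
# emits a total order over exactly the hit ids it was given and never sees
# confirmatory outcomes (the interfaces only accept readouts, features or
# ids, so label leakage is structurally impossible).

#' Rank hits by primary readout
#'
#' The de facto triage heuristic: hits sorted most-active-first by the
#' primary readout (orientation is normalized at load, larger = more
#' active). Used directly as a true-positive prioritization baseline; its
#' reverse serves as a false-positive baseline. Ties keep stable input
#' order.
#'
#' @param sset a \linkS4class{ScreenSet}.
#' @param decreasing most-active-first (default) or reversed.
#' @return character vector of hit ids, best first.
#' @export
rankByPrimaryReadout <- function(sset, decreasing = TRUE) {
  hit <- isHit(sset)
  r <- readouts(sset)[hit]
  if (any(is.na(r))) stop("missing readout", call. = FALSE)
  ids <- compoundIds(sset)[hit]
  ord <- if (decreasing) .stableOrderDesc(r) else .stableOrderDesc(-r)
  ids[ord]
}

#' Random hit ranking
#'
#' Uniform random permutation, reproducible per seed; the expectation
#' baseline against which relative precision equals zero.
#'
#' @param hitIds character vector of hit ids.
#' @param seed RNG seed.
#' @return a permutation of \code{hitIds}.
#' @export
rankRandom <- function(hitIds, seed = 0L) {
  if (length(hitIds) <= 1L) return(hitIds)
  .withSeed(seed, hitIds[sample.int(length(hitIds))])
}

#' Isolation-forest anomaly scorer
#'
#' Builds an isolation forest on call: an ensemble of trees that split on
#' a random feature at a random threshold; samples isolated after short
#' paths are anomalous. Scores follow the standard
#' \eqn{2^{-E[h(x)]/c(\psi)}} normalization with subsample size
#' \eqn{\psi}. Conventional defaults: 100 trees, subsample 256.
#'
#' @param nTrees ensemble size.
#' @param sampleSize subsample per tree (capped at n).
#' @param seed RNG seed.
#' @return a scorer \code{function(X) -> numeric} usable with
#'   \code{\link{rankByAnomaly}}; higher = more anomalous.
#' @export
isolationForestScorer <- function(nTrees = 100L, sampleSize = 256L,
                                  seed = 0L) {
  force(nTrees); force(sampleSize); force(seed)
  function(X) {
    X <- as.matrix(X)
    n <- nrow(X)
    psi <- min(sampleSize, n)
    hlim <- ceiling(log2(max(psi, 2)))
    .withSeed(seed, {
      paths <- matrix(0, n, nTrees)
      for (b in seq_len(nTrees)) {
        idx <- sample.int(n, psi)
        tree <- .growITree(X[idx, , drop = FALSE], 0L, hlim)
        paths[, b] <- .iTreePath(tree, X)
      }
      avg <- rowMeans(paths)
      2^(-avg / .avgPathLength(psi))
    })
  }
}

# Average unsuccessful-search path length in a BST of n nodes.
.avgPathLength <- function(n) {
  if (n <= 1) return(1)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

.growITree <- function(X, depth, hlim) {
  n <- nrow(X)
  if (n <= 1L || depth >= hlim)
    return(list(leaf = TRUE, size = n))
  spread <- apply(X, 2, function(v) diff(range(v)))
  usable <- which(spread > 0)
  if (length(usable) == 0L) return(list(leaf = TRUE, size = n))
  q <- usable[sample.int(length(usable), 1L)]
  lo <- min(X[, q]); hi <- max(X[, q])
  p <- stats::runif(1, lo, hi)
  left <- X[, q] < p
  list(leaf = FALSE, q = q, p = p,
       l = .growITree(X[left, , drop = FALSE], depth + 1L, hlim),
       r = .growITree(X[!left, , drop = FALSE], depth + 1L, hlim))
}

.iTreePath <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  rec <- function(node, rows, depth) {
    if (length(rows) == 0L) return()
    if (node$leaf) {
      out[rows] <<- depth + if (node$size > 1) .avgPathLength(node$size) else 0
      return()
    }
    left <- X[rows, node$q] < node$p
    rec(node$l, rows[left], depth + 1)
    rec(node$r, rows[!left], depth + 1)
  }
  rec(tree, seq_len(n), 0)
  out
}

#' Rank hits by anomaly score
#'
#' Sorts hits most-anomalous-first under a pluggable scorer (adapter
#' contract: any \code{function(features) -> numeric}, higher = more
#' anomalous). The shipped default is \code{\link{isolationForestScorer}}.
#' Used as a false-positive detection baseline. Constant features yield
#' all-equal scores, stable order and a warning.
#'
#' @param X features of the hits: \linkS4class{FeatureMatrix} or matrix,
#'   rows aligned to \code{hitIds}.
#' @param hitIds character ids aligned to the rows of \code{X} (default:
#'   feature row ids).
#' @param scorer anomaly scorer function.
#' @return character vector of hit ids, most anomalous first.
#' @export
rankByAnomaly <- function(X, hitIds = NULL,
                          scorer = isolationForestScorer()) {
  fi <- .featureInput(X)
  if (is.null(hitIds)) hitIds <- fi$ids
  if (length(hitIds) != nrow(fi$values))
    stop("hitIds misaligned with features", call. = FALSE)
  sc <- tryCatch(scorer(fi$values),
                 error = function(e) stop("anomaly scorer failed: ",
                                          conditionMessage(e), call. = FALSE))
  if (length(sc) != length(hitIds))
    stop("anomaly scorer returned wrong length", call. = FALSE)
  if (length(sc) > 1L && diff(range(sc)) == 0)
    warning("all anomaly scores equal; ranking falls back to stable input order")
  hitIds[.stableOrderDesc(sc)]
}

#' Read precomputed external ranking scores
#'
#' Adapter for external predictors (frequent-hitter, aggregation,
#' autofluorescence, object-importance, ...): a CSV with columns
#' \code{compound_id}, \code{score} and a \code{higher_is_more_suspect}
#' flag column (1/0). Returns a ranking over the requested ids,
#' most-suspect-first.
#'
#' @param path CSV path.
#' @param hitIds ids to rank; ids absent from the file are placed last in
#'   stable input order with a warning.
#' @return character vector of \code{hitIds}, most suspect first.
#' @export
rankByExternalScores <- function(path, hitIds) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("compound_id", "score", "higher_is_more_suspect")
  if (!all(need %in% colnames(tab)))
    stop("external score table needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  sgn <- if (all(tab$higher_is_more_suspect %in% c(1, TRUE))) 1 else -1
  idx <- match(hitIds, as.character(tab$compound_id))
  if (any(is.na(idx)))
    warning(sum(is.na(idx)), " id(s) missing from external scores; placed last")
  sc <- sgn * tab$score[idx]
  sc[is.na(sc)] <- -Inf
  hitIds[.stableOrderDesc(sc)]
}
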