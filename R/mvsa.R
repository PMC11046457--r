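# MVS-A core: fit a gradient-boosting classifier on the primary screen,
# record the raw margin F_t(x_i) of every sample after every iteration, and
# accumulate per-sample influence from the binary log-loss gradients and
# hessians along the trace. A sample that persistently contradicts the
# boundary the ensemble is learning keeps large gradients throughout
# training and ends with a high score; well-fit samples saturate (|g| -> 0,
# h -> 0) and score near zero.

#' Boosting configuration
#'
#' Fixed out-of-the-box defaults (no per-dataset tuning): 100 iterations,
#' learning rate 0.1, depth-6 trees, a 20-sample minimum per leaf and no
#' class weighting.
#'
#' @param nIterations number of boosting iterations T (>= 1).
#' @param learningRate shrinkage in (0, 1].
#' @param maxDepth maximum tree depth.
#' @param minChildSamples minimum samples per leaf; mapped onto the
#'   trainer's hessian-mass constraint at the label base rate
#'   (\code{minChildSamples * p(1-p)}), an approximation documented in the
#'   methods vignette.
#' @param seed RNG seed recorded in all outputs.
#' @param classWeighting \code{"none"} or \code{"balanced"}
#'   (positive-class reweighting by the class ratio).
#' @return a validated configuration list.
#' @export
boostingConfig <- function(nIterations = 100L, learningRate = 0.1,
                           maxDepth = 6L, minChildSamples = 20L,
                           seed = 0L,
                           classWeighting = c("none", "balanced")) {
  classWeighting <- match.arg(classWeighting)
  if (nIterations < 1L) stop("nIterations must be >= 1", call. = FALSE)
  if (learningRate <= 0 || learningRate > 1)
    stop("learningRate must be in (0, 1]", call. = FALSE)
  list(nIterations = as.integer(nIterations),
       learningRate = learningRate,
       maxDepth = as.integer(maxDepth),
       minChildSamples = as.integer(minChildSamples),
       seed = as.integer(seed),
       classWeighting = classWeighting)
}

.featureInput <- function(X) {
  if (methods::is(X, "FeatureMatrix"))
    list(values = featureValues(X), ids = featureRowIds(X))
  else
    list(values = X,
         ids = if (!is.null(rownames(X))) rownames(X)
               else as.character(seq_len(nrow(X))))
}

#' Fit a boosting classifier and record its margin trace
#'
#' Trains a binary gradient-boosting classifier (hits vs inactives) and
#' returns the raw additive score \eqn{F_t(x_i)} of every training sample
#' after every iteration, starting from the base score
#' \eqn{F_0 = \log(\bar p/(1-\bar p))} at the label prevalence. Training
#' is deterministic given the seed (single thread, histogram trees).
#' Margins are reconstructed from the per-tree leaf assignments, which is
#' exact up to the trainer's float32 output resolution.
#'
#' @param X a \linkS4class{FeatureMatrix}, base matrix or sparse
#'   \code{dgCMatrix} (rows = samples).
#' @param y binary labels (0/1 or logical), both classes present.
#' @param config see \code{\link{boostingConfig}}.
#' @return A \linkS4class{BoostingTrace}.
#' @export
fitBoostingTrace <- function(X, y, config = boostingConfig()) {
  fi <- .featureInput(X)
  Xv <- fi$values
  if (methods::is(Xv, "Matrix") && !methods::is(Xv, "dgCMatrix"))
    Xv <- methods::as(methods::as(Xv, "dMatrix"), "CsparseMatrix")
  y <- as.numeric(y)
  n <- nrow(Xv)
  if (length(y) != n) stop("X and y are misaligned", call. = FALSE)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("degenerate labels: both classes must be present", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  if (is.matrix(Xv) && any(!is.finite(Xv)))
    stop("non-finite feature values", call. = FALSE)
  if (n < config$minChildSamples)
    stop(sprintf("n = %d below minChildSamples = %d", n,
                 config$minChildSamples), call. = FALSE)
  pbar <- mean(y)
  params <- list(
    objective = "binary:logistic",
    eta = config$learningRate,
    max_depth = config$maxDepth,
    min_child_weight = config$minChildSamples * pbar * (1 - pbar),
    base_score = pbar,
    nthread = 1,
    seed = config$seed,
    tree_method = "hist")
  if (config$classWeighting == "balanced")
    params$scale_pos_weight <- sum(y == 0) / sum(y == 1)
  dtrain <- xgboost::xgb.DMatrix(Xv, label = y, nthread = 1)
  bst <- xgboost::xgb.train(params, dtrain, nrounds = config$nIterations,
                            verbose = 0)
  T <- config$nIterations
  leaves <- stats::predict(bst, dtrain, predleaf = TRUE)
  tree <- xgboost::xgb.model.dt.tree(model = bst)
  leafRows <- tree$Feature == "Leaf"
  lut <- matrix(NA_real_, max(tree$Node) + 1L, T)
  lut[cbind(tree$Node[leafRows] + 1L, tree$Tree[leafRows] + 1L)] <-
    tree$Gain[leafRows]
  contrib <- matrix(lut[cbind(as.vector(leaves) + 1L,
                              rep(seq_len(T), each = n))], n, T)
  F0 <- stats::qlogis(pbar)
  margins <- matrix(0, T + 1L, n)
  margins[1L, ] <- F0
  for (t in seq_len(T)) margins[t + 1L, ] <- margins[t, ] + contrib[, t]
  colnames(margins) <- fi$ids
  methods::new("BoostingTrace", margins = margins, config = config)
}

#' Binary log-loss gradient and hessian at a raw margin
#'
#' For margin \eqn{F} and label \eqn{y \in \{0,1\}}:
#' \eqn{p = 1/(1+e^{-F})}, gradient \eqn{g = p - y}, hessian
#' \eqn{h = p(1-p)}. Hence \eqn{g \in (-1, 1)} and
#' \eqn{h \in (0, 0.25]}. Vectorized over both arguments.
#'
#' @param margin numeric raw margin(s) F.
#' @param y numeric label(s) in \{0,1\}.
#' @return list with components \code{g} and \code{h}.
#' @export
#' @examples
#' loglossGradHess(0, 1)   # g = -0.5, h = 0.25
loglossGradHess <- function(margin, y) {
  if (any(!is.finite(margin))) stop("margin must be finite", call. = FALSE)
  p <- stats::plogis(margin)
  list(g = p - y, h = p * (1 - p))
}

#' MVS-A sample-influence scores from a boosting trace
#'
#' Accumulates, for every training sample, the minimal-variance-sampling
#' magnitude \eqn{\sqrt{g_{i,t}^2 + \lambda h_{i,t}^2}} of its log-loss
#' gradient \eqn{g} and hessian \eqn{h} at the margin entering each
#' boosting iteration \eqn{t = 0, \dots, T-1}, in-sample on the training
#' data itself:
#' \deqn{s_i = \sum_{t=0}^{T-1} \sqrt{g_{i,t}^2 + \lambda h_{i,t}^2}.}
#' With \code{aggregation = "mean"} the sum is divided by \eqn{T}
#' (rank-equivalent at fixed \eqn{T}, comparable across different
#' \eqn{T}). With \eqn{\lambda = 0} the score reduces exactly to
#' \eqn{\sum_t |g_{i,t}|}. Higher scores mark samples that persistently
#' contradict the learned boundary - among primary hits these are likely
#' assay false positives.
#'
#' @param trace a \linkS4class{BoostingTrace}.
#' @param y binary training labels aligned to the trace columns.
#' @param lambda nonnegative hessian regularizer (default 1).
#' @param aggregation \code{"sum"} (default) or \code{"mean"}.
#' @return An \linkS4class{InfluenceScores}.
#' @export
mvsaInfluence <- function(trace, y, lambda = 1,
                          aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop("lambda must be a single nonnegative number", call. = FALSE)
  m <- traceMargins(trace)
  T <- nrow(m) - 1L
  n <- ncol(m)
  y <- as.numeric(y)
  if (length(y) != n) stop("trace and y are misaligned", call. = FALSE)
  s <- numeric(n)
  for (t in seq_len(T)) {
    gh <- loglossGradHess(m[t, ], y)
    s <- s + sqrt(gh$g^2 + lambda * gh$h^2)
  }
  if (aggregation == "mean") s <- s / T
  names(s) <- colnames(m)
  methods::new("InfluenceScores", scores = s, lambda = lambda,
               aggregation = aggregation, config = traceConfig(trace))
}

#' Triage primary hits by influence score
#'
#' Sorts the hits by MVS-A score, descending (ties broken by stable input
#' order), flags the top \code{ceiling(fraction * nHits)} as likely false
#' positives and the bottom \code{ceiling(fraction * nHits)} as likely
#' true positives, and retains the full ranking for budget-flexible use.
#'
#' @param scores an \linkS4class{InfluenceScores} over all training
#'   samples.
#' @param y binary labels aligned to the scores; 1 marks hits.
#' @param fraction flagging fraction in (0, 0.5] (default 0.1, i.e.
#'   top/bottom 10 percent of the hits).
#' @return A \linkS4class{TriageResult}.
#' @export
triageHits <- function(scores, y, fraction = 0.1) {
  if (fraction <= 0 || fraction > 0.5)
    stop("fraction must be in (0, 0.5]", call. = FALSE)
  s <- influenceValues(scores)
  y <- as.numeric(y)
  if (length(y) != length(s))
    stop("scores and y are misaligned", call. = FALSE)
  hitIdx <- which(y == 1)
  if (length(hitIdx) == 0L)
    stop("no actives to triage", call. = FALSE)
  sh <- s[hitIdx]
  if (length(sh) > 1L && diff(range(sh)) == 0)
    warning("all hit scores equal; ranking falls back to stable input order")
  ord <- .stableOrderDesc(sh)
  ranked <- hitIdx[ord]
  nh <- length(ranked)
  k <- ceiling(fraction * nh)
  ids <- names(s)[ranked]
  flag <- rep("unflagged", nh)
  fpSel <- seq_len(k)
  tpSel <- setdiff(seq(nh - k + 1L, nh), fpSel)
  flag[fpSel] <- "likely_FP"
  flag[tpSel] <- "likely_TP"
  tb <- DataFrame(compoundId = ids, score = unname(s[ranked]),
                  rank = seq_len(nh), flag = flag)
  methods::new("TriageResult", table = tb,
               likelyFP = ids[fpSel], likelyTP = ids[tpSel],
               fraction = fraction)
}

#' Rank primary inactives as false-negative candidates
#'
#' Sorts the primary-inactive compounds by MVS-A score, descending: an
#' inactive the classifier persistently wants to call active is a likely
#' mislabeled true active ("dark chemical matter" candidate). Rank 1 is
#' the most likely false negative. Ties keep stable input order, so the
#' ranked id sequence is invariant to input permutation.
#'
#' @param scores an \linkS4class{InfluenceScores} over all training
#'   samples.
#' @param y binary labels aligned to the scores; 0 marks inactives.
#' @return A \link[S4Vectors]{DataFrame} with \code{compoundId},
#'   \code{score}, \code{rank}.
#' @export
rankFalseNegativeCandidates <- function(scores, y) {
  s <- influenceValues(scores)
  y <- as.numeric(y)
  if (length(y) != length(s))
    stop("scores and y are misaligned", call. = FALSE)
  inIdx <- which(y == 0)
  if (length(inIdx) == 0L)
    return(DataFrame(compoundId = character(0), score = numeric(0),
                     rank = integer(0)))
  ranked <- inIdx[.stableOrderDesc(s[inIdx])]
  DataFrame(compoundId = names(s)[ranked], score = unname(s[ranked]),
            rank = seq_along(ranked))
}
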