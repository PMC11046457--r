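# Early-recognition metric suite for scoring hit rankings against
# confirmatory ground truth, plus the paired significance machinery used
# to compare methods across datasets.

#' Precision among the top k of a ranking
#'
#' @param ranking character vector of ids, best first.
#' @param positives character vector of ground-truth positive ids.
#' @param k cutoff, 1 <= k <= length(ranking).
#' @return \eqn{|top_k \cap positives| / k}.
#' @export
precisionAtK <- function(ranking, positives, k) {
  n <- length(ranking)
  if (k < 1 || k > n) stop("k out of range [1, ", n, "]", call. = FALSE)
  sum(ranking[seq_len(k)] %in% positives) / k
}

#' Precision relative to prevalence
#'
#' Scales a precision by the positive prevalence of the evaluated set:
#' \eqn{precision/prevalence - 1}. Zero means the ranking is equal to
#' random sorting; positive values are the fractional improvement over
#' assay noise (percent improvement when multiplied by 100).
#'
#' @param precision a precision in [0, 1].
#' @param prevalence positive prevalence in (0, 1).
#' @export
relativePrecision <- function(precision, prevalence) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("undefined metric: prevalence must be in (0, 1)", call. = FALSE)
  precision / prevalence - 1
}

#' Enrichment factor in the top fraction
#'
#' Precision within the top \code{ceiling(fraction * n)} of the ranking
#' divided by overall prevalence; 1.0 is the random expectation and
#' 1/prevalence the ceiling.
#'
#' @param ranking character vector of ids, best first.
#' @param positives ground-truth positive ids.
#' @param topFraction fraction in (0, 1].
#' @export
enrichmentFactor <- function(ranking, positives, topFraction = 0.1) {
  if (topFraction <= 0 || topFraction > 1)
    stop("topFraction must be in (0, 1]", call. = FALSE)
  n <- length(ranking)
  k <- ceiling(topFraction * n)
  prev <- sum(ranking %in% positives) / n
  if (prev <= 0 || prev >= 1)
    stop("undefined metric: prevalence must be in (0, 1)", call. = FALSE)
  precisionAtK(ranking, positives, k) / prev
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' Early-recognition metric in [0, 1] with exponential weight
#' \eqn{e^{-\alpha r/N}} on the rank \eqn{r} of each positive
#' (Truchon-Bailey closed form). With \eqn{N} items and \eqn{n}
#' positives at 1-based ranks \eqn{r_i}:
#' \deqn{RIE = \frac{(1/n)\sum_i e^{-\alpha r_i/N}}
#'   {(1/N)(1-e^{-\alpha})/(e^{\alpha/N}-1)}}
#' \deqn{BEDROC = RIE \cdot \frac{(n/N)\sinh(\alpha/2)}
#'   {\cosh(\alpha/2)-\cosh(\alpha/2-\alpha n/N)}
#'   + \frac{1}{1-e^{\alpha(1-n/N)}}.}
#'
#' @param ranking character vector of ids, best first.
#' @param positives ground-truth positive ids; at least one positive and
#'   one negative must be present in the ranking.
#' @param alpha early-recognition weight (> 0); default 20, putting
#'   about 80 percent of the weight on the first 8 percent of the list.
#' @export
bedroc <- function(ranking, positives, alpha = 20) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  N <- length(ranking)
  isPos <- ranking %in% positives
  n <- sum(isPos)
  if (n == 0L || n == N)
    stop("degenerate label set: need a positive and a negative",
         call. = FALSE)
  r <- which(isPos)
  Ra <- n / N
  rie <- mean(exp(-alpha * r / N)) /
    ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

#' Scaffold diversity of a compound selection
#'
#' Fraction of unique Bemis-Murcko scaffolds among the selected
#' structures. Acyclic molecules share the single empty-scaffold class.
#'
#' @param selectedSmiles non-empty character vector of structures.
#' @return value in (0, 1].
#' @export
scaffoldDiversity <- function(selectedSmiles) {
  if (length(selectedSmiles) == 0L)
    stop("empty selection", call. = FALSE)
  sc <- murckoScaffold(selectedSmiles)
  length(unique(sc)) / length(sc)
}

#' One-tailed paired Wilcoxon signed-rank test
#'
#' Tests whether paired scores of method A exceed those of comparator B
#' (alternative "greater" on the differences). Zero differences are
#' dropped, as in the classic signed-rank construction. The p-value uses
#' the exact null distribution for up to 25 non-zero untied differences
#' and the normal approximation with continuity correction above (or with
#' ties).
#'
#' @param scoresA,scoresB paired numeric vectors, equal length >= 5.
#' @param alternative "greater" (default): A beats B.
#' @return the one-tailed p-value.
#' @export
pairedSignedRank <- function(scoresA, scoresB, alternative = "greater") {
  if (length(scoresA) != length(scoresB))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(scoresA) < 5L)
    stop("need at least 5 pairs", call. = FALSE)
  d <- scoresA - scoresB
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("undefined test: all paired differences are zero", call. = FALSE)
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = alternative,
                       exact = exact, correct = TRUE)$p.value)
}

#' Bonferroni correction
#'
#' Multiplies p-values by the number of comparisons and caps at 1.
#'
#' @param pValues numeric p-values.
#' @param m number of comparisons (default: length of \code{pValues}).
#' @export
bonferroni <- function(pValues, m = length(pValues)) {
  pmin(1, pValues * m)
}

#' Evaluate hit rankings against confirmatory ground truth
#'
#' Scores each ranking on the confirmed hits only (untested hits are
#' excluded): for the false-positive detection task the positives are the
#' ground-truth false positives, for true-positive detection the
#' confirmed actives. Reports relative precision and enrichment factor at
#' the top \code{topFraction}, BEDROC at \code{alpha}, and - when
#' structures are available - the scaffold diversity of the top
#' selection. The identity \eqn{EF = relative\ precision + 1} at matching
#' K is asserted on every run.
#'
#' @param sset a \linkS4class{ScreenSet} with confirmatory outcomes.
#' @param rankings named list of character id vectors (best first), each
#'   a ranking of (at least) the confirmed hits; ids outside the
#'   confirmed-hit set are dropped from the evaluated order.
#' @param task \code{"fp_detection"}, \code{"tp_detection"} or both.
#' @param topFraction K as a fraction of the evaluated hits
#'   (default 0.1, the triage fraction).
#' @param alpha BEDROC early-recognition parameter (default 20).
#' @return tidy data.frame: method, task, metric, value.
#' @export
evaluateRankings <- function(sset, rankings,
                             task = c("fp_detection", "tp_detection"),
                             topFraction = 0.1, alpha = 20) {
  task <- match.arg(task, several.ok = TRUE)
  confirmed <- isHit(sset) & confirmatoryOutcomes(sset) != "untested"
  if (!any(confirmed)) stop("no confirmed hits to evaluate", call. = FALSE)
  evalIds <- compoundIds(sset)[confirmed]
  fpIds <- compoundIds(sset)[isFalsePositive(sset)]
  tpIds <- compoundIds(sset)[isTruePositive(sset)]
  smiles <- compoundSmiles(sset)
  names(smiles) <- compoundIds(sset)
  rows <- list()
  for (method in names(rankings)) {
    rk <- rankings[[method]]
    rk <- rk[rk %in% evalIds]
    if (!setequal(rk, evalIds))
      stop(sprintf("ranking '%s' does not cover the confirmed hits", method),
           call. = FALSE)
    n <- length(rk)
    k <- ceiling(topFraction * n)
    for (tk in task) {
      pos <- if (tk == "fp_detection") fpIds else tpIds
      prev <- sum(rk %in% pos) / n
      pk <- precisionAtK(rk, pos, k)
      rp <- relativePrecision(pk, prev)
      ef <- enrichmentFactor(rk, pos, topFraction)
      stopifnot(isTRUE(all.equal(ef, rp + 1)))
      bd <- bedroc(rk, pos, alpha)
      sd_ <- NA_real_
      topSmi <- smiles[rk[seq_len(k)]]
      if (!anyNA(topSmi)) sd_ <- scaffoldDiversity(topSmi)
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, task = tk,
        metric = c("relative_precision", "enrichment_factor", "bedroc",
                   "scaffold_diversity"),
        value = c(rp, ef, bd, sd_), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
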