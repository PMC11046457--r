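#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.OUTCOME_LEVELS <- c("active", "inactive", "inconclusive", "untested")

#' ScreenSet: an aligned table of screening compound records
#'
#' Container for one high-throughput screening campaign: one record per
#' compound with an identifier, an optional structure (SMILES), the
#' assay-normalized primary readout (oriented so that larger = more active),
#' the binary primary activity call, and - for primary hits with follow-up
#' data - the confirmatory-screen outcome (\code{"active"},
#' \code{"inactive"}, \code{"inconclusive"}; \code{"untested"} otherwise).
#' Structure-free campaigns (e.g. simulated screens) carry \code{NA} SMILES;
#' structure-dependent operations refuse such records explicitly.
#'
#' The confirmatory outcome defines ground truth for evaluation: a hit that
#' is inactive or inconclusive on confirmation is a false positive, a hit
#' that confirms is a true positive, and untested hits are excluded from
#' metrics.
#'
#' @slot records a \link[S4Vectors]{DataFrame} with columns
#'   \code{compoundId}, \code{smiles}, \code{readout}, \code{primaryActive},
#'   \code{confirmatoryOutcome}.
#' @slot metadata named list: campaign \code{name}, declared
#'   \code{readoutOrientation}, threshold provenance, load/standardization
#'   reports.
#' @aliases ScreenSet
#' @export
setClass("ScreenSet",
  slots = c(records = "DataFrame", metadata = "list"))

setValidity("ScreenSet", function(object) {
  rec <- object@records
  need <- c("compoundId", "smiles", "readout", "primaryActive",
            "confirmatoryOutcome")
  if (!all(need %in% colnames(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$compoundId))
    return("compoundId values must be unique within a dataset")
  if (!all(rec$confirmatoryOutcome %in% .OUTCOME_LEVELS))
    return("confirmatoryOutcome outside {active,inactive,inconclusive,untested}")
  bad <- !rec$primaryActive & rec$confirmatoryOutcome != "untested"
  if (any(bad))
    return("confirmatory outcomes are only defined for primary hits")
  if (any(!is.finite(rec$readout)))
    return("readout must be finite")
  TRUE
})

#' Construct a ScreenSet
#'
#' @param compoundId character vector of unique compound identifiers.
#' @param smiles character vector of structures (\code{NA} for
#'   structure-free records).
#' @param readout numeric primary readout, oriented larger = more active.
#' @param primaryActive logical primary activity call.
#' @param confirmatoryOutcome character, one of \code{"active"},
#'   \code{"inactive"}, \code{"inconclusive"}, \code{"untested"}; defaults
#'   to \code{"untested"} everywhere.
#' @param name campaign name stored in metadata.
#' @param readoutOrientation orientation of \code{readout} as supplied;
#'   \code{"lower_more_active"} inputs are sign-flipped on construction so
#'   the stored readout always satisfies larger = more active.
#' @param metadata further metadata entries (list).
#' @return A \linkS4class{ScreenSet}.
#' @export
#' @examples
#' ScreenSet(compoundId = c("a", "b"), smiles = c("CCO", "c1ccccc1"),
#'           readout = c(1.2, -0.3), primaryActive = c(TRUE, FALSE))
ScreenSet <- function(compoundId, smiles = NA_character_, readout,
                      primaryActive,
                      confirmatoryOutcome = "untested",
                      name = "screen",
                      readoutOrientation = c("higher_more_active",
                                             "lower_more_active"),
                      metadata = list()) {
  readoutOrientation <- match.arg(readoutOrientation)
  n <- length(compoundId)
  smiles <- rep_len(as.character(smiles), n)
  confirmatoryOutcome <- rep_len(as.character(confirmatoryOutcome), n)
  readout <- as.numeric(readout)
  if (readoutOrientation == "lower_more_active") readout <- -readout
  rec <- DataFrame(compoundId = as.character(compoundId),
                   smiles = smiles,
                   readout = readout,
                   primaryActive = as.logical(primaryActive),
                   confirmatoryOutcome = confirmatoryOutcome)
  md <- c(list(name = name,
               readoutOrientation = "higher_more_active",
               inputOrientation = readoutOrientation),
          metadata)
  new("ScreenSet", records = rec, metadata = md)
}

#' FeatureMatrix: numeric features row-aligned to a ScreenSet
#'
#' @slot values numeric matrix (dense or \code{dgCMatrix}), one row per
#'   compound in dataset order.
#' @slot rowIds compound identifiers aligned to the rows.
#' @slot featureKind one of \code{"circular_fp"}, \code{"physchem"},
#'   \code{"custom"}.
#' @slot params generation parameters (radius / bit count / descriptor set).
#' @export
setClass("FeatureMatrix",
  slots = c(values = "ANY", rowIds = "character",
            featureKind = "character", params = "list"))

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  if (!(is.matrix(v) || methods::is(v, "Matrix")))
    return("values must be a matrix or Matrix")
  if (nrow(v) != length(object@rowIds))
    return("rowIds length must equal nrow(values)")
  if (!object@featureKind %in% c("circular_fp", "physchem", "custom"))
    return("featureKind outside {circular_fp, physchem, custom}")
  if (is.matrix(v) && any(!is.finite(v)))
    return("values must be finite (descriptor failures are imputed upstream)")
  if (object@featureKind == "circular_fp") {
    rng <- range(if (is.matrix(v)) v else v@x, 0)
    if (rng[1] < 0 || rng[2] > 1)
      return("circular_fp entries must lie in {0,1}")
  }
  TRUE
})

FeatureMatrix <- function(values, rowIds, featureKind, params = list()) {
  new("FeatureMatrix", values = values, rowIds = as.character(rowIds),
      featureKind = featureKind, params = params)
}

#' BoostingTrace: per-iteration raw margins of a fitted boosting model
#'
#' Row \code{t + 1} holds the additive raw score (pre-sigmoid margin)
#' \eqn{F_t(x_i)} of every training sample after boosting iteration
#' \eqn{t}; the first row is the constant base score
#' \eqn{F_0 = \log(\bar p / (1 - \bar p))} at the label prevalence
#' \eqn{\bar p}.
#'
#' @slot margins (T+1) x n numeric matrix of raw margins; columns named by
#'   sample id.
#' @slot config the boosting configuration (see \code{\link{boostingConfig}}),
#'   including the seed.
#' @export
setClass("BoostingTrace",
  slots = c(margins = "matrix", config = "list"))

setValidity("BoostingTrace", function(object) {
  m <- object@margins
  if (any(!is.finite(m))) return("margins must be finite")
  if (nrow(m) < 2L) return("trace needs at least the base row and one iteration")
  if (diff(range(m[1L, ])) != 0) return("base-score row F_0 must be constant")
  cfg <- object@config
  if (!is.null(cfg$nIterations) && nrow(m) != cfg$nIterations + 1L)
    return("margins must have nIterations + 1 rows")
  TRUE
})

#' InfluenceScores: nonnegative MVS-A sample-influence scores
#'
#' @slot scores nonnegative numeric, one per training sample, named by id.
#' @slot lambda hessian regularizer used in the per-iteration magnitude.
#' @slot aggregation \code{"sum"} or \code{"mean"} over iterations.
#' @slot config provenance: the boosting config the trace came from.
#' @export
setClass("InfluenceScores",
  slots = c(scores = "numeric", lambda = "numeric",
            aggregation = "character", config = "list"))

setValidity("InfluenceScores", function(object) {
  if (any(object@scores < 0) || any(!is.finite(object@scores)))
    return("scores must be finite and nonnegative")
  if (!object@aggregation %in% c("sum", "mean"))
    return("aggregation outside {sum, mean}")
  if (length(object@lambda) != 1L || object@lambda < 0)
    return("lambda must be a single nonnegative number")
  TRUE
})

#' TriageResult: ranking of primary hits with flagged extremes
#'
#' Hits are sorted by influence score, descending; the top
#' \code{ceiling(fraction * nHits)} are flagged likely false positives and
#' the bottom \code{ceiling(fraction * nHits)} likely true positives.
#'
#' @slot table DataFrame with columns \code{compoundId}, \code{score},
#'   \code{rank} (1-based, rank 1 = highest score), \code{flag}.
#' @slot likelyFP compound ids flagged as likely false positives.
#' @slot likelyTP compound ids flagged as likely true positives.
#' @slot fraction the flagging fraction used.
#' @export
setClass("TriageResult",
  slots = c(table = "DataFrame", likelyFP = "character",
            likelyTP = "character", fraction = "numeric"))

setValidity("TriageResult", function(object) {
  tb <- object@table
  if (!all(c("compoundId", "score", "rank", "flag") %in% colnames(tb)))
    return("table must have compoundId, score, rank, flag")
  if (!all(object@likelyFP %in% tb$compoundId) ||
      !all(object@likelyTP %in% tb$compoundId))
    return("flagged subsets must be drawn from the ranked hits")
  if (object@fraction <= 0.5 &&
      length(intersect(object@likelyFP, object@likelyTP)) > 0 &&
      nrow(tb) > 1L)
    return("likelyFP and likelyTP must be disjoint for fraction <= 0.5")
  TRUE
})
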