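# Accessors and show methods for the core containers.

#' @describeIn ScreenSet number of compounds
#' @param x,object a \code{ScreenSet}
#' @export
setMethod("length", "ScreenSet", function(x) nrow(x@records))

#' Compound identifiers
#' @param x a \linkS4class{ScreenSet}
#' @return character vector in dataset order.
#' @export
compoundIds <- function(x) x@records$compoundId

#' Compound structures (SMILES)
#' @param x a \linkS4class{ScreenSet}
#' @return character vector of SMILES (NA for structure-free records).
#' @export
compoundSmiles <- function(x) x@records$smiles

#' Primary readouts (oriented larger = more active)
#' @param x a \linkS4class{ScreenSet}
#' @export
readouts <- function(x) x@records$readout

#' Primary activity calls
#' @param x a \linkS4class{ScreenSet}
#' @return logical vector; TRUE marks primary hits.
#' @export
isHit <- function(x) x@records$primaryActive

#' Confirmatory-screen outcomes
#' @param x a \linkS4class{ScreenSet}
#' @return character vector over
#'   \{active, inactive, inconclusive, untested\}.
#' @export
confirmatoryOutcomes <- function(x) x@records$confirmatoryOutcome

#' Ground-truth false-positive flags
#'
#' A compound is a confirmed false positive when it was called active in
#' the primary screen but was inactive or inconclusive in the confirmatory
#' screen.
#' @param x a \linkS4class{ScreenSet}
#' @export
isFalsePositive <- function(x) {
  isHit(x) & confirmatoryOutcomes(x) %in% c("inactive", "inconclusive")
}

#' Ground-truth true-positive flags
#'
#' A compound is a confirmed true positive when it was a primary hit and
#' active in the confirmatory screen.
#' @param x a \linkS4class{ScreenSet}
#' @export
isTruePositive <- function(x) {
  isHit(x) & confirmatoryOutcomes(x) == "active"
}

#' Number of primary hits
#' @param x a \linkS4class{ScreenSet}
#' @export
nHits <- function(x) sum(isHit(x))

#' Screen metadata
#' @param x a \linkS4class{ScreenSet}
#' @export
screenMetadata <- function(x) x@metadata

#' @describeIn ScreenSet subset records by index or logical mask
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[", "ScreenSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, records = x@records[i, , drop = FALSE])
})

#' @describeIn ScreenSet records as a base data.frame
#' @export
setMethod("as.data.frame", "ScreenSet", function(x, ...) {
  as.data.frame(x@records)
})

setMethod("show", "ScreenSet", function(object) {
  n <- length(object)
  nh <- nHits(object)
  conf <- sum(isHit(object) & confirmatoryOutcomes(object) != "untested")
  cat(sprintf("ScreenSet '%s': %d compounds, %d hits (%d with confirmatory data)\n",
              object@metadata$name, n, nh, conf))
  if (conf > 0)
    cat(sprintf("  confirmed FP fraction: %.3f\n",
                sum(isFalsePositive(object)) / conf))
})

#' Feature values
#' @param x a \linkS4class{FeatureMatrix}
#' @export
featureValues <- function(x) x@values

#' Feature kind
#' @param x a \linkS4class{FeatureMatrix}
#' @export
featureKind <- function(x) x@featureKind

#' Row identifiers of a FeatureMatrix
#' @param x a \linkS4class{FeatureMatrix}
#' @export
featureRowIds <- function(x) x@rowIds

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix [%s]: %d x %d\n", object@featureKind,
              nrow(object@values), ncol(object@values)))
})

#' Raw margins of a BoostingTrace
#' @param x a \linkS4class{BoostingTrace}
#' @return (T+1) x n matrix; row t+1 is the margin after iteration t.
#' @export
traceMargins <- function(x) x@margins

#' Boosting configuration of a trace
#' @param x a \linkS4class{BoostingTrace}
#' @export
traceConfig <- function(x) x@config

setMethod("show", "BoostingTrace", function(object) {
  cat(sprintf("BoostingTrace: %d iterations x %d samples (F0 = %.4f, seed %s)\n",
              nrow(object@margins) - 1L, ncol(object@margins),
              object@margins[1L, 1L], object@config$seed))
})

#' Influence score values
#' @param x an \linkS4class{InfluenceScores}
#' @return named numeric vector, one nonnegative score per sample.
#' @export
influenceValues <- function(x) x@scores

setMethod("show", "InfluenceScores", function(object) {
  cat(sprintf("InfluenceScores: n = %d, lambda = %g, aggregation = %s\n",
              length(object@scores), object@lambda, object@aggregation))
  cat(sprintf("  range [%.4g, %.4g]\n", min(object@scores),
              max(object@scores)))
})

#' Ranked triage table
#' @param x a \linkS4class{TriageResult}
#' @export
triageTable <- function(x) x@table

#' Likely-false-positive hit ids
#' @param x a \linkS4class{TriageResult}
#' @export
likelyFalsePositives <- function(x) x@likelyFP

#' Likely-true-positive hit ids
#' @param x a \linkS4class{TriageResult}
#' @export
likelyTruePositives <- function(x) x@likelyTP

setMethod("show", "TriageResult", function(object) {
  cat(sprintf("TriageResult: %d hits ranked; %d likely FP, %d likely TP (fraction %.2f)\n",
              nrow(object@table), length(object@likelyFP),
              length(object@likelyTP), object@fraction))
})
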