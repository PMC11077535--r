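#' @rdname accessors
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))
#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("helixWindows", function(x) standardGeneric("helixWindows"))
#' @rdname accessors
#' @export
setGeneric("isAligned", function(x) standardGeneric("isAligned"))
#' @rdname accessors
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))
#' @rdname accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
#' @rdname accessors
#' @export
setGeneric("meanVotes", function(x) standardGeneric("meanVotes"))
#' @rdname accessors
#' @export
setGeneric("normalizedVotes", function(x) standardGeneric("normalizedVotes"))
#' @rdname accessors
#' @export
setGeneric("votesQueryMoved", function(x) standardGeneric("votesQueryMoved"))
#' @rdname accessors
#' @export
setGeneric("votesTemplateMoved", function(x) standardGeneric("votesTemplateMoved"))
#' @rdname accessors
#' @export
setGeneric("winningOffset", function(x) standardGeneric("winningOffset"))
#' @rdname accessors
#' @export
setGeneric("runnerUpOffset", function(x) standardGeneric("runnerUpOffset"))
#' @rdname accessors
#' @export
setGeneric("dominanceRatio", function(x) standardGeneric("dominanceRatio"))
#' @rdname accessors
#' @export
setGeneric("productVector", function(x) standardGeneric("productVector"))
#' @rdname accessors
#' @export
setGeneric("templatesUsed", function(x) standardGeneric("templatesUsed"))

#' Accessors for helixvote S4 classes
#'
#' Read-only accessors for the slots of \linkS4class{ProfileFamily},
#' \linkS4class{VoteTable} and \linkS4class{ConsensusResult}.
#'
#' @param x The object.
#' @return The slot value.
#' @name accessors
#' @aliases familyId sequences helixWindows isAligned offsets nPairs
#'   meanVotes normalizedVotes votesQueryMoved votesTemplateMoved
#'   winningOffset runnerUpOffset dominanceRatio productVector templatesUsed
#' @examples
#' fam <- ProfileFamily("toy", c(s1 = "MVLSPADKTN"))
#' familyId(fam)
#' length(sequences(fam))
NULL

setMethod("familyId", "ProfileFamily", function(x) x@familyId)
setMethod("sequences", "ProfileFamily", function(x) x@sequences)
setMethod("helixWindows", "ProfileFamily", function(x) x@windows)
setMethod("isAligned", "ProfileFamily", function(x) x@isAligned)

setMethod("offsets", "VoteTable", function(x) x@offsets)
setMethod("nPairs", "VoteTable", function(x) x@nPairs)
setMethod("meanVotes", "VoteTable", function(x)
  stats::setNames(x@meanVotes, x@offsets))
setMethod("normalizedVotes", "VoteTable", function(x)
  stats::setNames(x@normalized, x@offsets))
setMethod("votesQueryMoved", "VoteTable", function(x)
  stats::setNames(x@votesQueryMoved, x@offsets))
setMethod("votesTemplateMoved", "VoteTable", function(x)
  stats::setNames(x@votesTemplateMoved, x@offsets))
setMethod("winningOffset", "VoteTable", function(x)
  .pickWinner(x@meanVotes, x@offsets)[["winner"]])

setMethod("offsets", "ConsensusResult", function(x) x@offsets)
setMethod("productVector", "ConsensusResult", function(x)
  stats::setNames(x@productVector, x@offsets))
setMethod("winningOffset", "ConsensusResult", function(x) x@winningOffset)
setMethod("runnerUpOffset", "ConsensusResult", function(x) x@runnerUpOffset)
setMethod("dominanceRatio", "ConsensusResult", function(x) x@dominanceRatio)
setMethod("templatesUsed", "ConsensusResult", function(x) x@templatesUsed)

setMethod("show", "ProfileFamily", function(object) {
  cat(sprintf("ProfileFamily '%s': %d sequence(s)%s\n", object@familyId,
              length(object@sequences),
              if (object@isAligned)
                sprintf(", aligned (width %d)",
                        Biostrings::width(object@sequences)[1L]) else ""))
  if (length(object@windows)) {
    spans <- vapply(object@windows,
                    function(w) sprintf("%s:%d-%d", w@helixId, w@start, w@end),
                    character(1))
    cat("  helix windows:", paste(spans, collapse = " "), "\n")
  }
})

setMethod("show", "HelixWindow", function(object) {
  cat(sprintf("HelixWindow %s [%s] %d-%d (%s)\n", object@helixId,
              object@familyId, object@start, object@end,
              object@coordinateSpace))
})

setMethod("show", "VoteTable", function(object) {
  w <- .pickWinner(object@meanVotes, object@offsets)
  cat(sprintf("VoteTable %s vs %s, helix %s: %d pairs over offsets %d..%d\n",
              object@templateId, object@queryId, object@helixId,
              object@nPairs, min(object@offsets), max(object@offsets)))
  cat(sprintf("  top offset %+d with mean %s votes\n", w[["winner"]],
              format(roundHalfDown(max(object@meanVotes)), big.mark = " ")))
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult helix %s over %d template(s): winner %+d (runner-up %+d, dominance %.3g)\n",
              object@helixId, length(object@templatesUsed),
              object@winningOffset, object@runnerUpOffset,
              object@dominanceRatio))
})

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf("ScoringScheme %s (out-of-range %g, gap %g)\n",
              object@matrixName, object@outOfRangeScore, object@gapScore))
})

setMethod("show", "PermutedLayout", function(object) {
  qo <- object@queryOrder
  if (!is.na(object@chainBreakAfter)) {
    i <- match(object@chainBreakAfter, qo)
    qo <- append(qo, "/", after = i)
  }
  cat(sprintf("PermutedLayout: templates %s | query %s\n",
              paste(object@canonicalOrder, collapse = "-"),
              paste(qo, collapse = "-")))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d sequence(s) of length %d, target identity %.2f, seed %d\n",
              object@nSequences, nchar(object@seedSequence),
              object@targetIdentity, object@rngSeed))
  if (length(object@plantedOffsets))
    cat("  planted offsets:",
        paste(sprintf("%s=%+d", names(object@plantedOffsets),
                      object@plantedOffsets), collapse = " "), "\n")
})
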