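#' @import methods
#' @importFrom Biostrings AAStringSet width readAAStringSet writeXStringSet
#'   BStringSet readBStringSet
#' @importFrom stats rbinom
#' @importFrom utils read.delim write.table data
NULL

## Residue alphabet: the 20 standard amino acids, ambiguity 'X', and the
## alignment gap '-'. '*' is reserved as the out-of-range marker emitted by
## extractWindow() and can never occur inside a stored sequence.
AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I",
                "L","K","M","F","P","S","T","W","Y","V")
ALPHABET_UNGAPPED <- c(AA_LETTERS, "X")
ALPHABET_GAPPED   <- c(ALPHABET_UNGAPPED, "-")
OOR_MARKER <- "*"
GAP_CHAR   <- "-"

VALID_HELIX_IDS <- c("A","B","C","D","E","F","G","H","IQ")
CANONICAL_HELICES <- c("A","B","C","D","E","F","G","H")

#' HelixWindow: a fixed residue span assigned to one globin helix
#'
#' A contiguous 1-based inclusive residue span (e.g. androglobin helix A,
#' Val939-Glu951) within the sequences of one family. Windows may be stated
#' in per-sequence coordinates or in alignment-column coordinates of an
#' internally aligned family.
#'
#' @slot helixId One of A-H or IQ.
#' @slot familyId Family the window belongs to.
#' @slot start,end 1-based inclusive span; length (end - start + 1) >= 4.
#' @slot coordinateSpace "sequence" or "alignment-column".
#' @exportClass HelixWindow
setClass("HelixWindow",
  representation(helixId = "character", familyId = "character",
                 start = "integer", end = "integer",
                 coordinateSpace = "character"))

setValidity("HelixWindow", function(object) {
  msg <- character()
  if (length(object@helixId) != 1L || !object@helixId %in% VALID_HELIX_IDS)
    msg <- c(msg, sprintf("helixId must be one of %s",
                          paste(VALID_HELIX_IDS, collapse = ", ")))
  if (length(object@start) != 1L || length(object@end) != 1L ||
      is.na(object@start) || is.na(object@end))
    msg <- c(msg, "start and end must be single non-missing integers")
  else {
    if (object@start < 1L)
      msg <- c(msg, "start must be >= 1 (coordinates are 1-based)")
    if (object@start > object@end)
      msg <- c(msg, sprintf("start (%d) must be <= end (%d)",
                            object@start, object@end))
    else if (object@end - object@start + 1L < 4L)
      msg <- c(msg, "window length must be >= 4")
  }
  if (!object@coordinateSpace %in% c("sequence", "alignment-column"))
    msg <- c(msg, "coordinateSpace must be 'sequence' or 'alignment-column'")
  if (length(msg)) msg else TRUE
})

#' ProfileFamily: a named set of homologous sequences with helix windows
#'
#' The profile unit of the voting method: one protein family (e.g. 235
#' alpha-hemoglobin sequences, or 73 androglobin globin domains), optionally
#' internally aligned, with the residue span of each globin helix recorded as
#' a \linkS4class{HelixWindow}.
#'
#' @slot familyId Family name.
#' @slot sequences An \code{AAStringSet}; gaps only if \code{isAligned}.
#' @slot windows Named list of \linkS4class{HelixWindow} (names = helix ids).
#' @slot isAligned TRUE when the family carries an internal alignment
#'   (equal-width sequences).
#' @slot recordWindows Optional per-record window overrides for unaligned
#'   families: data.frame with columns record_id, helix_id, start, end. An
#'   override must have the same length as the family window for that helix.
#' @exportClass ProfileFamily
setClass("ProfileFamily",
  representation(familyId = "character", sequences = "AAStringSet",
                 windows = "list", isAligned = "logical",
                 recordWindows = "data.frame"),
  prototype(windows = list(), isAligned = FALSE,
            recordWindows = data.frame(record_id = character(),
                                       helix_id = character(),
                                       start = integer(), end = integer())))

setValidity("ProfileFamily", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (n < 1L) msg <- c(msg, "family must contain at least one record")
  ids <- names(object@sequences)
  if (is.null(ids) || any(ids == "") || anyNA(ids))
    msg <- c(msg, "every record must have a non-empty id")
  else {
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate record id(s): %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (any(grepl("[[:space:]]", ids)))
      msg <- c(msg, "record ids must not contain whitespace")
  }
  if (n >= 1L && any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "sequences must be non-empty")
  allowed <- if (isTRUE(object@isAligned)) ALPHABET_GAPPED else ALPHABET_UNGAPPED
  bad <- .firstBadChar(object@sequences, allowed)
  if (!is.null(bad))
    msg <- c(msg, sprintf("illegal character '%s' in record '%s' at position %d",
                          bad$char, bad$id, bad$pos))
  if (isTRUE(object@isAligned) && n > 1L &&
      length(unique(Biostrings::width(object@sequences))) != 1L)
    msg <- c(msg, "aligned family must have equal-length sequences")
  for (w in object@windows) {
    if (!is(w, "HelixWindow")) { msg <- c(msg, "windows must be HelixWindow objects"); break }
    if (w@familyId != object@familyId)
      msg <- c(msg, sprintf("window %s belongs to family '%s', not '%s'",
                            w@helixId, w@familyId, object@familyId))
    if (w@coordinateSpace == "alignment-column") {
      if (!isTRUE(object@isAligned))
        msg <- c(msg, sprintf("window %s uses alignment-column coordinates but the family is not aligned", w@helixId))
      else if (w@end > Biostrings::width(object@sequences)[1L])
        msg <- c(msg, sprintf("window %s end (%d) exceeds alignment width (%d)",
                              w@helixId, w@end, Biostrings::width(object@sequences)[1L]))
    }
  }
  if (length(object@windows) &&
      !identical(names(object@windows),
                 unname(vapply(object@windows, function(w) w@helixId,
                               character(1)))))
    msg <- c(msg, "windows list names must equal their helixId")
  if (length(msg)) msg else TRUE
})

# locate the first disallowed character across a set of sequences
.firstBadChar <- function(sequences, allowed) {
  for (i in seq_along(sequences)) {
    chars <- strsplit(as.character(sequences[[i]]), "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% allowed)
    if (length(bad))
      return(list(id = names(sequences)[i], pos = bad[1L], char = chars[bad[1L]]))
  }
  NULL
}

#' ScoringScheme: substitution matrix plus edge-handling scores
#'
#' Ungapped window scoring under a symmetric amino-acid substitution matrix
#' (default BLOSUM62 as shipped with Biostrings). Positions that fall outside
#' a sequence when a window is slid score \code{outOfRangeScore} (default:
#' the matrix minimum over the 20 standard residues, so extreme shifts cannot
#' win by truncation); alignment gap characters score \code{gapScore}.
#'
#' @slot matrixName Name of the matrix ("BLOSUM62" unless supplied).
#' @slot matrix Numeric matrix over at least the 20 standard residues.
#' @slot outOfRangeScore Score per out-of-range position.
#' @slot gapScore Score per position involving a gap.
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(matrixName = "character", matrix = "matrix",
                 outOfRangeScore = "numeric", gapScore = "numeric",
                 lookup = "matrix"))

setValidity("ScoringScheme", function(object) {
  m <- object@matrix
  if (!all(AA_LETTERS %in% rownames(m)) || !all(AA_LETTERS %in% colnames(m)))
    return("matrix must cover the 20 standard amino acids")
  core <- m[AA_LETTERS, AA_LETTERS]
  if (!isTRUE(all.equal(core, t(core))))
    return("matrix must be symmetric over the 20 standard residues")
  TRUE
})

#' OffsetRange: the span of integer shifts explored by voting
#'
#' @slot minShift,maxShift Inclusive bounds with minShift <= 0 <= maxShift.
#'   The default, -25..+25, is the range over which query and template
#'   helices are slid against each other.
#' @exportClass OffsetRange
setClass("OffsetRange",
  representation(minShift = "integer", maxShift = "integer"),
  prototype(minShift = -25L, maxShift = 25L))

setValidity("OffsetRange", function(object) {
  if (length(object@minShift) != 1L || length(object@maxShift) != 1L)
    return("minShift and maxShift must be single integers")
  if (object@minShift > 0L || object@maxShift < 0L)
    return("offset range must satisfy minShift <= 0 <= maxShift")
  TRUE
})

#' VoteTable: per-offset vote counts for one template/query/helix triple
#'
#' Every cross-family sequence pair casts one vote (split 1/k across k tied
#' offsets) for its best-scoring offset, once with the query window slid
#' (\code{votesQueryMoved}) and once with the template window slid and the
#' result re-indexed onto the query-moved axis (\code{votesTemplateMoved}).
#' A positive offset means the query helix content lies that many residues
#' to the right (C-terminal) of the configured window coordinates.
#'
#' @slot templateId,queryId,helixId Identity of the comparison.
#' @slot offsets Integer offset axis (query-moved convention).
#' @slot votesQueryMoved,votesTemplateMoved Vote vectors; each sums to nPairs.
#' @slot meanVotes Per-offset mean of the two directions.
#' @slot normalized meanVotes scaled to [0,1] by its maximum (all-zero input
#'   stays all-zero).
#' @slot nPairs Number of cross-family pairs (|template| x |query|).
#' @exportClass VoteTable
setClass("VoteTable",
  representation(templateId = "character", queryId = "character",
                 helixId = "character", offsets = "integer",
                 votesQueryMoved = "numeric", votesTemplateMoved = "numeric",
                 meanVotes = "numeric", normalized = "numeric",
                 nPairs = "integer"))

setValidity("VoteTable", function(object) {
  msg <- character()
  k <- length(object@offsets)
  for (nm in c("votesQueryMoved", "votesTemplateMoved", "meanVotes", "normalized"))
    if (length(slot(object, nm)) != k)
      msg <- c(msg, sprintf("%s must have one entry per offset", nm))
  if (any(object@votesQueryMoved < 0) || any(object@votesTemplateMoved < 0))
    msg <- c(msg, "vote counts must be non-negative")
  if (length(object@nPairs) != 1L || object@nPairs < 1L)
    msg <- c(msg, "nPairs must be a single positive integer")
  tol <- 1e-8 * max(1, object@nPairs)
  if (!length(msg)) {
    if (abs(sum(object@votesQueryMoved) - object@nPairs) > tol)
      msg <- c(msg, "query-moved votes must sum to nPairs")
    if (abs(sum(object@votesTemplateMoved) - object@nPairs) > tol)
      msg <- c(msg, "template-moved votes must sum to nPairs")
    if (max(abs(object@meanVotes -
                (object@votesQueryMoved + object@votesTemplateMoved) / 2)) > tol)
      msg <- c(msg, "meanVotes must equal the per-offset mean of the two directions")
    if (any(object@normalized < 0) || any(object@normalized > 1 + 1e-12))
      msg <- c(msg, "normalized votes must lie in [0,1]")
    if (any(object@meanVotes > 0) && abs(max(object@normalized) - 1) > 1e-12)
      msg <- c(msg, "normalized maximum must be 1 when any vote is nonzero")
  }
  if (length(msg)) msg else TRUE
})

#' ConsensusResult: cross-template product of normalized vote vectors
#'
#' The entrywise product over templates of the [0,1]-normalized vote vectors
#' for one helix; the winning offset is the argmax (ties broken toward the
#' smallest |offset|, then the negative one).
#'
#' @slot helixId Helix the consensus is for.
#' @slot templatesUsed Template ids that entered the product.
#' @slot offsets Offset axis.
#' @slot productVector Entrywise product, each entry in [0,1].
#' @slot winningOffset,runnerUpOffset Best and second-best offsets.
#' @slot dominanceRatio product(winner)/product(runner-up); Inf when the
#'   runner-up product is 0.
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  representation(helixId = "character", templatesUsed = "character",
                 offsets = "integer", productVector = "numeric",
                 winningOffset = "integer", runnerUpOffset = "integer",
                 dominanceRatio = "numeric"))

setValidity("ConsensusResult", function(object) {
  if (length(object@productVector) != length(object@offsets))
    return("productVector must have one entry per offset")
  if (any(object@productVector < 0) || any(object@productVector > 1 + 1e-12))
    return("product entries must lie in [0,1]")
  TRUE
})

#' PermutedLayout: helix display order of a circularly permuted query
#'
#' Describes how the query's helices map onto the canonical A-H template
#' order: androglobin expresses helices D-H on the N-terminal side, then
#' (after a chain break and the inserted IQ calmodulin-binding segment)
#' helices A-C, so its queryOrder is D,E,F,G,H,IQ,A,B,C with the break after
#' H.
#'
#' @slot canonicalOrder Helix order of the templates (subset of A..H).
#' @slot queryOrder Order in which the query expresses those helices, plus
#'   at most one inserted non-helix segment ("IQ").
#' @slot chainBreakAfter Helix (in query order) after which the rendered
#'   query sequence is discontiguous; NA_character_ when there is no break.
#' @slot annotations data.frame with columns glyph, family_id, position
#'   (1-based residue/column index) marking key residues: 'a' CD1 aromatic,
#'   'b' proximal His, 'c' distal His/Gln, '#' disulfide cysteines.
#' @exportClass PermutedLayout
setClass("PermutedLayout",
  representation(canonicalOrder = "character", queryOrder = "character",
                 chainBreakAfter = "character", annotations = "data.frame"),
  prototype(chainBreakAfter = NA_character_,
            annotations = data.frame(glyph = character(),
                                     family_id = character(),
                                     position = integer())))

setValidity("PermutedLayout", function(object) {
  msg <- character()
  if (!all(object@canonicalOrder %in% CANONICAL_HELICES))
    msg <- c(msg, "canonicalOrder must be a subset of helices A..H")
  if (is.unsorted(match(object@canonicalOrder, CANONICAL_HELICES)))
    msg <- c(msg, "canonicalOrder must follow A..H order")
  extra <- setdiff(object@queryOrder, c(object@canonicalOrder, "IQ"))
  if (length(extra))
    msg <- c(msg, sprintf("queryOrder contains unknown segment(s): %s",
                          paste(extra, collapse = ", ")))
  helicesOnly <- setdiff(object@queryOrder, "IQ")
  if (!setequal(helicesOnly, object@canonicalOrder))
    msg <- c(msg, "queryOrder must contain exactly the canonical helices (plus optionally IQ)")
  else if (length(helicesOnly) > 1L) {
    pos <- match(helicesOnly, object@canonicalOrder)
    # a rotation of 1..n has exactly one backward step (or none)
    drops <- sum(diff(pos) < 0)
    if (drops > 1L)
      msg <- c(msg, "queryOrder must be a rotation of canonicalOrder")
  }
  if (!is.na(object@chainBreakAfter) &&
      !object@chainBreakAfter %in% object@queryOrder)
    msg <- c(msg, "chainBreakAfter must name a segment of queryOrder")
  if (!all(c("glyph", "family_id", "position") %in% colnames(object@annotations)))
    msg <- c(msg, "annotations must have columns glyph, family_id, position")
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: recipe for a synthetic sequence family
#'
#' Defines a family derived from a single seed sequence with a controlled
#' expected pairwise identity, optional planted helix offsets and exact
#' planted column compositions, fully reproducible from one integer seed.
#'
#' @slot seedSequence Residue string the family is derived from.
#' @slot nSequences Number of records to generate.
#' @slot targetIdentity Expected mean pairwise identity between generated
#'   records, in (0, 1]; the per-position substitution rate is calibrated so
#'   the realized pairwise identity matches this target (see
#'   \code{\link{generateFamily}}). Values below 0.05, the floor of the
#'   uniform-background substitution model, are rejected.
#' @slot plantedOffsets Named integer vector helix id -> planted shift.
#' @slot columnPlants data.frame(column, residue, count): exact residue
#'   counts forced at given columns.
#' @slot rngSeed Single integer seed.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(seedSequence = "character", nSequences = "integer",
                 targetIdentity = "numeric", plantedOffsets = "integer",
                 columnPlants = "data.frame", rngSeed = "integer"),
  prototype(plantedOffsets = integer(),
            columnPlants = data.frame(column = integer(),
                                      residue = character(),
                                      count = integer()),
            rngSeed = 1L))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  chars <- strsplit(object@seedSequence, "", fixed = TRUE)[[1]]
  if (!length(chars) || !all(chars %in% ALPHABET_UNGAPPED))
    msg <- c(msg, "seedSequence must be a non-empty string over the amino-acid alphabet")
  if (object@nSequences < 1L)
    msg <- c(msg, "nSequences must be positive")
  if (object@targetIdentity <= 0 || object@targetIdentity > 1)
    msg <- c(msg, "targetIdentity must lie in (0, 1]")
  else {
    if (object@targetIdentity < 0.05)
      msg <- c(msg, "targetIdentity below 0.05 is unreachable under uniform-background substitution")
    if (object@targetIdentity * length(chars) < 1)
      msg <- c(msg, "targetIdentity x sequence length must be >= 1")
  }
  cp <- object@columnPlants
  if (!all(c("column", "residue", "count") %in% colnames(cp)))
    msg <- c(msg, "columnPlants must have columns column, residue, count")
  else if (nrow(cp)) {
    if (any(cp$count > object@nSequences))
      msg <- c(msg, "a column plant count cannot exceed nSequences")
    if (any(cp$column < 1L | cp$column > length(chars)))
      msg <- c(msg, "column plant outside the sequence")
    if (any(!cp$residue %in% AA_LETTERS))
      msg <- c(msg, "planted residues must be standard amino acids")
    if (anyDuplicated(cp$column))
      msg <- c(msg, "at most one plant per column")
  }
  if (length(msg)) msg else TRUE
})
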