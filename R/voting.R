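## Core voting engine: every ordered cross-family sequence pair scores a
## fixed-length helix window at every integer offset and votes for its best
## offset. Ties split the vote 1/k. Everything is deterministic; iteration
## order is the input record order.

# integer codes (into LOOKUP_LETTERS) for every record of a family
.familyCodes <- function(family) {
  lapply(as.character(family@sequences), .encode)
}

OOR_CODE <- length(ALPHABET_UNGAPPED) + 2L  # index of '*' in LOOKUP_LETTERS

# n x L integer matrix of window codes for every record at one shift;
# positions outside the record are the out-of-range code
.windowCodeMatrix <- function(codes, starts, L, shift) {
  n <- length(codes)
  out <- matrix(OOR_CODE, n, L)
  rel <- 0:(L - 1L)
  for (i in seq_len(n)) {
    idx <- starts[i] + shift + rel
    v <- codes[[i]]
    ok <- idx >= 1L & idx <= length(v)
    if (any(ok)) out[i, ok] <- v[idx[ok]]
  }
  out
}

# score matrix (nFixed x nMoved) between fixed windows F and moved windows W
.scoreMatrix <- function(lookup, F, W) {
  s <- matrix(0, nrow(F), nrow(W))
  for (k in seq_len(ncol(F)))
    s <- s + lookup[F[, k], W[, k], drop = FALSE]
  s
}

#' Cast one direction of offset votes for a helix
#'
#' Scores every ordered (template record, query record) pair at every shift
#' in \code{range} and gives each pair one vote for its best-scoring shift;
#' when k shifts tie for the maximum the vote is split 1/k, so the vector
#' always sums to the number of pairs. \code{direction} selects which
#' family's window is slid while the other stays at its configured span.
#' Votes are indexed by the shift applied to the moved family; see
#' \code{\link{tally}} for the re-indexing that puts both directions on one
#' axis.
#'
#' @param template,query \linkS4class{ProfileFamily} objects whose windows
#'   for \code{helix} have identical length.
#' @param helix Helix id, e.g. "A".
#' @param range An \linkS4class{OffsetRange}.
#' @param direction "query_moved" or "template_moved".
#' @param scheme A \linkS4class{ScoringScheme}.
#' @return Named numeric vector of votes (names = shifts of the moved
#'   family), with attribute \code{nPairs}.
#' @examples
#' t <- ProfileFamily("t", c(a = "MVLSPADKTNVKAAW"),
#'                    windows = list(HelixWindow("A", "t", 3, 9)))
#' q <- ProfileFamily("q", c(b = "MVLSPADKTNVKAAW"),
#'                    windows = list(HelixWindow("A", "q", 3, 9)))
#' v <- castVotes(t, q, "A", OffsetRange(-3, 3), "query_moved", scoringScheme())
#' v  # the single self-pair votes for shift 0
#' @export
castVotes <- function(template, query, helix, range = OffsetRange(),
                      direction = c("query_moved", "template_moved"),
                      scheme = scoringScheme()) {
  direction <- match.arg(direction)
  stopifnot(is(template, "ProfileFamily"), is(query, "ProfileFamily"),
            is(range, "OffsetRange"), is(scheme, "ScoringScheme"))
  Lt <- .windowLength(template, helix)
  Lq <- .windowLength(query, helix)
  if (Lt != Lq)
    stop(sprintf("helix %s windows differ in length between '%s' (%d) and '%s' (%d)",
                 helix, template@familyId, Lt, query@familyId, Lq))
  L <- Lt
  shifts <- offsetAxis(range)
  tCodes <- .familyCodes(template); tStarts <- .windowStarts(template, helix)
  qCodes <- .familyCodes(query);    qStarts <- .windowStarts(query, helix)
  if (direction == "query_moved") {
    fixed <- .windowCodeMatrix(tCodes, tStarts, L, 0L)
    movedCodes <- qCodes; movedStarts <- qStarts
  } else {
    fixed <- .windowCodeMatrix(qCodes, qStarts, L, 0L)
    movedCodes <- tCodes; movedStarts <- tStarts
  }
  nFixed <- nrow(fixed); nMoved <- length(movedCodes)
  nPairs <- length(tCodes) * length(qCodes)
  scores <- matrix(NA_real_, nFixed * nMoved, length(shifts))
  for (si in seq_along(shifts)) {
    W <- .windowCodeMatrix(movedCodes, movedStarts, L, shifts[si])
    scores[, si] <- as.vector(.scoreMatrix(scheme@lookup, fixed, W))
  }
  best <- do.call(pmax, as.data.frame(scores))
  isMax <- scores >= best - 1e-9
  votes <- colSums(isMax / rowSums(isMax))
  names(votes) <- shifts
  attr(votes, "nPairs") <- nPairs
  votes
}

#' Scale a vote vector to [0, 1]
#'
#' Divides by the vector maximum, the scaling used for the per-helix vote
#' bars; an all-zero vector maps to all zeros.
#'
#' @param meanVotes Non-negative numeric vector.
#' @return Vector of the same length in [0, 1].
#' @examples
#' normalizeVotes(c(10, 5, 0))
#' @export
normalizeVotes <- function(meanVotes) {
  if (any(meanVotes < 0)) stop("vote counts must be non-negative")
  m <- max(meanVotes)
  if (m == 0) return(meanVotes)
  meanVotes / m
}

#' Round half-down to integer
#'
#' Display rounding for vote means: exact .5 values round toward zero
#' (2.5 -> 2), everything else to the nearest integer. Full precision is
#' always retained internally; this is only for reports.
#'
#' @param x Non-negative numeric vector.
#' @return Integer-valued numeric vector.
#' @examples
#' roundHalfDown(c(10332.5, 2219, 0.4))
#' @export
roundHalfDown <- function(x) ceiling(x - 0.5)

#' Construct a VoteTable from per-direction vote vectors
#'
#' Combines the two direction vectors (already on the shared query-moved
#' offset axis) into means and [0,1]-normalized values. Use
#' \code{\link{tally}} to compute the vectors from sequence families; this
#' constructor also lets known vote counts be injected directly.
#'
#' @param templateId,queryId,helixId Identity of the comparison.
#' @param offsets Integer offset axis.
#' @param votesQueryMoved,votesTemplateMoved Vote vectors on that axis.
#' @param nPairs Number of cross-family pairs; defaults to
#'   \code{sum(votesQueryMoved)}.
#' @return A \linkS4class{VoteTable}.
#' @examples
#' ## inject the alpha-Hb vs Adgb helix A counts (votes not at 0 or +4
#' ## pooled on a third offset so each direction still sums to 17155 pairs)
#' vt <- VoteTable("aHb", "Adgb", "A", offsets = c(-1L, 0L, 4L),
#'                 votesQueryMoved = c(17155 - 10664 - 3664, 10664, 3664),
#'                 votesTemplateMoved = c(17155 - 10001 - 774, 10001, 774))
#' roundHalfDown(meanVotes(vt))
#' @export
VoteTable <- function(templateId, queryId, helixId, offsets,
                      votesQueryMoved, votesTemplateMoved,
                      nPairs = NULL) {
  if (is.null(nPairs)) nPairs <- sum(votesQueryMoved)
  meanVotes <- (votesQueryMoved + votesTemplateMoved) / 2
  new("VoteTable", templateId = templateId, queryId = queryId,
      helixId = helixId, offsets = as.integer(offsets),
      votesQueryMoved = as.numeric(votesQueryMoved),
      votesTemplateMoved = as.numeric(votesTemplateMoved),
      meanVotes = meanVotes, normalized = normalizeVotes(meanVotes),
      nPairs = as.integer(round(nPairs)))
}

#' Tally both voting directions into a VoteTable
#'
#' Runs \code{\link{castVotes}} with the query windows slid and again with
#' the template windows slid, then puts both on a single axis: sliding the
#' template by t is the same relative displacement as sliding the query by
#' -t, so the template-moved vector is re-indexed by negation. On that axis
#' a positive offset means the query helix content lies to the right
#' (C-terminal) of its configured window coordinates. Means and normalized
#' values follow.
#'
#' @inheritParams castVotes
#' @return A \linkS4class{VoteTable}.
#' @examples
#' sc <- scoringScheme()
#' t <- ProfileFamily("t", c(a = "GMVLSPADKTNVKAAWGKV"),
#'                    windows = list(HelixWindow("A", "t", 5, 12)))
#' q <- ProfileFamily("q", c(b = "GMVLSPADKTNVKAAWGKV"),
#'                    windows = list(HelixWindow("A", "q", 5, 12)))
#' tab <- tally(t, q, "A", OffsetRange(-4, 4), sc)
#' meanVotes(tab)
#' @export
tally <- function(template, query, helix, range = OffsetRange(),
                  scheme = scoringScheme()) {
  vq <- castVotes(template, query, helix, range, "query_moved", scheme)
  vt <- castVotes(template, query, helix, range, "template_moved", scheme)
  nPairs <- attr(vq, "nPairs")
  # template shift t <-> query-moved offset -t: reverse onto the shared axis
  vtRe <- rev(as.numeric(vt))
  VoteTable(template@familyId, query@familyId, helix,
            offsets = offsetAxis(range),
            votesQueryMoved = as.numeric(vq),
            votesTemplateMoved = vtRe, nPairs = nPairs)
}

# winner/runner-up on an offset axis: ties resolved toward smallest |offset|,
# then the negative one first
.pickWinner <- function(values, offsets) {
  ord <- order(-values, abs(offsets), offsets)
  list(winner = offsets[ord[1L]],
       runnerUp = if (length(offsets) > 1L) offsets[ord[2L]] else NA_integer_,
       winnerValue = values[ord[1L]],
       runnerUpValue = if (length(offsets) > 1L) values[ord[2L]] else NA_real_)
}

#' Export a VoteTable to TSV
#'
#' One row per offset with both direction counts, their mean and the
#' normalized value.
#'
#' @param table A \linkS4class{VoteTable}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
exportVoteTable <- function(table, path) {
  df <- data.frame(template_id = table@templateId, query_id = table@queryId,
                   helix_id = table@helixId, offset = table@offsets,
                   votes_query_moved = table@votesQueryMoved,
                   votes_template_moved = table@votesTemplateMoved,
                   mean = table@meanVotes, normalized = table@normalized)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
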