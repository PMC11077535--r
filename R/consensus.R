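#' Consensus offset across templates by vote-vector multiplication
#'
#' Multiplies the [0,1]-normalized vote vectors of several templates
#' entrywise, so only an offset supported by every template keeps a high
#' product; the argmax of the product is the consensus offset for the helix.
#' Ties are resolved toward the smallest |offset| (the no-shift null), then
#' the negative one. Templates whose vote vectors are all zero carry no
#' information and are dropped from the product with a warning rather than
#' zeroing the consensus.
#'
#' @param tables List of \linkS4class{VoteTable} objects for one helix, one
#'   per template, sharing the same offset axis.
#' @return A \linkS4class{ConsensusResult}.
#' @examples
#' v1 <- VoteTable("t1", "q", "A", c(0L, 4L), c(8, 2), c(9, 1))
#' v2 <- VoteTable("t2", "q", "A", c(0L, 4L), c(7, 3), c(9, 1))
#' consensusOffsets(list(v1, v2))
#' @export
consensusOffsets <- function(tables) {
  if (!length(tables))
    stop("consensus needs at least one vote table")
  helices <- unique(vapply(tables, function(t) t@helixId, character(1)))
  if (length(helices) != 1L)
    stop("all vote tables must describe the same helix, got: ",
         paste(helices, collapse = ", "))
  axis <- tables[[1L]]@offsets
  for (t in tables)
    if (!identical(t@offsets, axis))
      stop("vote tables must share one offset axis")
  zero <- vapply(tables, function(t) all(t@meanVotes == 0), logical(1))
  if (any(zero)) {
    warning("dropping zero-vote template(s) from the consensus: ",
            paste(vapply(tables[zero], function(t) t@templateId,
                         character(1)), collapse = ", "))
    tables <- tables[!zero]
  }
  if (!length(tables))
    stop("no template contributed any votes")
  prod <- Reduce(`*`, lapply(tables, function(t) t@normalized))
  w <- .pickWinner(prod, axis)
  dom <- if (is.na(w$runnerUp)) Inf
         else if (w$runnerUpValue == 0) Inf
         else w$winnerValue / w$runnerUpValue
  new("ConsensusResult", helixId = helices,
      templatesUsed = vapply(tables, function(t) t@templateId, character(1)),
      offsets = axis, productVector = as.numeric(prod),
      winningOffset = as.integer(w$winner),
      runnerUpOffset = as.integer(w$runnerUp), dominanceRatio = dom)
}

#' Mean cross-family percent identity of a helix at an offset
#'
#' For every ordered (template record, query record) pair, the fraction of
#' window positions carrying the identical residue when the query window is
#' read at \code{offset}, averaged over all pairs and expressed as a
#' percentage. Out-of-range and gap positions count as non-identical, so the
#' denominator is always the full window length.
#'
#' @param template,query \linkS4class{ProfileFamily} objects with
#'   equal-length windows for \code{helix}.
#' @param helix Helix id.
#' @param offset Integer offset at which the query window is read (use the
#'   consensus winner).
#' @return Percentage in [0, 100].
#' @examples
#' t <- ProfileFamily("t", c(a = "GACDEFG"),
#'                    windows = list(HelixWindow("B", "t", 2, 6)))
#' q <- ProfileFamily("q", c(b = "GACDQFG"),
#'                    windows = list(HelixWindow("B", "q", 2, 6)))
#' percentIdentity(t, q, "B", 0)   # 4 of 5 positions -> 80
#' @export
percentIdentity <- function(template, query, helix, offset = 0L) {
  L <- .windowLength(template, helix)
  if (L != .windowLength(query, helix))
    stop(sprintf("helix %s windows differ in length between the families", helix))
  Tm <- .windowCodeMatrix(.familyCodes(template),
                          .windowStarts(template, helix), L, 0L)
  Qm <- .windowCodeMatrix(.familyCodes(query),
                          .windowStarts(query, helix), L, as.integer(offset))
  nIdent <- matrix(0, nrow(Tm), nrow(Qm))
  valid <- length(ALPHABET_UNGAPPED)  # codes above this are gap or marker
  for (k in seq_len(L)) {
    eq <- outer(Tm[, k], Qm[, k], `==`) &
      outer(Tm[, k] <= valid, Qm[, k] <= valid, `&`)
    nIdent <- nIdent + eq
  }
  mean(nIdent) / L * 100
}

#' Mean helical percent identity
#'
#' Unweighted arithmetic mean of per-helix percent identities, the summary
#' used to rank a query's overall similarity to each template family.
#'
#' @param perHelix Named numeric vector or list, helix id -> percentage.
#' @return A single percentage.
#' @examples
#' meanHelixIdentity(c(A = 15.3, B = 14.1, E = 20.0, F = 26.0, G = 9.5, H = 7.8))
#' @export
meanHelixIdentity <- function(perHelix) {
  v <- unlist(perHelix)
  if (!length(v)) stop("at least one helix identity is required")
  mean(v)
}

#' Residue frequencies at one alignment column
#'
#' Fractions of each residue among the non-gap characters of one column of
#' an internally aligned family (e.g. the CD1 column, where androglobin
#' carries Tyr in ~82\% of sequences). The gap fraction is reported
#' separately via the \code{gapFraction} attribute.
#'
#' @param family An aligned \linkS4class{ProfileFamily}.
#' @param column 1-based alignment column.
#' @return Named numeric vector of fractions summing to 1 over non-gap
#'   residues (empty when the column is all gaps), sorted decreasing, with
#'   attribute \code{gapFraction}.
#' @examples
#' fam <- ProfileFamily("toy", c(a = "AYG", b = "AYG", c = "AFG", d = "AYG"),
#'                      isAligned = TRUE)
#' columnFrequencies(fam, 2)   # Y 0.75, F 0.25
#' @export
columnFrequencies <- function(family, column) {
  stopifnot(is(family, "ProfileFamily"))
  if (!isTRUE(family@isAligned))
    stop("column frequencies require an internally aligned family")
  column <- as.integer(column)
  width <- Biostrings::width(family@sequences)[1L]
  if (column < 1L || column > width)
    stop(sprintf("column %d outside alignment width %d", column, width))
  chars <- substr(as.character(family@sequences), column, column)
  isGap <- chars == GAP_CHAR
  gapFraction <- mean(isGap)
  res <- chars[!isGap]
  freqs <- if (length(res)) sort(table(res) / length(res), decreasing = TRUE)
           else table(character())
  out <- stats::setNames(as.numeric(freqs), names(freqs))
  attr(out, "gapFraction") <- gapFraction
  out
}

#' Export consensus results to TSV
#'
#' One row per offset per helix with the product value and a winner flag.
#'
#' @param results List of \linkS4class{ConsensusResult} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
exportConsensus <- function(results, path) {
  if (is(results, "ConsensusResult")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(helix_id = r@helixId, offset = r@offsets,
               product = r@productVector,
               winner = r@offsets == r@winningOffset)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
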