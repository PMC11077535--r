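## Extended lookup alphabet: 20 residues, X, gap, out-of-range marker.
LOOKUP_LETTERS <- c(ALPHABET_UNGAPPED, GAP_CHAR, OOR_MARKER)

#' Construct a ScoringScheme
#'
#' Window scores are plain sums of substitution-matrix entries over the
#' window positions — ungapped, no insertions. Out-of-range positions
#' (created when a window is slid past a sequence end) contribute
#' \code{outOfRangeScore}; by default this is the matrix minimum over the 20
#' standard residues, so a shift can never profit from hanging off the edge.
#' Positions where either sequence carries an alignment gap contribute
#' \code{gapScore} (default 0); out-of-range takes precedence over gap.
#'
#' @param matrix Symmetric substitution matrix over (at least) the 20
#'   standard residues, or NULL for BLOSUM62 as shipped with Biostrings.
#' @param matrixName Label used in reports.
#' @param outOfRangeScore Score per out-of-range position; default
#'   \code{min(matrix)} over the standard residues.
#' @param gapScore Score per gapped position.
#' @return A \linkS4class{ScoringScheme}.
#' @examples
#' sc <- scoringScheme()        # BLOSUM62, out-of-range -4, gap 0
#' sc
#' @export
scoringScheme <- function(matrix = NULL, matrixName = NULL,
                          outOfRangeScore = NULL, gapScore = 0) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
    if (is.null(matrixName)) matrixName <- "BLOSUM62"
  }
  if (is.null(matrixName)) matrixName <- "custom"
  if (is.null(outOfRangeScore))
    outOfRangeScore <- min(matrix[AA_LETTERS, AA_LETTERS])
  lookup <- .buildLookup(matrix, outOfRangeScore, gapScore)
  new("ScoringScheme", matrixName = matrixName, matrix = matrix,
      outOfRangeScore = outOfRangeScore, gapScore = gapScore,
      lookup = lookup)
}

# Dense lookup over LOOKUP_LETTERS with edge rules baked in:
# gap vs anything (non-oor) = gapScore; out-of-range vs anything = oorScore.
.buildLookup <- function(matrix, outOfRangeScore, gapScore) {
  k <- length(LOOKUP_LETTERS)
  lk <- matrix(0, k, k, dimnames = list(LOOKUP_LETTERS, LOOKUP_LETTERS))
  have <- intersect(ALPHABET_UNGAPPED, rownames(matrix))
  lk[have, have] <- matrix[have, have]
  if (!"X" %in% have) { lk["X", ALPHABET_UNGAPPED] <- -1; lk[ALPHABET_UNGAPPED, "X"] <- -1 }
  lk[GAP_CHAR, ] <- gapScore; lk[, GAP_CHAR] <- gapScore
  lk[OOR_MARKER, ] <- outOfRangeScore; lk[, OOR_MARKER] <- outOfRangeScore
  lk
}

# residue string -> integer codes into the lookup alphabet
.encode <- function(residues) {
  codes <- match(strsplit(residues, "", fixed = TRUE)[[1]], LOOKUP_LETTERS)
  if (anyNA(codes))
    stop("string contains a character outside the residue alphabet")
  codes
}

#' Score one pair of equal-length windows
#'
#' @param templateWindow,queryWindow Residue strings of identical length as
#'   returned by \code{\link{extractWindow}} (may contain '*' markers and,
#'   for aligned families, '-').
#' @param scheme A \linkS4class{ScoringScheme}.
#' @return The window score (a single number).
#' @examples
#' sc <- scoringScheme()
#' scorePairAtOffset("AAA", "AAA", sc)   # 3 x BLOSUM62[A,A] = 12
#' scorePairAtOffset("AA*", "AAA", sc)   # 2 x 4 + out-of-range (-4) = 4
#' @export
scorePairAtOffset <- function(templateWindow, queryWindow, scheme) {
  stopifnot(is(scheme, "ScoringScheme"))
  a <- .encode(templateWindow); b <- .encode(queryWindow)
  if (length(a) != length(b))
    stop("windows must have identical length")
  sum(scheme@lookup[cbind(a, b)])
}

#' Construct an OffsetRange
#'
#' @param minShift,maxShift Inclusive shift bounds (minShift <= 0 <= maxShift).
#'   Defaults to the -25..+25 range used for the androglobin alignments.
#' @return An \linkS4class{OffsetRange}.
#' @export
OffsetRange <- function(minShift = -25L, maxShift = 25L) {
  new("OffsetRange", minShift = as.integer(minShift),
      maxShift = as.integer(maxShift))
}

#' @rdname OffsetRange
#' @param x An OffsetRange.
#' @export
offsetAxis <- function(x) x@minShift:x@maxShift
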