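#' Construct a SyntheticSpec
#'
#' @param seedSequence Residue string the family derives from.
#' @param nSequences Number of records.
#' @param targetIdentity Expected mean pairwise identity between records, in
#'   [0.05, 1].
#' @param plantedOffsets Named integer vector helix id -> shift to plant via
#'   \code{\link{plantOffset}}.
#' @param columnPlants data.frame(column, residue, count) of exact residue
#'   counts to force at given columns.
#' @param rngSeed Integer seed; the whole family is reproducible from it.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
SyntheticSpec <- function(seedSequence, nSequences, targetIdentity = 1,
                          plantedOffsets = integer(),
                          columnPlants = NULL, rngSeed = 1L) {
  if (is.null(columnPlants))
    columnPlants <- data.frame(column = integer(), residue = character(),
                               count = integer())
  po <- as.integer(plantedOffsets)
  names(po) <- names(plantedOffsets)
  new("SyntheticSpec", seedSequence = seedSequence,
      nSequences = as.integer(nSequences),
      targetIdentity = as.numeric(targetIdentity),
      plantedOffsets = po, columnPlants = columnPlants,
      rngSeed = as.integer(rngSeed))
}

#' Generate a random seed sequence
#'
#' Uniform draw over the 20 standard residues; a convenience for building
#' \linkS4class{SyntheticSpec} objects in tests and simulations.
#'
#' @param length Sequence length.
#' @param rngSeed Integer seed.
#' @return Residue string.
#' @export
randomSeedSequence <- function(length, rngSeed = 1L) {
  set.seed(rngSeed)
  paste(sample(AA_LETTERS, length, replace = TRUE), collapse = "")
}

# Per-position substitution rate m such that two records independently
# mutated from the seed at rate m (uniform replacement over the 19 other
# residues) have expected pairwise identity t:
#   P(match) = (1-m)^2 + m^2/19 = t  =>  m = (19/20)(1 - sqrt(1 - 20(1-t)/19))
.calibratedRate <- function(targetIdentity) {
  disc <- 1 - 20 * (1 - targetIdentity) / 19
  (19 / 20) * (1 - sqrt(max(disc, 0)))
}

#' Generate a synthetic sequence family
#'
#' Derives \code{nSequences} records from the seed sequence by independent
#' per-position substitution with uniform replacement (the original residue
#' excluded). The substitution rate is calibrated so that the expected mean
#' \emph{pairwise} identity between records equals \code{targetIdentity},
#' which is what the twilight-zone regime is stated in. Column plants then
#' force exact residue counts at chosen columns (records 1..count receive the
#' planted residue; any later record that drew it there is switched to a
#' deterministic alternative, keeping the count exact). If the spec carries
#' planted offsets, \code{\link{plantOffset}} is applied per helix. Byte
#' identical output is guaranteed for identical specs: one seed drives the
#' stream, with per-record substreams drawn up front so records are
#' independent of each other's length of RNG use.
#'
#' @param spec A \linkS4class{SyntheticSpec}.
#' @param familyId Family name for the result.
#' @param windows Named list of \linkS4class{HelixWindow} for the family
#'   (required when the spec plants offsets).
#' @return A \linkS4class{ProfileFamily}.
#' @examples
#' spec <- SyntheticSpec(randomSeedSequence(60, 7), nSequences = 5,
#'                       targetIdentity = 0.5, rngSeed = 42)
#' generateFamily(spec)
#' @export
generateFamily <- function(spec, familyId = "synthetic", windows = list()) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  seedChars <- strsplit(spec@seedSequence, "", fixed = TRUE)[[1]]
  len <- length(seedChars)
  n <- spec@nSequences
  m <- .calibratedRate(spec@targetIdentity)
  set.seed(spec@rngSeed)
  recordSeeds <- sample.int(.Machine$integer.max - 1L, n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    set.seed(recordSeeds[i])
    chars <- seedChars
    mut <- which(stats::runif(len) < m)
    for (p in mut) {
      pool <- AA_LETTERS[AA_LETTERS != chars[p]]
      chars[p] <- pool[sample.int(length(pool), 1L)]
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  cp <- spec@columnPlants
  if (nrow(cp)) {
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    for (r in seq_len(nrow(cp))) {
      col <- cp$column[r]; res <- cp$residue[r]; cnt <- cp$count[r]
      mat[seq_len(cnt), col] <- res
      if (cnt < n) {
        rest <- (cnt + 1L):n
        clash <- rest[mat[rest, col] == res]
        if (length(clash)) {
          alt <- if (seedChars[col] != res) seedChars[col]
                 else AA_LETTERS[AA_LETTERS != res][1L]
          mat[clash, col] <- alt
        }
      }
    }
    seqs <- apply(mat, 1L, paste, collapse = "")
  }
  names(seqs) <- sprintf("%s_%03d", familyId, seq_len(n))
  fam <- ProfileFamily(familyId, seqs, windows = windows)
  if (length(spec@plantedOffsets)) {
    for (h in names(spec@plantedOffsets))
      fam <- plantOffset(fam, h, spec@plantedOffsets[[h]],
                         rngSeed = spec@rngSeed + match(h, names(spec@plantedOffsets)))
  }
  fam
}

#' Displace a helix window's content by a known shift
#'
#' Builds a ground-truth query family: in every record the residues of the
#' helix window are moved \code{shift} positions to the right (negative =
#' left) of the configured window coordinates, and the vacated positions are
#' filled with uniform random residues. Records are padded at the C terminus
#' when the displaced window would overhang. After planting, reading the
#' window at offset \code{shift} recovers the original helix content, so a
#' correct voting run reports \code{shift} as the winner.
#'
#' @param family A \linkS4class{ProfileFamily} with a window for
#'   \code{helix}.
#' @param helix Helix id.
#' @param shift Integer displacement; must lie within \code{range} and must
#'   not push the window before position 1.
#' @param rngSeed Integer seed for the filler residues.
#' @param range An \linkS4class{OffsetRange} bounding legal shifts.
#' @return The displaced \linkS4class{ProfileFamily} (windows unchanged).
#' @export
plantOffset <- function(family, helix, shift, rngSeed = 1L,
                        range = OffsetRange()) {
  stopifnot(is(family, "ProfileFamily"))
  shift <- as.integer(shift)
  if (shift < range@minShift || shift > range@maxShift)
    stop(sprintf("shift %+d outside the offset range %d..%d",
                 shift, range@minShift, range@maxShift))
  w <- family@windows[[helix]]
  if (is.null(w))
    stop(sprintf("family '%s' defines no window for helix %s",
                 family@familyId, helix))
  if (w@start + shift < 1L)
    stop(sprintf("shift %+d pushes helix %s before the first residue",
                 shift, helix))
  if (shift == 0L) return(family)
  set.seed(rngSeed)
  recordSeeds <- sample.int(.Machine$integer.max - 1L,
                            length(family@sequences))
  seqs <- as.character(family@sequences)
  for (i in seq_along(seqs)) {
    set.seed(recordSeeds[i])
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    need <- w@end + shift
    if (need > length(chars))
      chars <- c(chars, sample(AA_LETTERS, need - length(chars),
                               replace = TRUE))
    content <- chars[w@start:w@end]
    vacated <- setdiff(w@start:w@end, (w@start:w@end) + shift)
    chars[vacated] <- sample(AA_LETTERS, length(vacated), replace = TRUE)
    chars[(w@start:w@end) + shift] <- content
    seqs[i] <- paste(chars, collapse = "")
  }
  sset <- Biostrings::AAStringSet(seqs)
  names(sset) <- names(family@sequences)
  initialize(family, sequences = sset)
}

#' Mean pairwise identity of a family
#'
#' Mean fraction of identical positions over all unordered record pairs of
#' an equal-length (e.g. seed-derived) family, as a percentage.
#'
#' @param family A \linkS4class{ProfileFamily} with equal-length sequences.
#' @return Percentage in [0, 100].
#' @export
meanPairwiseIdentity <- function(family) {
  seqs <- as.character(family@sequences)
  if (length(unique(nchar(seqs))) != 1L)
    stop("pairwise identity requires equal-length sequences")
  n <- length(seqs)
  if (n < 2L) return(100)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  total <- 0; count <- 0
  for (i in seq_len(n - 1L)) {
    eq <- sweep(mat[(i + 1L):n, , drop = FALSE], 2L, mat[i, ], `==`)
    total <- total + sum(rowMeans(eq))
    count <- count + (n - i)
  }
  total / count * 100
}

#' Write a synthetic family plus its ground-truth sidecar
#'
#' Emits the family as FASTA and a JSON sidecar recording the generating
#' spec, the planted truth and the realized pairwise identity, so test
#' harnesses can check recovery without re-deriving the truth.
#'
#' @param spec The \linkS4class{SyntheticSpec} used.
#' @param family The generated \linkS4class{ProfileFamily}.
#' @param fastaPath,truthPath Output paths.
#' @return \code{truthPath}, invisibly.
#' @export
writeSyntheticFixture <- function(spec, family, fastaPath, truthPath) {
  writeFastaFamily(family, fastaPath)
  truth <- list(
    family_id = family@familyId,
    n_sequences = spec@nSequences,
    sequence_length = nchar(spec@seedSequence),
    target_identity = spec@targetIdentity,
    realized_identity_pct = meanPairwiseIdentity(family),
    planted_offsets = as.list(spec@plantedOffsets),
    column_plants = spec@columnPlants,
    rng_seed = spec@rngSeed)
  jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA)
  invisible(truthPath)
}
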