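#' Construct a HelixWindow
#'
#' @param helixId One of A-H or IQ.
#' @param familyId Family the window belongs to.
#' @param start,end 1-based inclusive residue (or alignment-column) span.
#' @param coordinateSpace "sequence" (default) or "alignment-column".
#' @return A \linkS4class{HelixWindow}.
#' @examples
#' HelixWindow("A", "Adgb", 939, 951)   # androglobin helix A, Val939-Glu951
#' @export
HelixWindow <- function(helixId, familyId, start, end,
                        coordinateSpace = c("sequence", "alignment-column")) {
  new("HelixWindow", helixId = as.character(helixId),
      familyId = as.character(familyId),
      start = as.integer(start), end = as.integer(end),
      coordinateSpace = match.arg(coordinateSpace))
}

#' Construct a ProfileFamily
#'
#' @param familyId Family name.
#' @param sequences Named character vector or \code{AAStringSet}.
#' @param windows List of \linkS4class{HelixWindow} for this family.
#' @param isAligned TRUE when the sequences form an internal alignment.
#' @param recordWindows Optional per-record window override table
#'   (columns record_id, helix_id, start, end), used for unaligned families
#'   whose helices sit at different positions per record.
#' @return A \linkS4class{ProfileFamily}.
#' @examples
#' fam <- ProfileFamily("toy", c(s1 = "MVLSPADKTN", s2 = "MVHLTPEEKS"))
#' fam
#' @export
ProfileFamily <- function(familyId, sequences, windows = list(),
                          isAligned = FALSE, recordWindows = NULL) {
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  if (length(windows))
    names(windows) <- vapply(windows, function(w) w@helixId, character(1))
  if (is.null(recordWindows))
    recordWindows <- data.frame(record_id = character(),
                                helix_id = character(),
                                start = integer(), end = integer())
  new("ProfileFamily", familyId = familyId, sequences = sequences,
      windows = windows, isAligned = isAligned,
      recordWindows = recordWindows)
}

#' Read one sequence family from a FASTA file
#'
#' Parses a standard FASTA file (wrapped or unwrapped lines) into a
#' \linkS4class{ProfileFamily}, validating ids and the residue alphabet.
#' Record order is preserved. The record id is the header token up to the
#' first whitespace.
#'
#' @param path Path to the FASTA file.
#' @param familyId Family name; defaults to the file name without extension.
#' @param allowGaps Permit '-' characters (internally aligned family). When
#'   TRUE and all sequences have equal width, the family is marked aligned.
#' @param windows Optional list of \linkS4class{HelixWindow}.
#' @return A \linkS4class{ProfileFamily}.
#' @seealso \code{\link{writeFastaFamily}}
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "MVLS", ">s2", "MVHL"), fa)
#' readFastaFamily(fa, familyId = "toy")
#' @export
readFastaFamily <- function(path, familyId = NULL, allowGaps = FALSE,
                            windows = list()) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  lines <- .checkFastaShape(path)
  hdr <- which(startsWith(trimws(lines), ">"))
  ids <- sub("[[:space:]].*$", "", sub("^>", "", trimws(lines[hdr])))
  bounds <- c(hdr, length(lines) + 1L)
  residues <- vapply(seq_along(hdr), function(i) {
    body <- lines[seq.int(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    paste(gsub("[[:space:]]", "", body), collapse = "")
  }, character(1))
  names(residues) <- ids
  # validate residues on the raw text: FASTA readers that silently drop
  # unknown codes would otherwise corrupt the record
  for (i in seq_along(residues)) {
    ch <- strsplit(residues[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% ALPHABET_GAPPED)
    if (length(bad))
      stop(sprintf("illegal character '%s' in record '%s' at position %d",
                   ch[bad[1L]], ids[i], bad[1L]))
    if (!allowGaps) {
      gap <- which(ch == GAP_CHAR)
      if (length(gap))
        stop(sprintf("gap character in record '%s' at position %d; use allowGaps = TRUE for aligned families",
                     ids[i], gap[1L]))
    }
  }
  if (is.null(familyId))
    familyId <- sub("\\.[^.]*$", "", basename(path))
  seqs <- Biostrings::AAStringSet(residues)
  aligned <- allowGaps && length(unique(Biostrings::width(seqs))) == 1L
  ProfileFamily(familyId, seqs, windows = windows, isAligned = aligned)
}

# minimal structural check so malformed files fail with a line number;
# returns the file's lines for the caller to parse
.checkFastaShape <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty))
    stop("malformed FASTA at line 1: file is empty")
  if (!startsWith(trimws(lines[nonEmpty[1L]]), ">"))
    stop(sprintf("malformed FASTA at line %d: expected a '>' header", nonEmpty[1L]))
  headers <- which(startsWith(trimws(lines), ">"))
  follow <- headers + 1L
  dangling <- headers[follow > length(lines) |
                      (follow %in% headers) |
                      !nzchar(trimws(lines[pmin(follow, length(lines))]))]
  if (length(dangling))
    stop(sprintf("malformed FASTA at line %d: header without sequence", dangling[1L]))
  invisible(lines)
}

#' Write a family back to FASTA
#'
#' @param family A \linkS4class{ProfileFamily}.
#' @param path Output path.
#' @param width Line wrap width (0 = unwrapped).
#' @return \code{path}, invisibly.
#' @export
writeFastaFamily <- function(family, path, width = 60L) {
  stopifnot(is(family, "ProfileFamily"))
  Biostrings::writeXStringSet(family@sequences, filepath = path,
                              width = if (width > 0L) width else 20001L)
  invisible(path)
}

#' Load helix-window definitions from a TSV or YAML config
#'
#' The config lists, per family, the residue span of each globin helix.
#' TSV files need columns \code{family_id, helix_id, start, end} and
#' optionally \code{coordinate_space}; YAML files map family id ->
#' helix id -> list(start, end[, coordinate_space]). Missing helices are
#' permitted (helices C and D are typically placed manually, not voted on).
#'
#' @param path Path to the config file; format chosen by extension
#'   (.yml/.yaml vs anything else = TSV).
#' @return Named list: family id -> named list of \linkS4class{HelixWindow}.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("family_id\thelix_id\tstart\tend",
#'              "Adgb\tA\t939\t951",
#'              "Adgb\tH\t866\t877"), tsv)
#' cfg <- loadHelixConfig(tsv)
#' cfg$Adgb$A
#' @export
loadHelixConfig <- function(path) {
  if (!file.exists(path))
    stop("helix config not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    rows <- do.call(rbind, lapply(names(raw), function(fam) {
      do.call(rbind, lapply(names(raw[[fam]]), function(h) {
        e <- raw[[fam]][[h]]
        data.frame(family_id = fam, helix_id = h,
                   start = as.integer(e$start), end = as.integer(e$end),
                   coordinate_space = if (is.null(e$coordinate_space))
                     "sequence" else e$coordinate_space)
      }))
    }))
  } else {
    rows <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("family_id", "helix_id", "start", "end")
    if (!all(need %in% colnames(rows)))
      stop("helix config must have columns ", paste(need, collapse = ", "))
    if (is.null(rows$coordinate_space))
      rows$coordinate_space <- "sequence"
  }
  out <- list()
  for (i in seq_len(nrow(rows))) {
    w <- HelixWindow(rows$helix_id[i], rows$family_id[i],
                     rows$start[i], rows$end[i],
                     coordinateSpace = rows$coordinate_space[i])
    out[[rows$family_id[i]]][[rows$helix_id[i]]] <- w
  }
  out
}

#' Attach helix windows to a family
#'
#' @param family A \linkS4class{ProfileFamily}.
#' @param windows Named list of \linkS4class{HelixWindow} (e.g. one entry of
#'   the list returned by \code{\link{loadHelixConfig}}).
#' @return The family with windows set (validated).
#' @export
setHelixWindows <- function(family, windows) {
  names(windows) <- vapply(windows, function(w) w@helixId, character(1))
  initialize(family, windows = windows)
}

#' Extract a helix window at an integer shift
#'
#' Reads the window span displaced by \code{shift} residues: positions
#' \code{start+shift .. end+shift}. Positions that fall before the first or
#' after the last residue are returned as the out-of-range marker '*', so the
#' extracted string always has the full window length and scores at
#' different shifts stay commensurable. Gap characters of aligned families
#' are preserved.
#'
#' @param residues A residue string (or an object coercible to one, e.g. an
#'   \code{AAString}).
#' @param window A \linkS4class{HelixWindow}.
#' @param shift Integer displacement (0 = the configured span).
#' @return Character scalar of length \code{end - start + 1}, possibly
#'   containing '*' markers.
#' @examples
#' w <- HelixWindow("E", "toy", 2, 5)
#' extractWindow("MVLSPADK", w, 0)    # "VLSP"
#' extractWindow("MVLSPADK", w, -2)   # "**MV": slid off the N terminus
#' @export
extractWindow <- function(residues, window, shift = 0L) {
  residues <- as.character(residues)
  stopifnot(length(residues) == 1L, is(window, "HelixWindow"))
  shift <- as.integer(shift)
  n <- nchar(residues)
  pos <- (window@start:window@end) + shift
  chars <- rep(OOR_MARKER, length(pos))
  ok <- pos >= 1L & pos <= n
  if (any(ok))
    chars[ok] <- strsplit(substr(residues, min(pos[ok]), max(pos[ok])),
                          "", fixed = TRUE)[[1]]
  paste(chars, collapse = "")
}

# Effective window for one record: the family window unless a per-record
# override exists; returns c(start, end) in that record's coordinates.
.effectiveSpan <- function(family, window, recordId) {
  rw <- family@recordWindows
  if (nrow(rw)) {
    hit <- which(rw$record_id == recordId & rw$helix_id == window@helixId)
    if (length(hit)) {
      s <- as.integer(rw$start[hit[1L]]); e <- as.integer(rw$end[hit[1L]])
      if (e - s != window@end - window@start)
        stop(sprintf("record window override for '%s' helix %s must match the family window length",
                     recordId, window@helixId))
      return(c(s, e))
    }
  }
  c(window@start, window@end)
}

# Per-record window start positions for a whole family (vector of length n).
.windowStarts <- function(family, helix) {
  w <- family@windows[[helix]]
  if (is.null(w))
    stop(sprintf("family '%s' defines no window for helix %s",
                 family@familyId, helix))
  ids <- names(family@sequences)
  vapply(ids, function(id) .effectiveSpan(family, w, id)[1L], integer(1))
}

.windowLength <- function(family, helix) {
  w <- family@windows[[helix]]
  if (is.null(w))
    stop(sprintf("family '%s' defines no window for helix %s",
                 family@familyId, helix))
  w@end - w@start + 1L
}
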