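#' Construct a PermutedLayout
#'
#' @param canonicalOrder Helix order of the templates (subset of A..H, in
#'   A..H order).
#' @param queryOrder Order in which the query expresses those helices; may
#'   include one inserted non-helix segment "IQ".
#' @param chainBreakAfter Segment of \code{queryOrder} after which the query
#'   chain is discontiguous, or NA for a contiguous query.
#' @param annotations data.frame(glyph, family_id, position) of key-residue
#'   marks ('a' CD1 aromatic, 'b' proximal His, 'c' distal His/Gln,
#'   '#' disulfide cysteines).
#' @return A \linkS4class{PermutedLayout}.
#' @examples
#' adgbLayout()
#' @export
PermutedLayout <- function(canonicalOrder, queryOrder,
                           chainBreakAfter = NA_character_,
                           annotations = NULL) {
  if (is.null(annotations))
    annotations <- data.frame(glyph = character(), family_id = character(),
                              position = integer())
  new("PermutedLayout", canonicalOrder = as.character(canonicalOrder),
      queryOrder = as.character(queryOrder),
      chainBreakAfter = as.character(chainBreakAfter),
      annotations = annotations)
}

#' The androglobin layout
#'
#' Androglobin expresses globin helices D-H on the N-terminal side of its
#' globin domain, then, after the chain break and the inserted IQ
#' calmodulin-binding segment, helices A-C.
#'
#' @param annotations Optional annotation data.frame (see
#'   \code{\link{PermutedLayout}}).
#' @return A \linkS4class{PermutedLayout}.
#' @export
adgbLayout <- function(annotations = NULL) {
  PermutedLayout(canonicalOrder = CANONICAL_HELICES,
                 queryOrder = c("D", "E", "F", "G", "H", "IQ", "A", "B", "C"),
                 chainBreakAfter = "H", annotations = annotations)
}

#' Read key-residue annotations from YAML
#'
#' The file maps each glyph to a family id and one or more 1-based residue
#' positions, e.g. \code{"#": {family: Adgb, position: [787, 978]}}.
#'
#' @param path YAML file path.
#' @return data.frame(glyph, family_id, position).
#' @export
readAnnotations <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(rbind, lapply(names(raw), function(g) {
    e <- raw[[g]]
    data.frame(glyph = g, family_id = e$family,
               position = as.integer(unlist(e$position)))
  }))
}

# split queryOrder into the two chain segments (everything is segment 1 when
# there is no break)
.querySegments <- function(layout) {
  if (is.na(layout@chainBreakAfter))
    return(stats::setNames(rep(1L, length(layout@queryOrder)),
                           layout@queryOrder))
  cut <- match(layout@chainBreakAfter, layout@queryOrder)
  seg <- ifelse(seq_along(layout@queryOrder) <= cut, 1L, 2L)
  stats::setNames(seg, layout@queryOrder)
}

#' Render the circularly permuted multi-family alignment
#'
#' Lays out one representative sequence per template family plus the query
#' in canonical helix order (A..H): helix windows in uppercase blocks, each
#' family's own inter-helix residues in lowercase between them, the query's
#' windows read at their winning offsets, '/' where the query chain breaks,
#' and an annotation line carrying the key-residue glyphs. Window positions
#' a query offset pushes outside the sequence render as '-'. An inserted
#' non-helix segment (the IQ domain) is not part of the canonical block
#' layout; its span is reported on a trailing note line.
#'
#' @param templates List of \linkS4class{ProfileFamily} template families.
#' @param query The query \linkS4class{ProfileFamily}.
#' @param consensus Named list helix id -> \linkS4class{ConsensusResult}
#'   (or plain integer offsets) giving each voted helix's offset.
#' @param layout A \linkS4class{PermutedLayout}.
#' @param manualOffsets Named integer vector of offsets for helices without
#'   a consensus (the non-voted helices C and D). A canonical helix with
#'   neither a consensus nor a manual offset is a configuration error.
#' @param representatives Optional named character vector family id ->
#'   record id; default is each family's first record.
#' @return Object of class \code{PermutedAlignment}: list with \code{lines}
#'   (named character, one per family), \code{marker} (the glyph line) and
#'   \code{notes}; see \code{\link{writePermutedAlignment}}.
#' @export
assemblePermutedAlignment <- function(templates, query, consensus, layout,
                                      manualOffsets = integer(),
                                      representatives = NULL) {
  stopifnot(is(layout, "PermutedLayout"), is(query, "ProfileFamily"))
  if (is(templates, "ProfileFamily")) templates <- list(templates)
  helices <- layout@canonicalOrder
  qOffsets <- vapply(helices, function(h) {
    if (!is.null(consensus[[h]])) {
      v <- consensus[[h]]
      if (is(v, "ConsensusResult")) v@winningOffset else as.integer(v)
    } else if (h %in% names(manualOffsets)) {
      as.integer(manualOffsets[[h]])
    } else {
      stop(sprintf("helix %s has neither a consensus nor a manual offset", h))
    }
  }, integer(1))

  families <- c(templates, list(query))
  ids <- vapply(families, familyId, character(1))
  reps <- vapply(families, function(f) {
    id <- if (!is.null(representatives) && familyId(f) %in% names(representatives))
      representatives[[familyId(f)]] else names(f@sequences)[1L]
    if (!id %in% names(f@sequences))
      stop(sprintf("representative '%s' not found in family '%s'", id, familyId(f)))
    as.character(f@sequences[[id]])
  }, character(1))
  isQuery <- c(rep(FALSE, length(templates)), TRUE)
  seg <- .querySegments(layout)
  qorder <- layout@queryOrder

  # per family: parallel character and residue-index tracks, built block by
  # block; pads and '/' carry index NA
  chars <- rep(list(character()), length(families))
  resIdx <- rep(list(integer()), length(families))
  appendBlock <- function(k, txt, idx) {
    chars[[k]] <<- c(chars[[k]], txt)
    resIdx[[k]] <<- c(resIdx[[k]], idx)
  }
  spanChars <- function(residues, from, to, lower = FALSE) {
    if (to < from) return(list(txt = character(), idx = integer()))
    n <- nchar(residues)
    pos <- from:to
    txt <- rep("-", length(pos)); idx <- rep(NA_integer_, length(pos))
    ok <- pos >= 1L & pos <= n
    if (any(ok)) {
      s <- strsplit(substr(residues, min(pos[ok]), max(pos[ok])), "")[[1]]
      txt[ok] <- if (lower) tolower(s) else s
      idx[ok] <- pos[ok]
    }
    list(txt = txt, idx = idx)
  }

  for (hi in seq_along(helices)) {
    h <- helices[hi]
    # window block
    blocks <- lapply(seq_along(families), function(k) {
      f <- families[[k]]
      w <- f@windows[[h]]
      if (is.null(w)) return(list(txt = character(), idx = integer()))
      off <- if (isQuery[k]) qOffsets[[h]] else 0L
      spanChars(reps[k], w@start + off, w@end + off)
    })
    bw <- max(vapply(blocks, function(b) length(b$txt), integer(1)))
    for (k in seq_along(families)) {
      b <- blocks[[k]]
      pad <- bw - length(b$txt)
      appendBlock(k, c(b$txt, rep("-", pad)), c(b$idx, rep(NA_integer_, pad)))
    }
    if (hi == length(helices)) break
    # linker block to the next canonical helix
    h2 <- helices[hi + 1L]
    linkers <- lapply(seq_along(families), function(k) {
      f <- families[[k]]
      w1 <- f@windows[[h]]; w2 <- f@windows[[h2]]
      if (is.null(w1) || is.null(w2))
        return(list(txt = character(), idx = integer()))
      if (isQuery[k]) {
        if (!is.na(seg[h]) && !is.na(seg[h2]) && seg[h] != seg[h2])
          return(list(txt = "/", idx = NA_integer_))
        p1 <- match(h, qorder); p2 <- match(h2, qorder)
        if (is.na(p1) || is.na(p2) || abs(p1 - p2) != 1L)
          return(list(txt = character(), idx = integer()))
        spanChars(reps[k], w1@end + qOffsets[[h]] + 1L,
                  w2@start + qOffsets[[h2]] - 1L, lower = TRUE)
      } else {
        spanChars(reps[k], w1@end + 1L, w2@start - 1L, lower = TRUE)
      }
    })
    lw <- max(vapply(linkers, function(b) length(b$txt), integer(1)))
    for (k in seq_along(families)) {
      b <- linkers[[k]]
      pad <- lw - length(b$txt)
      appendBlock(k, c(b$txt, rep("-", pad)), c(b$idx, rep(NA_integer_, pad)))
    }
  }

  width <- length(chars[[1L]])
  lines <- stats::setNames(vapply(chars, paste, character(1), collapse = ""),
                           ids)

  # annotation marker line: place each glyph at the display column holding
  # that family's residue
  marker <- rep(" ", width)
  ann <- layout@annotations
  for (r in seq_len(nrow(ann))) {
    k <- match(ann$family_id[r], ids)
    if (is.na(k)) next
    col <- which(resIdx[[k]] == ann$position[r])
    if (length(col)) marker[col[1L]] <- ann$glyph[r]
  }

  notes <- character()
  if ("IQ" %in% qorder) {
    iq <- query@windows[["IQ"]]
    if (!is.null(iq))
      notes <- sprintf("%s IQ segment: residues %d-%d (inserted between helices %s and %s)",
                       familyId(query), iq@start, iq@end,
                       qorder[match("IQ", qorder) - 1L],
                       qorder[match("IQ", qorder) + 1L])
  }

  structure(list(lines = lines, marker = paste(marker, collapse = ""),
                 notes = notes, offsets = qOffsets),
            class = "PermutedAlignment")
}

#' @export
print.PermutedAlignment <- function(x, ...) {
  nm <- format(c("", names(x$lines)))
  cat(nm[1L], " ", x$marker, "\n", sep = "")
  for (i in seq_along(x$lines))
    cat(nm[i + 1L], " ", x$lines[[i]], "\n", sep = "")
  for (n in x$notes) cat(n, "\n")
  invisible(x)
}

#' Write a rendered alignment as text and aligned FASTA
#'
#' The text file carries the marker line, one line per family and any notes;
#' the FASTA file holds the equal-length display lines (including '/' and
#' lowercase linkers) and round-trips through any aligned-FASTA reader.
#'
#' @param x A \code{PermutedAlignment} from
#'   \code{\link{assemblePermutedAlignment}}.
#' @param textPath,fastaPath Output paths (either may be NULL to skip).
#' @return \code{x}, invisibly.
#' @export
writePermutedAlignment <- function(x, textPath = NULL, fastaPath = NULL) {
  stopifnot(inherits(x, "PermutedAlignment"))
  if (!is.null(textPath)) {
    con <- file(textPath, "w"); on.exit(close(con))
    nm <- format(c("", names(x$lines)))
    writeLines(paste0(nm[1L], " ", x$marker), con)
    for (i in seq_along(x$lines))
      writeLines(paste0(nm[i + 1L], " ", x$lines[[i]]), con)
    writeLines(x$notes, con)
  }
  if (!is.null(fastaPath)) {
    sset <- Biostrings::BStringSet(x$lines)
    Biostrings::writeXStringSet(sset, fastaPath, width = 20001L)
  }
  invisible(x)
}
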