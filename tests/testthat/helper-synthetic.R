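# Shared builders and independent oracles for the test suite. The oracles
# deliberately use the slow, obvious formulation (extractWindow +
# scorePairAtOffset in loops) so they stay independent of the vectorized
# voting engine they check.

AAS <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

randomProtein <- function(len) paste(sample(AAS, len, replace = TRUE), collapse = "")

# family of n random-ish sequences with one helix window; flanks are real
# random residues
randomFamily <- function(famId, n, len = 60, winStart = 20, winLen = 10,
                         helix = "A") {
  seqs <- vapply(seq_len(n), function(i) randomProtein(len), character(1))
  names(seqs) <- paste0(famId, "_", seq_len(n))
  ProfileFamily(famId, seqs,
                windows = list(HelixWindow(helix, famId, winStart,
                                           winStart + winLen - 1L)))
}

# family whose sequences are a mutated helix core embedded in neutral 'X'
# padding; BLOSUM62 scores X constantly, so no slide can leave the pad
paddedFamily <- function(famId, n, core, mutRate = 0.4, pad = 30L,
                         helix = "A") {
  L <- nchar(core)
  coreChars <- strsplit(core, "")[[1]]
  seqs <- vapply(seq_len(n), function(i) {
    ch <- coreChars
    for (p in which(runif(L) < mutRate))
      ch[p] <- sample(setdiff(AAS, ch[p]), 1L)
    paste0(strrep("X", pad), paste(ch, collapse = ""), strrep("X", pad))
  }, character(1))
  names(seqs) <- paste0(famId, "_", seq_len(n))
  ProfileFamily(famId, seqs,
                windows = list(HelixWindow(helix, famId, pad + 1L, pad + L)))
}

# template/query pair derived from one seed sequence at a given pairwise
# identity, with the query's helix content displaced by `shift`
plantedPair <- function(seedSeq, n, identity, shift, helix = "A",
                        winStart = 40L, winLen = 13L, seeds = c(1L, 2L)) {
  win <- function(fam) list(HelixWindow(helix, fam, winStart,
                                        winStart + winLen - 1L))
  tf <- generateFamily(SyntheticSpec(seedSeq, n, identity, rngSeed = seeds[1]),
                       "tmpl", windows = win("tmpl"))
  qf <- generateFamily(SyntheticSpec(seedSeq, n, identity, rngSeed = seeds[2]),
                       "qry", windows = win("qry"))
  if (shift != 0L)
    qf <- plantOffset(qf, helix, shift, rngSeed = seeds[2] + 1000L)
  list(template = tf, query = qf)
}

# naive vote casting: pair x offset x extractWindow/scorePairAtOffset loops
naiveCastVotes <- function(template, query, helix, range, direction, scheme) {
  shifts <- offsetAxis(range)
  wT <- helixWindows(template)[[helix]]
  wQ <- helixWindows(query)[[helix]]
  tSeqs <- as.character(sequences(template))
  qSeqs <- as.character(sequences(query))
  votes <- setNames(numeric(length(shifts)), shifts)
  for (ts in tSeqs) {
    for (qs in qSeqs) {
      sc <- vapply(shifts, function(s) {
        if (direction == "query_moved")
          scorePairAtOffset(extractWindow(ts, wT, 0L),
                            extractWindow(qs, wQ, s), scheme)
        else
          scorePairAtOffset(extractWindow(ts, wT, s),
                            extractWindow(qs, wQ, 0L), scheme)
      }, numeric(1))
      best <- which(sc >= max(sc) - 1e-9)
      votes[best] <- votes[best] + 1 / length(best)
    }
  }
  votes
}

# brute-force mean cross-family percent identity at an offset
naivePercentIdentity <- function(template, query, helix, offset) {
  wT <- helixWindows(template)[[helix]]
  wQ <- helixWindows(query)[[helix]]
  L <- wT@end - wT@start + 1L
  vals <- c()
  for (ts in as.character(sequences(template))) {
    for (qs in as.character(sequences(query))) {
      a <- strsplit(extractWindow(ts, wT, 0L), "")[[1]]
      b <- strsplit(extractWindow(qs, wQ, offset), "")[[1]]
      ident <- a == b & !a %in% c("*", "-") & !b %in% c("*", "-")
      vals <- c(vals, sum(ident) / L)
    }
  }
  mean(vals) * 100
}

# brute-force all-vs-all mean pairwise identity (percent)
naivePairwiseIdentity <- function(family) {
  seqs <- as.character(sequences(family))
  n <- length(seqs)
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1)) {
    a <- strsplit(seqs[i], "")[[1]]
    for (j in (i + 1):n) {
      b <- strsplit(seqs[j], "")[[1]]
      tot <- tot + mean(a == b); cnt <- cnt + 1
    }
  }
  tot / cnt * 100
}
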