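sc <- scoringScheme()

test_that("window scores sum substitution-matrix entries with edge rules", {
  expect_identical(scorePairAtOffset("AAA", "AAA", sc), 12)  # 3 x diag(A)
  expect_identical(scorePairAtOffset("AA*", "AAA", sc), 2 * 4 - 4)
  expect_identical(scorePairAtOffset("A-A", "AAA", sc), 8)   # gap scores 0
  expect_error(scorePairAtOffset("AA", "AAA", sc), "length")
  # a window against itself dominates any other window of equal length
  set.seed(3)
  for (i in 1:10) {
    a <- randomProtein(12); b <- randomProtein(12)
    expect_gte(scorePairAtOffset(a, a, sc), scorePairAtOffset(a, b, sc))
  }
})

test_that("scoring scheme rejects asymmetric matrices and defaults sensibly", {
  m <- matrix(0, 20, 20, dimnames = list(AAS, AAS))
  m[1, 2] <- 5
  expect_error(scoringScheme(m), "symmetric")
  expect_equal(scoringScheme()@outOfRangeScore, -4)  # BLOSUM62 minimum
})

test_that("a self-comparison votes entirely for offset zero", {
  set.seed(21)
  fam <- randomFamily("self", 1, len = 70, winStart = 30, winLen = 10)
  v <- castVotes(fam, fam, "A", OffsetRange(-10, 10), "query_moved", sc)
  expect_identical(sum(v), attr(v, "nPairs") + 0)
  expect_identical(as.numeric(v["0"]), 1)
})

test_that("tied best offsets split the vote fractionally", {
  # one query strictly prefers +4, the other carries the helix content at
  # both 0 and +4 and ties; expected votes {0: 0.5, +4: 1.5}
  core <- "ACDE"
  pad <- strrep("X", 20)
  tmpl <- ProfileFamily("t", c(t1 = paste0(pad, core, pad)),
                        windows = list(HelixWindow("A", "t", 21, 24)))
  qry <- ProfileFamily("q",
    c(q1 = paste0(pad, "XXXX", core, strrep("X", 16)),   # core only at +4
      q2 = paste0(pad, core, core, strrep("X", 16))),    # core at 0 and +4
    windows = list(HelixWindow("A", "q", 21, 24)))
  v <- castVotes(tmpl, qry, "A", OffsetRange(-4, 6), "query_moved", sc)
  # verify the construction with the naive oracle, then the tie rule
  nv <- naiveCastVotes(tmpl, qry, "A", OffsetRange(-4, 6), "query_moved", sc)
  expect_equal(as.numeric(v), as.numeric(nv))
  expect_identical(as.numeric(v["4"]), 1.5)
  expect_identical(as.numeric(v["0"]), 0.5)
  expect_identical(sum(v), 2)
})

test_that("vectorized voting matches the naive pair x offset x position oracle", {
  set.seed(42)
  for (rep in 1:6) {
    tf <- randomFamily("t", 4, len = 55, winStart = sample(15:25, 1), winLen = 8)
    qf <- randomFamily("q", 4, len = 55, winStart = sample(15:25, 1), winLen = 8)
    for (dir in c("query_moved", "template_moved")) {
      fast <- castVotes(tf, qf, "A", OffsetRange(-12, 12), dir, sc)
      slow <- naiveCastVotes(tf, qf, "A", OffsetRange(-12, 12), dir, sc)
      expect_equal(as.numeric(fast), as.numeric(slow), tolerance = 1e-12)
    }
  }
})

test_that("tally re-indexes the template-moved direction by negation", {
  set.seed(5)
  tf <- randomFamily("t", 3, len = 60, winStart = 25, winLen = 10)
  qf <- randomFamily("q", 3, len = 60, winStart = 25, winLen = 10)
  rng <- OffsetRange(-8, 8)
  tab <- tally(tf, qf, "A", rng, sc)
  vq <- castVotes(tf, qf, "A", rng, "query_moved", sc)
  vt <- castVotes(tf, qf, "A", rng, "template_moved", sc)
  expect_equal(as.numeric(votesQueryMoved(tab)), as.numeric(vq))
  expect_equal(as.numeric(votesTemplateMoved(tab)), rev(as.numeric(vt)))
  expect_equal(as.numeric(meanVotes(tab)),
               (as.numeric(vq) + rev(as.numeric(vt))) / 2)
  expect_identical(nPairs(tab), 9L)
})

test_that("vote conservation and unit normalization hold across fuzzed inputs", {
  set.seed(99)
  for (i in 1:40) {
    n1 <- sample(1:4, 1); n2 <- sample(1:4, 1)
    len <- sample(30:45, 1)
    ws <- sample(8:(len - 20), 1)
    tf <- randomFamily("t", n1, len = len, winStart = ws, winLen = 6)
    qf <- randomFamily("q", n2, len = len, winStart = ws, winLen = 6)
    r <- OffsetRange(-sample(3:8, 1), sample(3:8, 1))
    tab <- tally(tf, qf, "A", r, sc)
    expect_equal(sum(votesQueryMoved(tab)), n1 * n2, tolerance = 1e-9)
    expect_equal(sum(votesTemplateMoved(tab)), n1 * n2, tolerance = 1e-9)
    expect_equal(max(normalizedVotes(tab)), 1)
  }
})

test_that("normalization scales by the maximum and keeps zero vectors zero", {
  expect_equal(normalizeVotes(c(10, 5, 0)), c(1, 0.5, 0))
  expect_equal(normalizeVotes(c(0, 0)), c(0, 0))
  expect_error(normalizeVotes(c(-1, 2)), "non-negative")
  expect_equal(round(normalizeVotes(c(2219, 10332.5)), 4), c(0.2148, 1))
})

test_that("report rounding is half-down", {
  expect_identical(roundHalfDown(c(10332.5, 2219, 0.4, 2.5, 2.51)),
                   c(10332, 2219, 0, 2, 3))
})

test_that("a planted +4 displacement wins the tally at +4", {
  pair <- plantedPair(randomSeedSequence(90, 31), n = 5, identity = 0.6,
                      shift = 4L, seeds = c(11L, 12L))
  tab <- tally(pair$template, pair$query, "A", OffsetRange(-25, 25), sc)
  expect_identical(winningOffset(tab), 4L)
  # and the two directions agree on the winner after re-indexing
  expect_identical(which.max(votesQueryMoved(tab)),
                   which.max(votesTemplateMoved(tab)))
})

test_that("mirror identity: neutral padding makes the directions coincide exactly", {
  set.seed(17)
  core <- randomProtein(12)
  fa <- paddedFamily("a", 6, core, mutRate = 0.5, pad = 30L)
  fb <- paddedFamily("b", 6, core, mutRate = 0.5, pad = 30L)
  vq <- castVotes(fa, fb, "A", OffsetRange(-25, 25), "query_moved", sc)
  vt <- castVotes(fa, fb, "A", OffsetRange(-25, 25), "template_moved", sc)
  expect_identical(as.numeric(vq), rev(as.numeric(vt)))
  # whole-sequence windows (every off-window read is out of range) too
  set.seed(18)
  mk <- function(id) {
    seqs <- vapply(1:4, function(i) randomProtein(14), character(1))
    names(seqs) <- paste0(id, 1:4)
    ProfileFamily(id, seqs, windows = list(HelixWindow("A", id, 1, 14)))
  }
  fc <- mk("c"); fd <- mk("d")
  vq2 <- castVotes(fc, fd, "A", OffsetRange(-10, 10), "query_moved", sc)
  vt2 <- castVotes(fc, fd, "A", OffsetRange(-10, 10), "template_moved", sc)
  expect_identical(as.numeric(vq2), rev(as.numeric(vt2)))
})

test_that("vote tables export to TSV with both directions and normalization", {
  set.seed(2)
  tf <- randomFamily("t", 2, len = 50, winStart = 20, winLen = 8)
  qf <- randomFamily("q", 2, len = 50, winStart = 20, winLen = 8)
  tab <- tally(tf, qf, "A", OffsetRange(-5, 5), sc)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  exportVoteTable(tab, tsv)
  df <- read.delim(tsv)
  expect_identical(nrow(df), 11L)
  expect_identical(df$offset, -5:5)
  expect_equal(df$mean, (df$votes_query_moved + df$votes_template_moved) / 2)
})

test_that("voting errors carry context", {
  tf <- randomFamily("t", 2, winLen = 8)
  qf <- randomFamily("q", 2, winLen = 9)
  expect_error(tally(tf, qf, "A"), "differ in length")
  expect_error(tally(tf, qf, "B"), "no window for helix B")
})
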