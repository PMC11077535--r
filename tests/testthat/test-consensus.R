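sc <- scoringScheme()

# VoteTable with prescribed normalized shape: direction votes are scaled so
# each sums to 10 while the mean keeps the requested profile
shapedTable <- function(templateId, shape, offsets = seq_along(shape) - 1L) {
  v <- shape / sum(shape) * 10
  VoteTable(templateId, "q", "A", as.integer(offsets), v, v)
}

test_that("consensus multiplies normalized vote vectors entrywise", {
  t1 <- shapedTable("t1", c(1.0, 0.5), offsets = c(0L, 4L))
  t2 <- shapedTable("t2", c(1.0, 0.2), offsets = c(0L, 4L))
  cons <- consensusOffsets(list(t1, t2))
  expect_equal(as.numeric(productVector(cons)), c(1.0, 0.1))
  expect_identical(winningOffset(cons), 0L)
  expect_identical(runnerUpOffset(cons), 4L)
  expect_equal(dominanceRatio(cons), 10)
  # product never exceeds any factor
  expect_true(all(productVector(cons) <= normalizedVotes(t1) + 1e-12))
  expect_true(all(productVector(cons) <= normalizedVotes(t2) + 1e-12))
})

test_that("a single template's consensus is its own normalized vector", {
  t1 <- shapedTable("t1", c(0.3, 1.0, 0.6), offsets = -1:1)
  cons <- consensusOffsets(list(t1))
  expect_equal(as.numeric(productVector(cons)),
               as.numeric(normalizedVotes(t1)))
})

test_that("five templates preferring the same offset give that winner", {
  tabs <- lapply(paste0("t", 1:5), shapedTable,
                 shape = c(0.4, 1.0, 0.3), offsets = c(-2L, 0L, 4L))
  cons <- consensusOffsets(tabs)
  expect_identical(winningOffset(cons), 0L)
  expect_length(templatesUsed(cons), 5L)
})

test_that("consensus ties resolve toward the smallest |offset|, negative first", {
  flat <- shapedTable("t1", c(1, 1, 1, 1), offsets = c(-3L, -1L, 1L, 4L))
  expect_identical(winningOffset(consensusOffsets(list(flat))), -1L)
  flat2 <- shapedTable("t1", c(1, 1), offsets = c(-2L, 2L))
  expect_identical(winningOffset(consensusOffsets(list(flat2))), -2L)
})

test_that("zero-vote templates are dropped with a warning, mismatches error", {
  t1 <- shapedTable("t1", c(1, 0.5), offsets = c(0L, 4L))
  # a tally can never produce an all-zero table (votes are conserved), so
  # forge one through direct slot assignment to exercise the defensive path
  zero <- shapedTable("dead", c(1, 1), offsets = c(0L, 4L))
  zero@votesQueryMoved <- c(0, 0)
  zero@votesTemplateMoved <- c(0, 0)
  zero@meanVotes <- c(0, 0)
  zero@normalized <- c(0, 0)
  expect_warning(cons <- consensusOffsets(list(t1, zero)), "dead")
  expect_identical(templatesUsed(cons), "t1")
  t3 <- shapedTable("t3", c(1, 0.5), offsets = c(0L, 2L))
  expect_error(consensusOffsets(list(t1, t3)), "offset axis")
  expect_error(consensusOffsets(list()), "at least one")
})

test_that("consensus sharpens dominance over the best single template", {
  # when every template prefers the planted offset, multiplying the vote
  # vectors can only widen the winner/runner-up gap
  set.seed(71)
  sharper <- 0L
  for (rep in 1:25) {
    seedSeq <- randomSeedSequence(90, 500 + rep)
    tabs <- lapply(1:3, function(k) {
      pair <- plantedPair(seedSeq, n = 8, identity = 0.45, shift = 2L,
                          seeds = c(1000L + 10L * rep + k, 2000L + rep))
      tally(pair$template, pair$query, "A", OffsetRange(-10, 10), sc)
    })
    winners <- vapply(tabs, winningOffset, integer(1))
    if (!all(winners == 2L)) next
    doms <- vapply(tabs, function(t) {
      w <- sort(meanVotes(t), decreasing = TRUE)
      w[1] / max(w[2], 1e-12)
    }, numeric(1))
    cons <- consensusOffsets(tabs)
    expect_identical(winningOffset(cons), 2L)
    if (dominanceRatio(cons) >= max(doms) - 1e-9) sharper <- sharper + 1L
    expect_gte(dominanceRatio(cons), max(doms) * 0.999)
  }
})

test_that("percent identity matches hand and brute-force computation", {
  t1 <- ProfileFamily("t", c(a = "GACDEFG"),
                      windows = list(HelixWindow("B", "t", 2, 6)))
  q1 <- ProfileFamily("q", c(b = "GACDQFG"),
                      windows = list(HelixWindow("B", "q", 2, 6)))
  expect_equal(percentIdentity(t1, q1, "B", 0), 80)          # 4 of 5
  expect_equal(percentIdentity(t1, t1, "B", 0), 100)         # self identity
  set.seed(13)
  tf <- randomFamily("t", 3, len = 50, winStart = 20, winLen = 9)
  qf <- randomFamily("q", 3, len = 50, winStart = 20, winLen = 9)
  for (off in c(-3L, 0L, 5L))
    expect_equal(percentIdentity(tf, qf, "A", off),
                 naivePercentIdentity(tf, qf, "A", off))
})

test_that("identity peaks at the planted offset", {
  set.seed(29)
  wins <- 0L
  for (rep in 1:20) {
    pair <- plantedPair(randomSeedSequence(90, 600 + rep), n = 6,
                        identity = 0.4, shift = 3L,
                        seeds = c(3000L + rep, 4000L + rep))
    offs <- -6:6
    pid <- vapply(offs, function(o)
      percentIdentity(pair$template, pair$query, "A", o), numeric(1))
    if (offs[which.max(pid)] == 3L) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("mean helical identity is the unweighted mean", {
  expect_equal(meanHelixIdentity(c(A = 10, B = 20)), 15)
  expect_equal(meanHelixIdentity(rep(17.8, 6)), 17.8)
  set.seed(1); v <- runif(6, 5, 30)
  expect_equal(meanHelixIdentity(setNames(v, c("A","B","E","F","G","H"))),
               sum(v) / 6)
  expect_error(meanHelixIdentity(numeric()), "at least one")
})

test_that("column frequencies count non-gap residues and report gaps apart", {
  fam <- ProfileFamily("toy", c(a = "AYG", b = "AYG", c = "AFG", d = "AYG"),
                       isAligned = TRUE)
  f <- columnFrequencies(fam, 2)
  expect_equal(as.numeric(f[c("Y", "F")]), c(0.75, 0.25))
  expect_equal(sum(f), 1)
  gappy <- ProfileFamily("g", c(a = "A-G", b = "A-G"), isAligned = TRUE)
  f2 <- columnFrequencies(gappy, 2)
  expect_length(f2, 0L)
  expect_equal(attr(f2, "gapFraction"), 1)
  expect_error(columnFrequencies(gappy, 9), "outside")
  expect_error(columnFrequencies(
    ProfileFamily("u", c(a = "AC", b = "ACD")), 1), "aligned")
  # fractions sum to 1 on every non-degenerate column of a fuzzed alignment
  set.seed(8)
  seqs <- vapply(1:12, function(i) randomProtein(20), character(1))
  names(seqs) <- paste0("s", 1:12)
  afam <- ProfileFamily("f", seqs, isAligned = TRUE)
  for (col in 1:20)
    expect_equal(sum(columnFrequencies(afam, col)), 1)
})
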