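---
title: "Helix profile alignment by offset voting: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helix profile alignment by offset voting: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixvote)
```

## The problem

Remote homologs below roughly 25% pairwise identity — the *twilight zone* —
defeat standard pairwise aligners: the best-scoring gapped alignment of two
individual sequences is often wrong, and a single misplaced gap shifts every
downstream structural assignment. The androglobin (Adgb) globin domain is a
hard instance: it is circularly permuted (helices D–H precede helices A–C in
the chain, with an inserted IQ calmodulin-binding segment between H and A),
and its identity to classical globins sits well inside the twilight zone.

`helixvote` sidesteps per-sequence alignment. It assumes the *structural
anatomy* of both families is known — each family has annotated helix windows
(the globin helices A–H) — and reduces alignment to one integer per helix:
the offset of the query family's helix window relative to the templates'.

## The model

For a template family $T$ with $|T|$ sequences and a query family $Q$ with
$|Q|$ sequences, fix a helix $h$ with equal-length windows configured in
both families. For every ordered cross-family pair $(t, q)$ and every offset
$s$ in a symmetric range ($-25..+25$ by default), compute the ungapped
window score

$$ W_{tq}(s) \;=\; \sum_{k=1}^{L} M\big(t[a{+}k{-}1],\; q[b{+}s{+}k{-}1]\big), $$

where $M$ is a substitution matrix (BLOSUM62 by default), $L$ the window
length, and $a, b$ the configured window starts. Each pair casts **one
vote** for its argmax offset; if $k$ offsets tie for the maximum, each
receives $1/k$ of the vote. Votes therefore conserve exactly: every
direction's vote vector sums to $|T| \times |Q|$.

The window is slid in both directions — moving the query window
(`query_moved`) and moving the template window (`template_moved`) — and the
template-moved vector is re-indexed by negating its offsets so both
histograms live on one axis ("how far is the query's window displaced"). The
reported vote count per offset is the mean of the two re-indexed directions.

Per template, the mean vote vector is normalized by its maximum to $[0,1]$.
The **consensus** across templates is the entrywise *product* of the
normalized vectors: an offset keeps a high product only if every template
family independently supports it, so disagreement between templates
suppresses spurious winners multiplicatively rather than additively.

```{r worked, eval = FALSE}
# the published alpha-Hb (235 records) vs Adgb (73 records) helix-A counts:
# 17155 pairs; offset 0 drew 10664 query-moved and 10001 template-moved
# votes, offset +4 drew 3664 and 774
tab <- VoteTable("alphaHb", "Adgb", "A", offsets = c(-1L, 0L, 4L),
                 votesQueryMoved = c(17155 - 10664 - 3664, 10664, 3664),
                 votesTemplateMoved = c(17155 - 10001 - 774, 10001, 774))
roundHalfDown(as.numeric(meanVotes(tab)[c("0", "4")]))  # 10332, 2219
```

## Parameters and their defaults

* **Offset range `OffsetRange(-25, 25)`.** Wide enough to contain any
  plausible helix register error plus the documented 4-residue class
  differences between globin lineages, narrow enough that a window never
  "wraps" to an unrelated part of the domain.
* **Substitution matrix: BLOSUM62.** The standard general-purpose matrix
  for distant homology; any symmetric matrix over the 20 standard residues
  can be supplied to `scoringScheme()`.
* **Out-of-range score: the matrix minimum** (−4 for BLOSUM62). Window
  positions slid past a sequence's end must be penalized, or short
  sequences would vote for extreme offsets that hide most of the window
  off-sequence; the matrix minimum is the harshest penalty expressible in
  the matrix's own units.
* **Gap score: 0.** Gap characters appear only in internally aligned
  families; a gap column is evidence of nothing, so it contributes nothing.
* **Tie splitting $1/k$.** Preserves vote conservation exactly and avoids
  an arbitrary preference among equally scoring offsets.
* **Rounding: half-down** (`roundHalfDown`). Direction means end in .5
  whenever the two direction counts differ by an odd number; a fixed
  half-down rule keeps reported integers deterministic and reproduces the
  published worked example (10332.5 → 10332).
* **Consensus tie-break: smallest |offset|, then the negative one.** The
  no-shift null is the conservative default when the product is flat.

## The mirror property, exactly

Intuition says the two sliding directions are the same experiment viewed
from opposite sides, so after re-indexing they should agree. With real
flanking residues they *almost* agree but not exactly: moving the query
window by $+s$ and moving the template window by $-s$ compare the same
diagonal of the residue–residue score matrix, but the window *frame*
differs by $s$ positions, so the two scores differ by the flanking content
entering and leaving the frame. The directions coincide **exactly** when —
and only when — everything outside the windows scores constantly: either
the window spans the whole sequence (all off-window reads are the constant
out-of-range penalty) or the flanks are neutral residues (the BLOSUM62 `X`
row is a constant −1). The package's test suite verifies exact equality in
both constructions; on natural sequences the two directions are reported
side by side and averaged rather than assumed identical.

## The synthetic generator

`generateFamily()` grows a family from one seed sequence by independent
per-position substitution, then optionally displaces helix windows
(`plantOffset`) and forces exact column compositions (planted CD1
tyrosines). It emulates the three things the voting method actually
consumes:

* a family of homologs with a controlled **expected pairwise identity** —
  the per-sequence substitution rate is calibrated so that the *pairwise*
  identity between two generated sequences (not the identity to the hidden
  seed) matches the target, which is what "25% identity" means operationally;
* a **known true offset**, planted by physically moving window content;
* **known column composition** for frequency reporting.

It does **not** emulate phylogenetic correlation (sequences are i.i.d.
around the seed), position-specific conservation, indels (families are
generated ungapped and equal-length), or compositional bias. Those factors
change how hard real families are, not what the correct answer is, so
planted fixtures remain valid ground truth for correctness testing while
real-data difficulty must be judged on real data. Targets below 5% identity
are rejected: they are unreachable above chance under a 20-letter alphabet.

Everything is reproducible from one integer seed: the generator draws one
sub-seed per record, so the same spec yields byte-identical FASTA output on
any run.

## Numerical and design choices

* Voting is vectorized: sequences are integer-encoded once (20 residues,
  `X`, `-`, and an out-of-range marker) and each offset's scores for all
  $|T| \times |Q|$ pairs accumulate by matrix indexing, so the published
  problem size (17155 pairs × 51 offsets × 2 directions) runs in seconds.
  A literal pair × offset × position triple loop is kept in the test suite
  as an independent oracle.
* Ties at the score maximum are detected with a $10^{-9}$ tolerance;
  all scores are small integers summed in double precision, so this cannot
  merge genuinely distinct scores.
* Zero-vote tables cannot arise from a tally (votes are conserved), but
  `consensusOffsets()` still drops an all-zero table with a warning rather
  than silently zeroing every product entry.
* Helices C and D are typically *not* voted on: in circularly permuted
  targets their equivalents may be absent or unalignable, so the renderer
  accepts manual offsets for them and refuses to guess
  (`assemblePermutedAlignment` errors on a canonical helix with neither a
  consensus nor a manual offset).

## Limitations

* The method aligns *windows*, not residues: it assumes helix boundaries
  are correctly annotated in every family and reports one rigid offset per
  helix. Intra-helix indels are invisible to it.
* Offsets are per-helix and independent; no global consistency constraint
  ties neighboring helices together.
* Percent identities in the twilight zone are descriptive, not
  significance-tested; the package reports them without p-values.
* The consensus product has no probabilistic calibration — the dominance
  ratio orders hypotheses but is not an odds ratio.
* Synthetic validation covers correctness of the machinery, not biological
  truth of any particular alignment.
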