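Package: helixvote
Title: Multi-Template Helix Profile Alignment by Offset Voting
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aligns a query protein family to multiple template families in
    the twilight zone of sequence similarity by sliding fixed helix windows
    over a range of integer offsets, scoring every cross-family sequence
    pair under a substitution matrix, and letting each pair vote for its
    best offset. Per-template vote histograms are normalized to [0,1] and
    multiplied across templates into a consensus offset per helix. Built for
    circularly permuted globins such as the androglobin globin domain, it
    also computes per-helix percent identity, aligned-column residue
    frequencies, and renders the permuted multi-family alignment with chain
    break and key-residue annotations. A synthetic-family generator with
    controlled pairwise identity and planted offsets supports validation
    without external sequence sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Biostrings, jsonlite, yaml
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, withr
Config/testthat/edition: 3
VignetteBuilder: knitr
biocViews: Alignment, SequenceMatching, Proteomics
RoxygenNote: 7.3.3
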