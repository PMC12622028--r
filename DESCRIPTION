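Package: teinvader
Title: Detecting and Characterizing Transposable Element Invasions from
    Population Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for discovering transposable element (TE) families that
    are invading natural populations but are absent from the reference genome,
    and for characterizing them. Covers divergence-based candidate read
    extraction from short-read alignments, k-mer contaminant filtering, de
    Bruijn unitig assembly, six-frame translated protein search against a TE
    protein library, majority-rule consensus building from aligned insertions,
    structural annotation of LTR retroelements (terminal repeats, ORFs,
    internal repeats), coverage-based copy-number estimation normalized by
    single-copy genes with a breadth-based presence caller, spatio-temporal
    invasion summaries, piRNA mapping with ping-pong signature statistics,
    and seed-extend-chain screening of genome assemblies. A seeded synthetic
    data generator produces genomes with planted TE copies, reads with truth
    alignments, small-RNA libraries, and invasion cohorts with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
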