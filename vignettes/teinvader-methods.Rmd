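---
title: "Detecting transposable element invasions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transposable element invasions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teinvader)
library(dplyr)
```

## The problem

A transposable element (TE) family that has only recently begun invading a
species is, almost by definition, missing from that species' reference
genome: the reference was assembled from strains collected before the
invasion. Standard TE annotation — mapping reads to a curated repeat
library, or masking a reference assembly — is therefore blind to exactly
the families that are most interesting for studying invasion dynamics.
`teinvader` implements the complementary strategy: mine population
short-read data for sequence that the reference cannot explain, assemble
it, and keep what looks like a TE; then characterize the resulting family
(structure, copy number through time, small-RNA silencing status) and
screen related species' assemblies for the likely donor of the horizontal
transfer.

All stages are in-memory, tibble-first functions; the `exec/teinvader`
script exposes them as shell subcommands for file-based pipelines.

## Discovery: from read alignments to TE candidates

The discovery pipeline (`detect_novel_te()`) runs five stages in a fixed
order, each with a conserved read ledger:

1. **Candidate read selection.** A read is a candidate when its alignment
   to the reference is missing, or present but with divergence strictly
   greater than 5% — divergence being the `NM` edit distance divided by the
   aligned length (CIGAR M/=/X/I/D; clips excluded from both numerator and
   denominator, so the ratio is bounded by 1). The 5% rule is strict
   ("more than"), so a read at exactly 0.05 stays. An optional rule for
   heavily soft-clipped reads (off by default) catches reads that straddle
   insertion junctions.
2. **Contaminant filtering.** Laboratory contaminants (human, *Wolbachia*,
   and whatever else the user supplies) are removed by canonical k-mer
   containment: a read is dropped when at least half of its canonical
   31-mers occur in the contaminant index. This replaces a full aligner
   with a deterministic, tunable membership test; at default parameters a
   read that is an exact substring of a contaminant always fails, and a
   read sharing no 31-mer always passes.
3. **Assembly.** A minimal de Bruijn assembler produces unitigs — maximal
   unambiguous graph paths — after dropping k-mers seen fewer than 2 times.
   At branch points, outgoing (and, symmetrically, incoming) edges whose
   k-mer abundance falls below 20% of the best sibling are ignored. This
   relative-abundance pruning is the one cleaning step beyond plain
   unitigs: at the read depths where this pipeline operates (TE-derived
   reads stack to the per-copy coverage times the copy number), shared
   sequencing errors recur often enough to pass an absolute coverage floor,
   and without pruning they fragment the unitigs into useless pieces.
   Pruning by relative abundance removes those error edges while leaving
   genuine equal-abundance branches (two real haplotypes, repeat exits)
   intact; there is no bubble popping and no scaffolding. Contigs shorter
   than `2k` are dropped, and output order (length descending, then
   sequence, canonical orientation) is deterministic.
4. **Translated search.** Contigs are translated in six frames, stop
   codons split the translations into peptides, and peptides are aligned
   locally (Smith–Waterman, BLOSUM62, affine gaps costing `11 + L`) to a
   TE protein library. Identity is matched residues over alignment
   columns; the reported span is the aligned peptide length times three,
   i.e. a nucleotide span on the contig.
5. **Candidate filter.** A contig is kept when its best hit exceeds 80%
   identity *and* 250 nt span, both strict.

The thresholds live in one validated object (`scan_thresholds()`); every
stage can also be called on its own.

### Why the span cutoff is in nucleotides

Published descriptions of this kind of filter ("alignment length >
250 bp") are ambiguous between amino-acid columns and nucleotide span.
We interpret it as nucleotide span on the contig (3 × aligned residues),
which is the more conservative reading for a translated search, and keep
it configurable.

## Element structure

`annotate_element()` combines three primitives:

- `detect_terminal_repeats()` finds LTRs by exact k-mer seeding between
  the first and last quarter of the element followed by ungapped maximal
  extension: on each candidate diagonal it reports the longest interval
  whose identity stays at or above the floor (default 95%). "Maximal"
  means exactly that — at a permissive floor the interval can absorb a few
  flanking bases beyond a perfect repeat, because a long run of exact
  matches banks enough identity credit. Callers that need base-precise
  boundaries (e.g. trimming an insertion to LTR-to-LTR extent) should
  raise the floor. Indel-containing LTR pairs are out of scope: recently
  inserted elements carry identical or near-identical LTRs.
- `self_dotplot()` reports exact k-mer self-matches on both strands,
  merges collinear runs, and summarizes tandem arrays as
  (start, end, unit length, copy count) — the way a dot plot reveals an
  internal low-complexity repeat region.
- `find_orfs()` scans all six frames for maximal ATG-to-stop spans
  (standard genetic code, no alternative starts); products are labelled
  gag/pol/env by the translated search when a protein library is given.

`majority_consensus()` builds a family consensus from aligned insertions:
per column, the most frequent of A/C/G/T wins (N never counts; ties break
A<C<G<T), and columns where the gap is the single most frequent symbol are
dropped, keeping the consensus ungapped and usable as a mapping reference.
A per-column occupancy table is emitted alongside, so segmental
presence/absence variants among insertions (a block present in some
copies, absent in others) remain visible instead of being silently
resolved.

## Copy number and presence

Copy number follows the coverage-normalization idea of DeviaTE-style
estimators: reads are mapped against a small database of the TE consensus
plus single-copy genes (SCGs); the per-position TE depth divided by the
mean SCG depth is the per-position copy estimate, and its mean over the
consensus is the sample's copy number. The SCG factor pools positions
across all SCGs rather than averaging per-gene means — for genes of
comparable length the difference is negligible and the pooled form is
easier to reason about. The mean is the default position summary; a
median option is available for robustness to internal deletions.

A family is **present** in a sample when at least 90% of consensus
positions have normalized coverage strictly above 1. The depth comparison
is strict per the rule's wording; the breadth comparison is inclusive
(exactly 90% counts), a boundary we fixed explicitly since prose
thresholds rarely state it.

`summarize_invasion()` joins presence calls with collection metadata into
per-(year, region) counts. Years with no samples are emitted with zero
totals: a detection gap between two positive years can be a sampling
artifact, and the output must make that visible rather than interpolate.

## Small RNAs and the ping-pong signature

`map_small_rnas()` places 23–29 nt reads (the piRNA length window;
configurable) at every position of the consensus on both strands with up
to 2 mismatches and no indels — a seed-free full scan is perfectly
affordable at consensus scale. Multi-mappers are weighted 1 over their
placement count, which keeps results deterministic.

The ping-pong signature is computed from 5'–5' overlaps of sense and
antisense reads: for each offset 1–20, the weighted count of read pairs
whose 5' ends overlap by exactly that many nucleotides. Germline ping-pong
amplification concentrates mass at offset 10. Two summaries are emitted,
since conventions differ between scripts in circulation: the z-score of
the offset-10 count against the other 19 offsets, and the fraction of
overlapping pairs at offset 10. For a degenerate histogram the z-score is
`NA` (no overlapping pairs at all) or `Inf` (all mass at 10). Note that in
a dense uniformly-placed library the fraction at 10 saturates well below
1 even when every antisense read has a designed partner, because unrelated
sense/antisense reads also overlap; the z-score is the robust statistic.

## Assembly screening

`screen_assembly()` is a seed–extend–chain homology search standing in
for a RepeatMasker-style scan with a single-family library: exact 13-mer
seeds on both strands, merged along diagonals, extended ungapped under an
X-drop rule (match +1, mismatch −3, drop 12), segments under 50 bp
discarded, collinear segments within 1 kb chained into one hit. The
1 kb chaining gap mirrors the fragment joining any such tool needs and is
configurable. Identity is computed over the extended segments only, so an
interior unaligned gap reduces the matched length but not the identity —
this is what lets a summary like "8.6 kb at 98.9%" separate span from
similarity. A hit is **full length** when it covers more than 80% of the
consensus. Internal self-homology of the family (LTR-vs-LTR matches, the
tandem region) necessarily produces nested sub-hits; hits at least 90%
contained in a longer-matching hit on the same contig are removed by
default.

Downstream, `extract_with_flanks()` cuts each hit with 3 kb of flank
(clipped at contig ends; minus-strand hits reverse-complemented), and
`require_two_ltrs()` keeps only insertions with a terminal-repeat pair of
at least 100 bp at 85% identity — fragments and solo LTRs fail — trimming
survivors to LTR-to-LTR extent. The detection window is the hit plus a
300 bp margin rather than the full flanked record, so the terminal-quarter
seeding of the repeat finder operates on the insertion itself.
`best_match_table()` reduces hit tables to one row per assembly (longest
match, ties to higher identity; zero rows for negative assemblies), the
standard scatter for donor-species reconnaissance.

## The synthetic data generator

Every test input is generated in code with exact ground truth; no
external data is needed anywhere in the package.

- `make_te_element()` builds an insect endogenous retrovirus-like element:
  two identical LTRs (default 514 bp) flanking a 5' UTR with a tandem
  repeat (3 × 200 bp) and gag/pol/env ORFs (500/1300/450 codons,
  ~8.9 kb total), with pol longest as in real errantiviruses. The
  element's own translated ORFs double as the TE protein library.
- `plant_te_copies()` inserts copies at uniform non-overlapping positions,
  each independently mutated by substitutions. The default per-copy
  divergence is 0: the invasions this package models are recent, and
  recently expanded insertions are nearly identical (identical LTRs, tight
  clustering). Divergence and `fragment_fraction` are dials used
  deliberately for degraded-relic and screening scenarios. Substitutions
  only — no indels — so truth alignments are single M-run CIGARs.
- `simulate_reads()` draws uniform read starts, Bernoulli strands and
  substitution errors, and writes the truth alignment of each read by
  bookkeeping rather than by running an aligner: a read is mapped only
  when it lies entirely within one genome segment deriving from a
  designated reference, with `NM` counting planted mutations plus
  sequencing errors in its span; TE-derived reads and junction-spanning
  reads are unmapped, which is precisely what feeds the discovery
  pipeline. (If a sequencing error hits a planted mutation it can revert
  the base; at the rates simulated here this is a ~10^-5 per-read event
  and is ignored.)
- `simulate_small_rnas()` pairs each antisense read with a sense partner
  at exact 10 nt 5'–5' overlap with probability `pingpong_fraction`,
  placing everything else uniformly.
- `simulate_invasion_cohort()` samples individuals whose carrier
  probability is logistic in years since the element reached their
  region — exactly 0 before arrival — under an explicit
  `invasion_scenario()` with per-region arrival years and rates.

What the generator does **not** emulate: indels and structural variants
within planted copies, quality-by-cycle error profiles, paired-end
geometry, GC-coverage bias, and real mapper behaviour at junctions (truth
mapping is all-or-nothing per read). Tests passing on these simulations
demonstrate the algorithmic contracts — recovery of planted truth under
substitution noise — not performance on real libraries, where mapper
artifacts and repeat families other than the target add background.

## Problem sizes and numerical choices

The test suite exercises a compact ~2.5 kb element against 20–30 kb
backbones for speed; the full-scale checks use the ~8.9 kb element, a
100 kb reference at 20× with 1% error for discovery, 30× for copy numbers
1–50, 100 kb assemblies for screening, and 100 seeded null libraries for
the ping-pong false-positive rate. These sizes were chosen as the
smallest at which every planted effect is unambiguous.

Other fixed choices: assembler k = 31 (odd, forbids palindromic k-mer
ambiguity), minimum k-mer coverage 2, branch ratio 0.2; contaminant
k = 31 with a 0.5 hit fraction; screening seed k = 13 (one expected
chance 13-mer per ~67 Mb of comparison, so random assemblies stay clean);
X-drop 12; LTR seed k = 13. All tie-breaks (equal-score hits,
equal-length contigs, equal-identity repeats) resolve lexicographically
or by fixed alphabet order so that every run of every stage is
reproducible bit for bit; every stochastic generator takes an explicit
seed and restores the caller's RNG state.

## Known limitations

- The assembler is deliberately minimal; for real libraries with
  polymorphic TE insertions an external assembler's contigs can be fed
  straight into `search_te_proteins()`.
- The translated search reports raw Smith–Waterman scores and identities,
  not E-values; the identity/span filter plays the role of significance
  control at desk scale.
- LTR detection is ungapped; elements whose two LTRs differ by indels
  will be reported only up to the longest ungapped block.
- Presence calling assumes mapping against the full-length consensus;
  solo-LTR-only samples produce high coverage over the LTR but fail the
  90% breadth rule, which is the intended reading of the rule.
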