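test_that("a planted exact copy is recovered as one full-length hit", {
  el <- small_element()
  bg <- simulate_genome(30000, seed = 91, id = "c1")
  pl <- plant_te_copies(bg, el, copy_count = 1, seed = 92)
  hits <- screen_assembly(pl$genome, el$element$seq)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 100)
  expect_equal(hits$matched_length, nchar(el$element$seq))
  expect_true(hits$full_length)
  expect_equal(hits$start, pl$truth$start)
  expect_equal(hits$end, pl$truth$end)
})

test_that("planted copies at 5% and 11% divergence keep tracking identity", {
  el <- small_element()
  for (seed in 1:3) {
    for (d in c(0.05, 0.11)) {
      bg <- simulate_genome(30000, seed = 900 + seed, id = "c1")
      pl <- plant_te_copies(bg, el, copy_count = 1, per_copy_divergence = d,
                            seed = 910 + seed)
      hits <- screen_assembly(pl$genome, el$element$seq)
      expect_equal(nrow(hits), 1L, info = sprintf("d=%.2f seed=%d", d, seed))
      expect_lt(abs(hits$identity - (100 - 100 * d)), 2)
      expect_true(hits$full_length)
    }
  }
})

test_that("a planted fragment is found but not full length", {
  el <- small_element()
  bg <- simulate_genome(20000, seed = 93, id = "c1")
  pl <- plant_te_copies(bg, el, copy_count = 1, fragment_fraction = 0.45,
                        seed = 94)
  hits <- screen_assembly(pl$genome, el$element$seq)
  expect_equal(nrow(hits), 1L)
  expect_false(hits$full_length)
  expect_lt(abs(hits$matched_length - 0.45 * nchar(el$element$seq)), 20)
})

test_that("a TE-free assembly yields no hits", {
  el <- small_element()
  bg <- simulate_genome(30000, seed = 95, id = "c1")
  hits <- screen_assembly(bg, el$element$seq)
  expect_equal(nrow(hits), 0L)
})

test_that("screening is strand symmetric up to coordinate mirroring", {
  el <- small_element()
  bg <- simulate_genome(25000, seed = 96, id = "c1")
  pl <- plant_te_copies(bg, el, copy_count = 1, per_copy_divergence = 0.05,
                        seed = 97)
  fwd <- screen_assembly(pl$genome, el$element$seq)
  L <- nchar(pl$genome$seq)
  flipped <- dplyr::mutate(pl$genome, seq = revcomp(seq))
  rev <- screen_assembly(flipped, el$element$seq)
  expect_equal(nrow(rev), nrow(fwd))
  expect_equal(rev$identity, fwd$identity)
  expect_equal(rev$matched_length, fwd$matched_length)
  expect_equal(rev$start, L - fwd$end)
  expect_equal(rev$end, L - fwd$start)
  expect_true(all(rev$strand != fwd$strand))
})

test_that("the full-length flag matches brute-force consensus coverage", {
  el <- small_element()
  clen <- nchar(el$element$seq)
  for (frac in c(0.3, 0.7, 0.9)) {
    bg <- simulate_genome(15000, seed = round(100 * frac), id = "c1")
    pl <- plant_te_copies(bg, el, copy_count = 1, fragment_fraction = frac,
                          seed = 98)
    hits <- screen_assembly(pl$genome, el$element$seq)
    expect_equal(hits$full_length[1], hits$matched_length[1] > 0.8 * clen)
  }
})

test_that("flank extraction clips at contig boundaries and flips strand", {
  assembly <- tibble::tibble(id = "c1", desc = "",
                             seq = random_dna(30000, seed = 99))
  hit <- tibble::tibble(assembly_id = "a", contig_id = "c1",
                        start = 5000L, end = 14000L, strand = "+")
  rec <- extract_with_flanks(assembly, hit)
  expect_equal(nchar(rec$seq), 15000L)
  expect_equal(rec$seq, substr(assembly$seq, 2001, 17000))

  near_edge <- tibble::tibble(assembly_id = "a", contig_id = "c1",
                              start = 1000L, end = 2000L, strand = "+")
  rec2 <- extract_with_flanks(assembly, near_edge)
  expect_equal(nchar(rec2$seq), 1000L + 1000L + 3000L)

  minus <- tibble::tibble(assembly_id = "a", contig_id = "c1",
                          start = 5000L, end = 14000L, strand = "-")
  rec3 <- extract_with_flanks(assembly, minus)
  expect_equal(rec3$seq, revcomp(rec$seq))
})

test_that("the two-LTR rule keeps intact elements and rejects relics", {
  el <- small_element()
  bg <- simulate_genome(12000, seed = 101, id = "c1")
  pl <- plant_te_copies(bg, el, copy_count = 1, seed = 102)
  hits <- screen_assembly(pl$genome, el$element$seq)
  ins <- extract_with_flanks(pl$genome, hits[1, ])
  res <- require_two_ltrs(ins, min_length = 100)
  expect_true(res$pass)
  # at the default 85% identity floor, maximal extension may absorb a few
  # dozen flanking bases beyond the true 120 bp repeats
  expect_gte(res$ltrs$length, 120L)
  expect_lt(abs(nchar(res$trimmed$seq) - nchar(el$element$seq)), 80)
  # at a 100% floor the trimmed insertion pins down the element exactly
  strict <- require_two_ltrs(ins, min_length = 100, min_identity = 100)
  expect_true(strict$pass)
  expect_true(grepl(el$element$seq, strict$trimmed$seq, fixed = TRUE))
  expect_lte(strict$ltrs$length, 124L)

  # solo LTR fails
  solo <- tibble::tibble(id = "solo", seq = paste0(
    random_dna(3000, seed = 103), substr(el$element$seq, 1, 120),
    random_dna(3000, seed = 104)))
  expect_false(require_two_ltrs(solo, min_length = 100)$pass)

  # element with one LTR deleted fails
  lopped <- tibble::tibble(id = "lop", seq = paste0(
    random_dna(3000, seed = 105),
    substr(el$element$seq, 121, nchar(el$element$seq)),
    random_dna(3000, seed = 106)))
  expect_false(require_two_ltrs(lopped, min_length = 100)$pass)
})

test_that("the best-match table keeps length-first, identity-tie-break rules", {
  hits <- tibble::tibble(
    assembly_id = c("sp1", "sp1", "sp2", "sp2"),
    contig_id = "c", start = 0L, end = 1L, strand = "+",
    matched_length = c(8000L, 2000L, 5000L, 5000L),
    identity = c(98, 99, 97, 99),
    n_segments = 1L, full_length = FALSE
  )
  best <- best_match_table(hits, assembly_ids = c("sp1", "sp2", "sp3"))
  expect_equal(best$best_matched_length, c(8000L, 5000L, 0L))
  expect_equal(best$best_identity, c(98, 99, 0))
  expect_equal(best$n_hits, c(2L, 2L, 0L))
})

test_that("fragmented insertions are counted once", {
  hits <- tibble::tibble(
    assembly_id = "a", contig_id = "c", strand = "+",
    start = c(1000L, 3000L, 40000L),
    end = c(2500L, 5000L, 48000L),
    matched_length = c(1500L, 2000L, 8000L),
    identity = 95, n_segments = 1L, full_length = FALSE
  )
  # first two hits are adjacent fragments; the third is a distinct locus
  expect_equal(count_insertions(hits), 2L)
})
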