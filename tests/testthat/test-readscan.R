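make_reads <- function(ids, len = 100L, seed = 1L) {
  tibble::tibble(
    id = ids, desc = "",
    seq = vapply(seq_along(ids), function(i) random_dna(len, seed + i),
                 character(1)),
    qual = strrep("I", len)
  )
}

test_that("alignment divergence follows NM over aligned length", {
  aln <- read_sam(write_sam_fixture(c(
    sam_line("perfect", 0L, "ref", 1L, "100M", strrep("A", 100), nm = 0L),
    sam_line("six", 0L, "ref", 1L, "100M", strrep("A", 100), nm = 6L),
    sam_line("indel", 0L, "ref", 1L, "90M5I5D", strrep("A", 95), nm = 10L)
  )))
  d <- alignment_divergence(aln)
  expect_equal(d$divergence[d$query_id == "perfect"], 0)
  expect_equal(d$divergence[d$query_id == "six"], 0.06)
  expect_equal(d$divergence[d$query_id == "indel"], 0.10)
})

test_that("divergence is undefined for unmapped or NM-less reads", {
  unmapped <- read_sam(write_sam_fixture(
    sam_line("u1", 4L, "*", 0L, "*", strrep("A", 50))))
  expect_error(alignment_divergence(unmapped),
               class = "teinvader_divergence_error")
  no_nm <- read_sam(write_sam_fixture(
    sam_line("n1", 0L, "ref", 1L, "50M", strrep("A", 50))))
  expect_error(alignment_divergence(no_nm),
               class = "teinvader_divergence_error")
})

test_that("candidate selection takes unmapped and strictly divergent reads once", {
  reads <- make_reads(c("unmapped", "at_cut", "above_cut", "below_cut"))
  aln <- read_sam(write_sam_fixture(c(
    sam_line("unmapped", 4L, "*", 0L, "*", reads$seq[1]),
    sam_line("at_cut", 0L, "ref", 1L, "100M", reads$seq[2], nm = 5L),
    sam_line("above_cut", 0L, "ref", 1L, "100M", reads$seq[3], nm = 7L),
    sam_line("below_cut", 0L, "ref", 1L, "100M", reads$seq[4], nm = 1L),
    sam_line("above_cut", 256L, "ref", 50L, "100M", reads$seq[3], nm = 7L)
  )))
  out <- select_candidate_reads(aln, reads)
  # 5% exactly is NOT above the "more than 5%" cut; secondary records ignored
  expect_setequal(out$id, c("unmapped", "above_cut"))
  expect_equal(sum(out$id == "above_cut"), 1L)
})

test_that("missing reads in the store are an error", {
  reads <- make_reads("present")
  aln <- read_sam(write_sam_fixture(
    sam_line("absent", 4L, "*", 0L, "*", strrep("A", 100))))
  expect_error(select_candidate_reads(aln, reads),
               class = "teinvader_missing_read_error")
})

test_that("soft-clip rule is off by default and strict when enabled", {
  reads <- make_reads("clipped")
  aln <- read_sam(write_sam_fixture(
    sam_line("clipped", 0L, "ref", 1L, "50S50M", reads$seq[1], nm = 0L)))
  expect_equal(nrow(select_candidate_reads(aln, reads)), 0L)
  th <- scan_thresholds(min_softclip_fraction = 0.5)
  expect_equal(select_candidate_reads(aln, reads, th)$id, "clipped")
})

test_that("contaminant containment drops reads by canonical k-mer fraction", {
  contaminant <- tibble::tibble(id = "wolb", desc = "",
                                seq = random_dna(5000, seed = 77))
  idx <- contaminant_index(contaminant, k = 31L)
  exact <- tibble::tibble(id = "inside", desc = "",
                          seq = substr(contaminant$seq, 101, 200),
                          qual = strrep("I", 100))
  random <- make_reads("random", seed = 123)
  # reverse complement of a contaminant fragment must also be caught
  rc <- tibble::tibble(id = "rc", desc = "",
                       seq = revcomp(substr(contaminant$seq, 501, 600)),
                       qual = strrep("I", 100))
  pool <- dplyr::bind_rows(exact, random, rc)
  kept <- filter_contaminants(pool, idx)
  expect_equal(kept$id, "random")
  # reads shorter than k pass through
  shorty <- tibble::tibble(id = "short", desc = "", seq = "ACGTACGT",
                           qual = "IIIIIIII")
  expect_equal(filter_contaminants(shorty, idx)$id, "short")
})

test_that("a read with sub-threshold k-mer hits is kept, matching brute force", {
  k <- 31L
  contaminant <- tibble::tibble(id = "c", desc = "",
                                seq = random_dna(2000, seed = 9))
  idx <- contaminant_index(contaminant, k = k)
  # build a 100-mer: 50 bases of contaminant + 50 random -> 20/70 k-mers hit
  mixed <- paste0(substr(contaminant$seq, 301, 350), random_dna(50, seed = 5))
  kms <- substring(mixed, 1:(nchar(mixed) - k + 1L), k:nchar(mixed))
  canon <- ifelse(kms <= revcomp(kms), kms, revcomp(kms))
  ckms <- substring(contaminant$seq, 1:(2000 - k + 1L), k:2000)
  ccanon <- unique(ifelse(ckms <= revcomp(ckms), ckms, revcomp(ckms)))
  frac <- mean(canon %in% ccanon)  # brute-force hit fraction
  expect_lt(frac, 0.5)
  expect_gt(frac, 0.2)
  reads <- tibble::tibble(id = "mixed", desc = "", seq = mixed,
                          qual = strrep("I", 100))
  expect_equal(filter_contaminants(reads, idx)$id, "mixed")
  strict <- scan_thresholds(contaminant_hit_fraction = frac)
  expect_equal(nrow(filter_contaminants(reads, idx, strict)), 0L)
})

test_that("contaminant filtering commutes with divergence selection", {
  el <- small_element()
  contaminant <- tibble::tibble(id = "w", desc = "",
                                seq = random_dna(3000, seed = 31))
  reads <- dplyr::bind_rows(
    make_reads(sprintf("g%d", 1:6), seed = 40),
    tibble::tibble(id = "cont1", desc = "",
                   seq = substr(contaminant$seq, 1, 100),
                   qual = strrep("I", 100))
  )
  aln <- read_sam(write_sam_fixture(c(
    sam_line("g1", 4L, "*", 0L, "*", reads$seq[1]),
    sam_line("g2", 0L, "ref", 1L, "100M", reads$seq[2], nm = 8L),
    sam_line("g3", 0L, "ref", 1L, "100M", reads$seq[3], nm = 2L),
    sam_line("g4", 0L, "ref", 1L, "100M", reads$seq[4], nm = 6L),
    sam_line("g5", 4L, "*", 0L, "*", reads$seq[5]),
    sam_line("g6", 0L, "ref", 1L, "100M", reads$seq[6], nm = 0L),
    sam_line("cont1", 4L, "*", 0L, "*", reads$seq[7])
  )))
  idx <- contaminant_index(contaminant)
  a <- filter_contaminants(select_candidate_reads(aln, reads), idx)
  pre <- filter_contaminants(reads, idx)
  b <- select_candidate_reads(
    dplyr::filter(aln, query_id %in% pre$id), pre)
  expect_equal(a$id, b$id)
  expect_equal(a$seq, b$seq)
})
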