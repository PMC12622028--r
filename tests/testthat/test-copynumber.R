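profile_of <- function(depths, ref = "te") {
  tibble::tibble(reference_id = ref, pos = seq_along(depths) - 1L,
                 depth = depths)
}

norm_of <- function(norm_depths) {
  # construct a normalized profile directly (SCG depth 1 everywhere)
  normalize_by_scg(profile_of(norm_depths), profile_of(rep(1, 100), "scg"))
}

test_that("pileup depth follows reference-consuming CIGAR spans", {
  aln <- read_sam(write_sam_fixture(c(
    sam_line("r1", 0L, "ref", 1L, "100M", strrep("A", 100)),
    sam_line("r2", 0L, "ref", 1L, "100M", strrep("A", 100)),
    sam_line("r3", 0L, "ref", 51L, "50M10D50M", strrep("A", 100))
  ), refs = c(ref = 200L)))
  cov <- coverage_profile(aln)
  expect_equal(nrow(cov), 200L)
  expect_equal(cov$depth[1:50], rep(2L, 50))
  # deletion counts as covered: r3 spans 110 reference bases
  expect_equal(sum(cov$depth > 0), 160L)
  expect_equal(cov$depth[101:160], rep(1L, 60))
  expect_equal(cov$depth[161:200], rep(0L, 40))
})

test_that("soft clips do not consume reference and unmapped reads are ignored", {
  aln <- read_sam(write_sam_fixture(c(
    sam_line("r1", 0L, "ref", 11L, "10S30M10S", strrep("A", 50)),
    sam_line("u1", 4L, "*", 0L, "*", strrep("C", 50))
  ), refs = c(ref = 100L)))
  cov <- coverage_profile(aln)
  expect_equal(sum(cov$depth), 30L)
  expect_equal(which(cov$depth == 1L), 11:40)
})

test_that("alignments past the reference end name the offending read", {
  aln <- read_sam(write_sam_fixture(
    sam_line("runaway", 0L, "ref", 190L, "50M", strrep("A", 50)),
    refs = c(ref = 200L)))
  expect_error(coverage_profile(aln), "runaway")
})

test_that("normalization divides by pooled SCG depth", {
  te <- profile_of(rep(20, 100))
  scg <- dplyr::bind_rows(profile_of(rep(12, 100), "scg1"),
                          profile_of(rep(8, 100), "scg2"))
  prof <- normalize_by_scg(te, scg)
  expect_equal(prof$scg_factor, 10)
  expect_equal(prof$copy_number, 2.0)

  zero <- normalize_by_scg(profile_of(rep(0, 50)), profile_of(rep(10, 50), "s"))
  expect_equal(zero$copy_number, 0)
  expect_equal(call_presence(zero)$breadth_above_one, 0)

  alt <- normalize_by_scg(profile_of(rep(c(0, 20), 50)),
                          profile_of(rep(10, 100), "s"))
  expect_equal(alt$copy_number, 1.0)
  expect_equal(call_presence(alt)$breadth_above_one, 0.5)
})

test_that("all-zero SCG coverage is an explicit error", {
  expect_error(normalize_by_scg(profile_of(rep(5, 10)),
                                profile_of(rep(0, 10), "s")),
               class = "teinvader_normalization_error")
})

test_that("presence needs 90% breadth of strictly-above-1 coverage", {
  # 95% of positions at 2.0 -> present; 85% -> absent; exactly 90% -> present
  for (case in list(list(frac = 0.95, present = TRUE),
                    list(frac = 0.85, present = FALSE),
                    list(frac = 0.90, present = TRUE))) {
    depths <- c(rep(2, case$frac * 100), rep(0, 100 - case$frac * 100))
    call <- call_presence(norm_of(depths))
    expect_equal(call$present, case$present,
                 info = sprintf("breadth %.2f", case$frac))
    expect_equal(call$breadth_above_one, case$frac)
  }
  # depth exactly at the threshold does not count (strict >)
  at_one <- call_presence(norm_of(rep(1, 100)))
  expect_equal(at_one$breadth_above_one, 0)
  expect_false(at_one$present)
})

test_that("copy number is invariant to depth scaling", {
  te <- profile_of(round(stats::runif(200, 0, 40)))
  scg <- profile_of(rep(10, 300), "scg")
  base <- normalize_by_scg(te, scg)
  for (fac in c(3, 10)) {
    scaled <- normalize_by_scg(
      dplyr::mutate(te, depth = depth * fac),
      dplyr::mutate(scg, depth = depth * fac))
    expect_equal(scaled$copy_number, base$copy_number)
    expect_equal(call_presence(scaled)$present, call_presence(base)$present)
  }
})

test_that("adding TE reads never decreases copy number or breadth", {
  refs <- c(te = 300L, scg = 300L)
  scg_lines <- vapply(seq(1L, 201L, by = 20L), function(p)
    sam_line(sprintf("s%d", p), 0L, "scg", p, "100M", strrep("A", 100)),
    character(1))
  te_lines <- vapply(seq(1L, 201L, by = 40L), function(p)
    sam_line(sprintf("t%d", p), 0L, "te", p, "100M", strrep("A", 100)),
    character(1))
  prev_cn <- -1; prev_breadth <- -1
  for (n in c(2L, 4L, 6L)) {
    aln <- read_sam(write_sam_fixture(c(scg_lines, te_lines[1:n]),
                                      refs = refs))
    est <- estimate_copy_number(aln, "te", "scg")
    expect_gte(est$call$copy_number, prev_cn)
    expect_gte(est$call$breadth_above_one, prev_breadth)
    prev_cn <- est$call$copy_number
    prev_breadth <- est$call$breadth_above_one
  }
})

test_that("simulated planted copies are recovered within 15%", {
  el <- small_element()  # ~2.5 kb element keeps the simulation quick
  scgs <- dplyr::bind_rows(lapply(1:3, function(i)
    simulate_genome(3000, seed = 200 + i, id = paste0("scg_", i))))
  for (c_copies in c(2L, 10L)) {
    for (seed in 1:3) {
      pl <- plant_te_copies(simulate_genome(10000, seed = 300 + seed,
                                            id = "bb"),
                            el, copy_count = c_copies, seed = 400 + seed)
      pl <- add_reference_segments(pl, scgs)
      sim <- simulate_reads(pl, coverage = 30, seed = 500 + seed,
                            target_refs = c("mini_te", scgs$id))
      est <- estimate_copy_number(sim$alignments, "mini_te", scgs$id)
      expect_lt(abs(est$call$copy_number - c_copies) / c_copies, 0.15,
                label = sprintf("c=%d seed=%d: %.2f", c_copies, seed,
                                est$call$copy_number))
    }
  }
})
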