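# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a random genome sequence
#'
#' I.i.d. bases at the requested GC content; reproducible for a fixed seed.
#'
#' @param length Sequence length in bp.
#' @param gc_fraction Fraction of G+C (default 0.42, a fly-like base
#'   composition).
#' @param seed RNG seed.
#' @param id Sequence id (default `"genome"`).
#' @return Single-row sequence tibble.
#' @export
simulate_genome <- function(length, gc_fraction = 0.42, seed = 1L,
                            id = "genome") {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    tibble(id = id, desc = "",
           seq = paste(sample(names(p), length, replace = TRUE, prob = p),
                       collapse = ""))
  })
}

# random open reading frame: ATG + (n_codons - 1) random non-stop codons +
# TAA; returned without the stop codon in the peptide
random_orf <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense_codons <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  codons <- c("ATG", sample(sense_codons, n_codons - 1L, replace = TRUE),
              "TAA")
  dna <- paste(codons, collapse = "")
  pep <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1, 3L * n_codons))))
  list(dna = dna, peptide = pep)
}

#' Build a synthetic LTR retroelement (insect endogenous retrovirus)
#'
#' Constructs an element with the canonical iERV architecture: two identical
#' LTRs (default 514 bp) flanking a 5' untranslated region that carries a
#' tandem repeat, followed by gag, pol and env open reading frames. The pol
#' ORF is the longest, as in real errantiviruses. The element's proteins
#' are returned alongside so they can serve as the TE protein library for
#' translated searches.
#'
#' @param seed RNG seed.
#' @param ltr_length LTR length in bp (default 514).
#' @param gag_aa,pol_aa,env_aa ORF lengths in codons (defaults 500, 1300,
#'   450).
#' @param utr_repeat_unit,utr_repeat_copies Tandem repeat in the 5' UTR
#'   (defaults: 200 bp unit, 3 copies).
#' @param id Element id (default `"synthetic_iERV"`). The generated element
#'   is synthetic throughout: sequence, proteins and coordinates carry no
#'   biological material.
#' @return A list of class `"synthetic_element"`: `element` (single-row
#'   sequence tibble), `proteins` (tibble of gag/pol/env amino-acid
#'   sequences), `ltr_length`, `orf_table` (0-based half-open coordinates),
#'   `repeat_region`.
#' @export
make_te_element <- function(seed = 1L, ltr_length = 514L,
                            gag_aa = 500L, pol_aa = 1300L, env_aa = 450L,
                            utr_repeat_unit = 200L, utr_repeat_copies = 3L,
                            id = "synthetic_iERV") {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    rnd <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
    ltr <- rnd(ltr_length)
    unit <- rnd(utr_repeat_unit)
    utr5 <- paste0(strrep(unit, utr_repeat_copies), rnd(60L))
    gag <- random_orf(gag_aa)
    pol <- random_orf(pol_aa)
    env <- random_orf(env_aa)
    sp1 <- rnd(60L); sp2 <- rnd(60L)
    utr3 <- rnd(300L)
    parts <- c(ltr, utr5, gag$dna, sp1, pol$dna, sp2, env$dna, utr3, ltr)
    lens <- nchar(parts)
    offs <- cumsum(c(0L, lens[-length(lens)]))
    seqs <- paste(parts, collapse = "")
    orf_table <- tibble(
      product = c("gag", "pol", "env"),
      start = offs[c(3L, 5L, 7L)],
      end = offs[c(3L, 5L, 7L)] + lens[c(3L, 5L, 7L)],
      aa_length = c(gag_aa, pol_aa, env_aa)
    )
    structure(
      list(
        element = tibble(id = id, desc = "synthetic LTR retroelement",
                         seq = seqs),
        proteins = tibble(id = c("gag", "pol", "env"),
                          desc = "synthetic TE protein",
                          seq = c(gag$peptide, pol$peptide, env$peptide)),
        ltr_length = ltr_length,
        orf_table = orf_table,
        repeat_region = tibble(start = offs[2L],
                               end = offs[2L] + utr_repeat_unit *
                                 utr_repeat_copies,
                               unit_length = utr_repeat_unit,
                               copy_count = utr_repeat_copies)
      ),
      class = "synthetic_element"
    )
  })
}

#' @export
print.synthetic_element <- function(x, ...) {
  cat(sprintf("Synthetic LTR retroelement: %d bp, %d bp LTRs, ORFs %s\n",
              nchar(x$element$seq), x$ltr_length,
              paste(sprintf("%s (%d aa)", x$proteins$id,
                            x$orf_table$aa_length), collapse = ", ")))
  invisible(x)
}

# mutate a sequence by substitutions at the given per-base rate; returns the
# sequence and the 1-based positions changed
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, positions = integer()))
  n <- nchar(seq)
  pos <- which(runif(n) < rate)
  if (length(pos) == 0) return(list(seq = seq, positions = integer()))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(setdiff(bases, b), 1L)
  }, character(1), USE.NAMES = FALSE)
  list(seq = paste(chars, collapse = ""), positions = pos)
}

#' Plant TE copies into a genome
#'
#' Inserts `copy_count` copies of a TE at uniform, non-overlapping backbone
#' positions, each independently mutated by substitutions at
#' `per_copy_divergence` (no indels, so truth alignments stay trivial).
#' Optionally each copy is a contiguous fragment of the element (a degraded
#' relic). The returned truth table and segment map are exact by
#' construction and drive the simulated read aligner.
#'
#' @param genome Single-row sequence tibble (the backbone).
#' @param te Single-row sequence tibble (the element), or a
#'   `synthetic_element`.
#' @param copy_count Number of copies to plant (0 leaves the genome
#'   untouched).
#' @param per_copy_divergence Per-base substitution probability per copy
#'   (default 0: a recent invasion plants near-identical copies).
#' @param fragment_fraction When not `NA`, each planted copy is a contiguous
#'   fragment of this fraction of the element, taken at a random offset.
#' @param seed RNG seed.
#' @return A list of class `"planted_genome"`: `genome` (modified single-row
#'   tibble), `truth` (tibble `copy`, `start`, `end` on the new genome,
#'   `te_start`, `te_end` on the element, `n_mutations`, `divergence`),
#'   `segments` (tibble `start`, `end` 0-based half-open on the new genome,
#'   `ref_id`, `ref_offset`), `mutated_positions` (1-based genome
#'   positions differing from their source reference).
#' @export
plant_te_copies <- function(genome, te, copy_count,
                            per_copy_divergence = 0,
                            fragment_fraction = NA_real_, seed = 1L) {
  stopifnot(copy_count >= 0, per_copy_divergence >= 0,
            per_copy_divergence <= 0.2)
  if (inherits(te, "synthetic_element")) te <- te$element
  backbone <- genome$seq[1]
  blen <- nchar(backbone)
  te_seq <- te$seq[1]
  te_len <- nchar(te_seq)
  if (copy_count == 0) {
    return(structure(list(
      genome = genome,
      truth = tibble(copy = integer(), start = integer(), end = integer(),
                     te_start = integer(), te_end = integer(),
                     n_mutations = integer(), divergence = numeric()),
      segments = tibble(start = 0L, end = blen, ref_id = genome$id[1],
                        ref_offset = 0L),
      mutated_positions = integer()
    ), class = "planted_genome"))
  }
  with_seed(seed, {
    sites <- sort(sample.int(blen - 1L, copy_count))
    copies <- vector("list", copy_count)
    for (i in seq_len(copy_count)) {
      if (!is.na(fragment_fraction)) {
        flen <- max(1L, round(fragment_fraction * te_len))
        off <- sample.int(te_len - flen + 1L, 1L) - 1L
        sub <- substr(te_seq, off + 1L, off + flen)
        copies[[i]] <- c(list(te_start = off, te_end = off + flen),
                         mutate_seq(sub, per_copy_divergence))
      } else {
        copies[[i]] <- c(list(te_start = 0L, te_end = te_len),
                         mutate_seq(te_seq, per_copy_divergence))
      }
    }
    pieces <- character(0)
    segments <- list()
    truth <- list()
    mutated <- integer(0)
    cursor_backbone <- 0L   # consumed backbone, 0-based
    cursor_genome <- 0L
    for (i in seq_len(copy_count)) {
      bb <- substr(backbone, cursor_backbone + 1L, sites[i])
      if (nchar(bb) > 0) {
        segments[[length(segments) + 1L]] <- tibble(
          start = cursor_genome, end = cursor_genome + nchar(bb),
          ref_id = genome$id[1], ref_offset = cursor_backbone
        )
        pieces <- c(pieces, bb)
        cursor_genome <- cursor_genome + nchar(bb)
      }
      cp <- copies[[i]]
      cp_len <- nchar(cp$seq)
      segments[[length(segments) + 1L]] <- tibble(
        start = cursor_genome, end = cursor_genome + cp_len,
        ref_id = te$id[1], ref_offset = cp$te_start
      )
      truth[[i]] <- tibble(
        copy = i, start = cursor_genome, end = cursor_genome + cp_len,
        te_start = cp$te_start, te_end = cp$te_end,
        n_mutations = length(cp$positions),
        divergence = length(cp$positions) / cp_len
      )
      mutated <- c(mutated, cursor_genome + cp$positions)
      pieces <- c(pieces, cp$seq)
      cursor_genome <- cursor_genome + cp_len
      cursor_backbone <- sites[i]
    }
    bb <- substr(backbone, cursor_backbone + 1L, blen)
    if (nchar(bb) > 0) {
      segments[[length(segments) + 1L]] <- tibble(
        start = cursor_genome, end = cursor_genome + nchar(bb),
        ref_id = genome$id[1], ref_offset = cursor_backbone
      )
      pieces <- c(pieces, bb)
    }
    structure(list(
      genome = tibble(id = genome$id[1], desc = "with planted TE copies",
                      seq = paste(pieces, collapse = "")),
      truth = bind_rows(truth),
      segments = bind_rows(segments),
      mutated_positions = mutated
    ), class = "planted_genome")
  })
}

#' Simulate short reads with exact truth alignments
#'
#' Uniform read starts, random strand, substitution sequencing errors. The
#' truth alignment of every read is produced by bookkeeping, not by running
#' an aligner: a read is recorded as mapped — with a full-match CIGAR and an
#' NM tag counting planted mutations plus sequencing errors in its span —
#' only when it lies entirely within one genome segment that derives from a
#' designated reference sequence; reads from other sequence (e.g. planted
#' TE copies absent from the reference) and reads spanning insertion
#' junctions are written as unmapped.
#'
#' @param planted A `planted_genome` ([plant_te_copies()]) or a single-row
#'   sequence tibble (then the whole genome is one designated reference).
#' @param coverage Mean fold coverage.
#' @param read_length Read length in nt (default 100).
#' @param error_rate Per-base substitution error rate (default 0.005).
#' @param seed RNG seed.
#' @param target_refs Reference ids reads can map to (default: every
#'   segment's `ref_id` except the TE; for a plain genome, its id).
#' @param reference_lengths Named lengths of the designated references
#'   (required when they cannot be inferred).
#' @param read_prefix Prefix for read ids.
#' @return A list: `reads` (tibble `id`, `desc`, `seq`, `qual`),
#'   `alignments` (tibble in [read_sam()] layout with the
#'   `reference_lengths` attribute set).
#' @export
simulate_reads <- function(planted, coverage, read_length = 100L,
                           error_rate = 0.005, seed = 1L,
                           target_refs = NULL, reference_lengths = NULL,
                           read_prefix = "read") {
  if (is.data.frame(planted)) {
    planted <- structure(list(
      genome = planted,
      segments = tibble(start = 0L, end = nchar(planted$seq[1]),
                        ref_id = planted$id[1], ref_offset = 0L),
      mutated_positions = integer()
    ), class = "planted_genome")
  }
  g <- planted$genome$seq[1]
  glen <- nchar(g)
  stopifnot(read_length <= glen)
  segs <- planted$segments
  if (is.null(target_refs)) target_refs <- unique(segs$ref_id)
  if (is.null(reference_lengths)) {
    # infer from segment extents; exact when segments tile each reference
    reference_lengths <- segs %>%
      filter(.data$ref_id %in% target_refs) %>%
      group_by(.data$ref_id) %>%
      summarise(len = max(.data$ref_offset + .data$end - .data$start),
                .groups = "drop") %>%
      (\(x) setNames(as.integer(x$len), x$ref_id))()
  }
  n_reads <- max(1L, round(coverage * glen / read_length))
  with_seed(seed, {
    starts <- sample.int(glen - read_length + 1L, n_reads, replace = TRUE)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(g, starts, starts + read_length - 1L)
    n_err <- rbinom(n_reads, read_length, error_rate)
    err_pos <- vector("list", n_reads)
    bases <- c("A", "C", "G", "T")
    for (i in which(n_err > 0L)) {
      pos <- sample.int(read_length, n_err[i])
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      chars[pos] <- vapply(chars[pos], function(b) {
        sample(setdiff(bases, b), 1L)
      }, character(1), USE.NAMES = FALSE)
      seqs[i] <- paste(chars, collapse = "")
      err_pos[[i]] <- pos
    }
    out_seq <- ifelse(strands == "-", revcomp(seqs), seqs)

    # truth mapping: the segment fully containing the read, if any
    seg_idx <- findInterval(starts - 1L, segs$start)
    contained <- (starts + read_length - 1L) <= segs$end[seg_idx]
    mappable <- contained & segs$ref_id[seg_idx] %in% target_refs
    muts <- sort(planted$mutated_positions)
    n_mut_span <- findInterval(starts + read_length - 1L, muts) -
      findInterval(starts - 1L, muts)
    ids <- sprintf("%s_%06d", read_prefix, seq_len(n_reads))
    ref_id <- ifelse(mappable, segs$ref_id[seg_idx], "*")
    pos <- ifelse(mappable,
                  segs$ref_offset[seg_idx] + (starts - 1L - segs$start[seg_idx]) + 1L,
                  0L)
    flag <- ifelse(mappable, ifelse(strands == "-", 16L, 0L), 4L)
    aln <- tibble(
      query_id = ids,
      flag = flag,
      reference_id = ref_id,
      pos = as.integer(pos),
      mapq = ifelse(mappable, 60L, 0L),
      cigar = ifelse(mappable, sprintf("%dM", read_length), "*"),
      seq = out_seq,
      qual = strrep("I", read_length),
      edit_distance = ifelse(mappable,
                             as.integer(n_err + n_mut_span), NA_integer_),
      is_mapped = mappable,
      strand = strands,
      is_secondary = FALSE
    )
    attr(aln, "reference_lengths") <- reference_lengths
    list(
      reads = tibble(id = ids, desc = "", seq = out_seq,
                     qual = strrep("I", read_length)),
      alignments = aln
    )
  })
}

#' Append extra reference sequences to a planted genome
#'
#' Concatenates additional sequences (e.g. single-copy genes) to a planted
#' genome and records them as segments mapping to their own reference ids,
#' so simulated reads from them are written as mapped. Used to build the
#' TE-plus-single-copy-gene mapping databases of coverage-based copy-number
#' estimation.
#'
#' @param planted A `planted_genome` ([plant_te_copies()]).
#' @param seqs Sequence tibble (`id`, `seq`) to append.
#' @return The extended `planted_genome`.
#' @export
add_reference_segments <- function(planted, seqs) {
  stopifnot(inherits(planted, "planted_genome"))
  g <- planted$genome$seq[1]
  cursor <- nchar(g)
  segs <- list(planted$segments)
  for (i in seq_len(nrow(seqs))) {
    L <- nchar(seqs$seq[i])
    segs[[length(segs) + 1L]] <- tibble(
      start = cursor, end = cursor + L, ref_id = seqs$id[i], ref_offset = 0L
    )
    cursor <- cursor + L
  }
  planted$genome$seq <- paste0(g, paste(seqs$seq, collapse = ""))
  planted$segments <- bind_rows(segs)
  planted
}

#' Simulate a small-RNA library with a tunable ping-pong fraction
#'
#' Generates `n_pairs` antisense piRNA-sized reads from the consensus; a
#' fraction of them receive a sense partner whose 5'-5' overlap is exactly
#' 10 nt (the ping-pong geometry), the remaining partners are placed
#' uniformly and independently. All reads are exact substrings (sense) or
#' reverse-complemented substrings (antisense) of the consensus.
#'
#' @param consensus Consensus sequence (string or single-row tibble).
#' @param n_pairs Number of antisense/sense read pairs.
#' @param pingpong_fraction Probability that a pair is ping-pong geometry.
#' @param length_range Read length window (default c(23, 29)).
#' @param seed RNG seed.
#' @return Read tibble (`id`, `desc`, `seq`).
#' @export
simulate_small_rnas <- function(consensus, n_pairs, pingpong_fraction,
                                length_range = c(23L, 29L), seed = 1L) {
  cons <- single_seq(consensus)
  clen <- nchar(cons)
  lmin <- length_range[1]; lmax <- length_range[2]
  stopifnot(clen >= 2L * lmax + 10L, pingpong_fraction >= 0,
            pingpong_fraction <= 1)
  if (n_pairs == 0) {
    return(tibble(id = character(), desc = character(), seq = character()))
  }
  with_seed(seed, {
    rows <- vector("list", 2L * n_pairs)
    for (i in seq_len(n_pairs)) {
      la <- sample(lmin:lmax, 1L)
      # antisense 5' end placed so that both partners always fit
      pa <- sample(seq(lmax, clen - lmax - 1L), 1L)  # 0-based 5' position
      anti <- revcomp(substr(cons, pa - la + 2L, pa + 1L))
      ls <- sample(lmin:lmax, 1L)
      if (runif(1) < pingpong_fraction) {
        ps <- pa - 9L                                 # 10 nt 5'-5' overlap
      } else {
        ps <- sample(seq(0L, clen - ls), 1L)
      }
      sense <- substr(cons, ps + 1L, ps + ls)
      rows[[2L * i - 1L]] <- tibble(id = sprintf("srna_%06d_a", i),
                                    desc = "", seq = anti)
      rows[[2L * i]] <- tibble(id = sprintf("srna_%06d_s", i),
                               desc = "", seq = sense)
    }
    bind_rows(rows)
  })
}

#' Define an invasion scenario
#'
#' @param origin_year Year the element first arrives anywhere.
#' @param origin_region Region of origin.
#' @param arrivals Tibble `region`, `arrival_year`, `rate` (logistic spread
#'   rate per year after arrival); every `arrival_year` must be at or after
#'   `origin_year`, and the origin region must arrive in `origin_year`.
#' @param sampling Tibble `year`, `region`, `n_samples` — the sampling plan.
#' @return A list of class `"invasion_scenario"`.
#' @export
invasion_scenario <- function(origin_year, origin_region, arrivals,
                              sampling) {
  stopifnot(all(arrivals$arrival_year >= origin_year))
  org <- arrivals$arrival_year[arrivals$region == origin_region]
  stopifnot(length(org) == 1L, org == origin_year)
  structure(
    list(origin_year = origin_year, origin_region = origin_region,
         arrivals = arrivals, sampling = sampling),
    class = "invasion_scenario"
  )
}

#' Simulate a sampled cohort under an invasion scenario
#'
#' Every sampled individual is TE-positive with probability
#' `plogis(rate * (year - arrival_year))` in its region — exactly 0 before
#' the regional arrival year — and the per-sample truth is recorded.
#'
#' @param scenario An [invasion_scenario()].
#' @param seed RNG seed.
#' @return A list: `meta` (tibble `sample_id`, `collection_year`, `region`,
#'   `source`), `truth` (tibble `sample_id`, `present`).
#' @export
simulate_invasion_cohort <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "invasion_scenario"))
  with_seed(seed, {
    plan <- scenario$sampling %>%
      left_join(scenario$arrivals, by = "region")
    rows <- list()
    n_tot <- 0L
    for (i in seq_len(nrow(plan))) {
      n <- plan$n_samples[i]
      if (n == 0) next
      p <- if (is.na(plan$arrival_year[i]) ||
               plan$year[i] < plan$arrival_year[i]) 0 else
        stats::plogis(plan$rate[i] * (plan$year[i] - plan$arrival_year[i]))
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = sprintf("s%04d", n_tot + seq_len(n)),
        collection_year = plan$year[i],
        region = plan$region[i],
        source = "simulated",
        present = runif(n) < p
      )
      n_tot <- n_tot + n
    }
    all <- bind_rows(rows)
    list(
      meta = select(all, "sample_id", "collection_year", "region", "source"),
      truth = select(all, "sample_id", "present")
    )
  })
}
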