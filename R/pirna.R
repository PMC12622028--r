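#' Map small RNAs to a TE consensus
#'
#' Places each adapter-trimmed small-RNA read of piRNA length (default
#' 23-29 nt) at every position of the consensus, on both strands, allowing
#' up to `max_mismatches` substitutions (no indels; a seed-free full scan is
#' fine at consensus scale). Multi-mapping reads are counted fractionally:
#' every placement carries weight 1 over the read's total number of
#' placements.
#'
#' @param reads Read tibble ([read_seqs()]).
#' @param consensus Consensus sequence (string or single-row tibble).
#' @param min_len,max_len piRNA length window in nt (defaults 23 and 29).
#' @param max_mismatches Substitution tolerance (default 2).
#' @return Tibble of class-tagged hits: `read_id`, `five_prime` (0-based
#'   position of the read's 5' end on the consensus: match start for sense
#'   hits, match end minus one for antisense hits), `strand`
#'   (`"sense"`/`"antisense"`), `length`, `weight`. The consensus length is
#'   stored in the `consensus_length` attribute.
#' @export
map_small_rnas <- function(reads, consensus, min_len = 23L, max_len = 29L,
                           max_mismatches = 2L) {
  cons <- single_seq(consensus)
  stopifnot(nchar(cons) > 0)
  subject <- Biostrings::DNAString(cons)
  keep <- nchar(reads$seq) >= min_len & nchar(reads$seq) <= max_len
  reads <- reads[keep, , drop = FALSE]
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rs <- reads$seq[i]
    sense <- Biostrings::matchPattern(rs, subject,
                                      max.mismatch = max_mismatches)
    anti <- Biostrings::matchPattern(revcomp(rs), subject,
                                     max.mismatch = max_mismatches)
    # mismatch-tolerant matching may propose placements overhanging the
    # consensus ends; keep only placements fully inside
    sense <- sense[Biostrings::start(sense) >= 1L &
                     Biostrings::end(sense) <= length(subject)]
    anti <- anti[Biostrings::start(anti) >= 1L &
                   Biostrings::end(anti) <= length(subject)]
    n_place <- length(sense) + length(anti)
    if (n_place == 0) next
    out[[i]] <- tibble(
      read_id = reads$id[i],
      five_prime = c(Biostrings::start(sense) - 1L,
                     Biostrings::end(anti) - 1L),
      strand = rep(c("sense", "antisense"),
                   c(length(sense), length(anti))),
      length = nchar(rs),
      weight = 1 / n_place
    )
  }
  hits <- bind_rows(out)
  if (nrow(hits) == 0) {
    hits <- tibble(read_id = character(), five_prime = integer(),
                   strand = character(), length = integer(),
                   weight = numeric())
  }
  attr(hits, "consensus_length") <- nchar(cons)
  hits
}

#' Ping-pong signature of a small-RNA hit set
#'
#' For every physically overlapping sense/antisense read pair, the offset is
#' the 5'-5' overlap length in nucleotides (antisense 5' position minus
#' sense 5' position, plus one). Weighted pair counts are accumulated for
#' offsets 1-20; ping-pong amplification puts its mass at offset 10, and the
#' signature is summarized as the z-score of the offset-10 count against the
#' other 19 offsets, plus the fraction of overlapping pairs at offset 10.
#'
#' @param hits Hit tibble from [map_small_rnas()].
#' @return A list of class `"pingpong_profile"`: `overlap_counts` (tibble
#'   `offset`, `count`), `zscore_at_10` (`NA` for an all-zero histogram,
#'   `Inf` when offset 10 carries mass but the other offsets have none),
#'   `fraction_at_10`, `total_pairs`, `n_sense`, `n_antisense` (weighted
#'   read counts).
#' @export
ping_pong_signature <- function(hits) {
  len <- attr(hits, "consensus_length")
  if (is.null(len)) {
    len <- if (nrow(hits) > 0) max(hits$five_prime) + 1L else 1L
  }
  s <- numeric(len)
  a <- numeric(len)
  sh <- filter(hits, .data$strand == "sense")
  ah <- filter(hits, .data$strand == "antisense")
  if (nrow(sh) > 0) {
    agg <- sh %>% group_by(.data$five_prime) %>%
      summarise(w = sum(.data$weight), .groups = "drop")
    s[agg$five_prime + 1L] <- agg$w
  }
  if (nrow(ah) > 0) {
    agg <- ah %>% group_by(.data$five_prime) %>%
      summarise(w = sum(.data$weight), .groups = "drop")
    a[agg$five_prime + 1L] <- agg$w
  }
  counts <- vapply(1:20, function(o) {
    idx <- seq_len(len - o + 1L)
    sum(s[idx] * a[idx + o - 1L])
  }, numeric(1))
  c10 <- counts[10]
  others <- counts[-10]
  # degenerate histograms: all-zero -> undefined; all mass at 10 (zero
  # spread elsewhere) -> maximal signature
  z <- if (all(counts == 0)) NA_real_
  else if (sd(others) == 0) sign(c10 - mean(others)) * Inf
  else (c10 - mean(others)) / sd(others)
  structure(
    list(
      overlap_counts = tibble(offset = 1:20, count = counts),
      zscore_at_10 = z,
      fraction_at_10 = if (sum(counts) > 0) c10 / sum(counts) else NA_real_,
      total_pairs = sum(counts),
      n_sense = sum(hits$weight[hits$strand == "sense"]),
      n_antisense = sum(hits$weight[hits$strand == "antisense"])
    ),
    class = "pingpong_profile"
  )
}

#' @export
print.pingpong_profile <- function(x, ...) {
  cat(sprintf("Ping-pong profile: %.1f sense / %.1f antisense weighted reads\n",
              x$n_sense, x$n_antisense))
  if (is.na(x$zscore_at_10)) {
    cat("  no overlapping pairs; z-score undefined\n")
  } else {
    cat(sprintf("  z-score at offset 10: %.2f (fraction %.3f of %.1f pairs)\n",
                x$zscore_at_10, x$fraction_at_10, x$total_pairs))
  }
  invisible(x)
}

#' Per-position sense/antisense small-RNA coverage of a consensus
#'
#' @param hits Hit tibble from [map_small_rnas()].
#' @return Tibble `pos` (0-based), `sense`, `antisense` (weighted 5'-end
#'   counts).
#' @export
small_rna_position_counts <- function(hits) {
  len <- attr(hits, "consensus_length")
  if (is.null(len)) len <- if (nrow(hits) > 0) max(hits$five_prime) + 1L else 0L
  base <- tibble(pos = seq_len(len) - 1L)
  agg <- hits %>%
    group_by(pos = .data$five_prime, strand = .data$strand) %>%
    summarise(w = sum(.data$weight), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "strand", values_from = "w")
  for (col in c("sense", "antisense")) {
    if (!col %in% names(agg)) agg[[col]] <- 0
  }
  base %>%
    left_join(agg, by = "pos") %>%
    mutate(sense = tidyr::replace_na(.data$sense, 0),
           antisense = tidyr::replace_na(.data$antisense, 0))
}
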