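#' Per-read alignment divergence
#'
#' Divergence of a mapped read from the reference is its edit distance (NM:
#' mismatches plus inserted plus deleted bases) divided by the aligned length
#' (CIGAR operations M/=/X/I/D). Soft- and hard-clipped bases enter neither
#' numerator nor denominator, so the ratio is always in \[0, 1\].
#'
#' @param alignments Alignment tibble ([read_sam()]).
#' @return The tibble with a `divergence` column appended.
#' @details Unmapped reads, or mapped reads without an NM tag, have no
#'   defined divergence; requesting it for such rows is an error.
#' @export
alignment_divergence <- function(alignments) {
  bad <- !alignments$is_mapped | is.na(alignments$edit_distance)
  if (any(bad)) {
    abort(sprintf(
      "divergence undefined for read '%s' (unmapped or missing NM tag)",
      alignments$query_id[which(bad)[1]]
    ), class = "teinvader_divergence_error")
  }
  mutate(alignments,
         divergence = .data$edit_distance / cigar_aligned_len(.data$cigar))
}

# fraction of a read soft-clipped, from its CIGAR
softclip_fraction <- function(cigar) {
  vapply(cigar, function(x) {
    p <- parse_cigar(x)
    if (p$query_span == 0L) return(0)
    sum(p$ops$len[p$ops$op == "S"]) / p$query_span
  }, numeric(1), USE.NAMES = FALSE)
}

#' Extract candidate reads for novel-TE discovery
#'
#' A read is a candidate when it is unmapped, or mapped with divergence
#' strictly greater than `thresholds$max_divergence` (optionally also when
#' heavily soft-clipped). Secondary and supplementary alignment records are
#' ignored; each read is emitted at most once, in read-store order.
#'
#' @param alignments Alignment tibble ([read_sam()]).
#' @param reads Read tibble ([read_seqs()]) keyed by `id`; every primary
#'   alignment's `query_id` must resolve here.
#' @param thresholds A [scan_thresholds()] object.
#' @return Tibble of candidate reads (columns of `reads`).
#' @export
select_candidate_reads <- function(alignments, reads,
                                   thresholds = scan_thresholds()) {
  aln <- filter(alignments, !.data$is_secondary)
  missing_ids <- setdiff(unique(aln$query_id), reads$id)
  if (length(missing_ids) > 0) {
    abort(sprintf("read '%s' referenced in alignments is absent from the read store",
                  missing_ids[1]), class = "teinvader_missing_read_error")
  }
  mapped <- filter(aln, .data$is_mapped, !is.na(.data$edit_distance))
  divergent <- character()
  if (nrow(mapped) > 0) {
    mapped <- alignment_divergence(mapped)
    keep <- mapped$divergence > thresholds$max_divergence
    if (!is.na(thresholds$min_softclip_fraction)) {
      keep <- keep |
        softclip_fraction(mapped$cigar) >= thresholds$min_softclip_fraction
    }
    divergent <- mapped$query_id[keep]
  }
  wanted <- unique(c(aln$query_id[!aln$is_mapped], divergent))
  filter(reads, .data$id %in% wanted)
}

#' Build a canonical k-mer contaminant index
#'
#' Stores the lexicographic minimum of each k-mer and its reverse complement
#' from one or more contaminant genomes; k-mers containing `N` are skipped.
#'
#' @param contaminants Sequence tibble ([read_seqs()]) of contaminant
#'   genomes.
#' @param k K-mer size (default 31).
#' @return A list of class `"contaminant_index"` with elements `k`,
#'   `kmer_set` (hashed environment) and `source_labels`.
#' @export
contaminant_index <- function(contaminants, k = 31L) {
  k <- as.integer(k)
  kmers <- seq_kmers(contaminants$seq, k)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  kmers <- unique(canonical(kmers))
  env <- new.env(hash = TRUE, parent = emptyenv(), size = max(length(kmers), 1L))
  for (km in kmers) assign(km, TRUE, envir = env)
  structure(
    list(k = k, kmer_set = env, source_labels = contaminants$id,
         n_kmers = length(kmers)),
    class = "contaminant_index"
  )
}

#' @export
print.contaminant_index <- function(x, ...) {
  cat(sprintf("Contaminant index: %d canonical %d-mers from %d sequence(s)\n",
              x$n_kmers, x$k, length(x$source_labels)))
  invisible(x)
}

#' Filter contaminant reads by canonical k-mer containment
#'
#' A read is dropped when the fraction of its canonical k-mers present in
#' the index reaches `thresholds$contaminant_hit_fraction`. Reads shorter
#' than k pass through untouched.
#'
#' @param reads Read tibble.
#' @param index A [contaminant_index()].
#' @param thresholds A [scan_thresholds()] object.
#' @return The reads tibble with contaminant rows removed.
#' @export
filter_contaminants <- function(reads, index,
                                thresholds = scan_thresholds()) {
  if (nrow(reads) == 0) return(reads)
  frac <- vapply(reads$seq, function(s) {
    kms <- seq_kmers(s, index$k)
    if (length(kms) == 0) return(0)
    hits <- sum(vapply(canonical(kms), exists, logical(1),
                       envir = index$kmer_set, inherits = FALSE))
    hits / length(kms)
  }, numeric(1), USE.NAMES = FALSE)
  reads[frac < thresholds$contaminant_hit_fraction, , drop = FALSE]
}
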