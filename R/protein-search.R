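#' Translated search of contigs against a TE protein library
#'
#' Each contig is translated in all six reading frames; stop codons split the
#' translations into peptides, and every peptide of at least `min_peptide_aa`
#' residues is locally aligned (Smith–Waterman, BLOSUM62, affine gaps: a gap
#' of length L costs `gap_open + L * gap_extend`) against every protein in
#' the library. Identity is matched residues over alignment columns, and the
#' nucleotide span is three times the number of aligned peptide residues.
#'
#' @param contigs Tibble with columns `id`, `seq` (DNA). Contigs shorter
#'   than 3 nt are skipped with a warning.
#' @param protein_db Tibble with columns `id`, `seq` (amino acids).
#' @param min_peptide_aa Minimum peptide length worth aligning (default 20).
#' @param gap_open,gap_extend Affine gap parameters (defaults 11 and 1).
#' @param min_score Hits scoring below this floor are discarded (default 40).
#' @return Tibble with one row per retained (contig, protein, peptide) local
#'   alignment: `contig_id`, `protein_id`, `identity` (percent), `span_nt`,
#'   `frame` (+1..+3 forward, -1..-3 reverse), `score`, and `is_best` marking
#'   the best-scoring hit of each contig (ties broken by protein id, then
#'   frame, for determinism).
#' @export
search_te_proteins <- function(contigs, protein_db,
                               min_peptide_aa = 20L,
                               gap_open = 11, gap_extend = 1,
                               min_score = 40) {
  stopifnot(nrow(protein_db) > 0)
  empty <- tibble(contig_id = character(), protein_id = character(),
                  identity = numeric(), span_nt = integer(),
                  frame = integer(), score = numeric(), is_best = logical())
  if (nrow(contigs) == 0) return(empty)
  short <- nchar(contigs$seq) < 3L
  if (any(short)) {
    warn(sprintf("skipping %d contig(s) shorter than 3 nt: %s",
                 sum(short), paste(contigs$id[short], collapse = ", ")))
    contigs <- contigs[!short, , drop = FALSE]
    if (nrow(contigs) == 0) return(empty)
  }
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  mat <- get("BLOSUM62", envir = data_env)
  prots <- Biostrings::AAStringSet(protein_db$seq)
  names(prots) <- protein_db$id

  # six-frame peptides of one contig, with stop-split
  frame_peptides <- function(seq) {
    fwd <- Biostrings::DNAString(seq)
    rev <- Biostrings::reverseComplement(fwd)
    out <- list()
    for (strand in c(1L, -1L)) {
      s <- if (strand == 1L) fwd else rev
      for (off in 0:2) {
        n_cod <- (length(s) - off) %/% 3L
        if (n_cod < 1L) next
        aa <- suppressWarnings(as.character(Biostrings::translate(
          Biostrings::subseq(s, off + 1L, off + 3L * n_cod),
          if.fuzzy.codon = "X"
        )))
        peps <- strsplit(aa, "*", fixed = TRUE)[[1]]
        keep <- nchar(peps) >= min_peptide_aa
        if (!any(keep)) next
        out[[length(out) + 1L]] <- tibble(
          frame = strand * (off + 1L),
          peptide = peps[keep]
        )
      }
    }
    if (length(out) == 0) tibble(frame = integer(), peptide = character())
    else bind_rows(out)
  }

  rows <- list()
  for (ci in seq_len(nrow(contigs))) {
    peps <- frame_peptides(contigs$seq[ci])
    if (nrow(peps) == 0) next
    pat <- Biostrings::AAStringSet(peps$peptide)
    for (pi in seq_len(length(prots))) {
      aln <- Biostrings::pairwiseAlignment(
        pat, prots[[pi]], type = "local", substitutionMatrix = mat,
        gapOpening = gap_open, gapExtension = gap_extend
      )
      sc <- Biostrings::score(aln)
      ok <- which(sc >= min_score)
      if (length(ok) == 0) next
      pat_aln <- as.character(Biostrings::pattern(aln))[ok]
      ncol_aln <- nchar(pat_aln)
      nmat <- Biostrings::nmatch(aln)[ok]
      q_res <- nchar(gsub("-", "", pat_aln, fixed = TRUE))
      rows[[length(rows) + 1L]] <- tibble(
        contig_id = contigs$id[ci],
        protein_id = protein_db$id[pi],
        identity = 100 * nmat / ncol_aln,
        span_nt = 3L * q_res,
        frame = peps$frame[ok],
        score = sc[ok]
      )
    }
  }
  if (length(rows) == 0) return(empty)
  hits <- bind_rows(rows) %>%
    arrange(.data$contig_id, desc(.data$score), .data$protein_id, .data$frame)
  hits %>%
    group_by(.data$contig_id) %>%
    mutate(is_best = row_number() == 1L) %>%
    ungroup()
}

#' Filter translated-search hits into retained TE candidates
#'
#' A contig is retained when its best hit strictly exceeds both the identity
#' and the nucleotide-span threshold (`> 80`% and `> 250` bp by default,
#' both strict). One row per retained contig, sorted by score descending
#' (ties broken lexicographically by contig then protein id).
#'
#' @param hits Hit tibble from [search_te_proteins()].
#' @param contigs Contig tibble (to carry sequence and support counts).
#' @param thresholds A [scan_thresholds()] object.
#' @return Tibble of candidate contigs: `id`, `seq`, `length`,
#'   `supporting_read_count`, `best_hit`, `identity`, `span_nt`, `frame`,
#'   `score`.
#' @export
filter_te_candidates <- function(hits, contigs,
                                 thresholds = scan_thresholds()) {
  empty <- tibble(id = character(), seq = character(), length = integer(),
                  supporting_read_count = integer(), best_hit = character(),
                  identity = numeric(), span_nt = integer(),
                  frame = integer(), score = numeric())
  if (nrow(hits) == 0) return(empty)
  passing <- hits %>%
    filter(.data$identity > thresholds$min_protein_identity,
           .data$span_nt > thresholds$min_alignment_span_nt) %>%
    arrange(desc(.data$score), .data$contig_id, .data$protein_id) %>%
    distinct(.data$contig_id, .keep_all = TRUE)
  if (nrow(passing) == 0) return(empty)
  support <- if ("supporting_read_count" %in% names(contigs)) {
    contigs$supporting_read_count
  } else rep(NA_integer_, nrow(contigs))
  passing %>%
    left_join(
      tibble(contig_id = contigs$id, seq = contigs$seq,
             length = nchar(contigs$seq), supporting_read_count = support),
      by = "contig_id"
    ) %>%
    transmute_candidates()
}

transmute_candidates <- function(x) {
  tibble(
    id = x$contig_id, seq = x$seq, length = x$length,
    supporting_read_count = x$supporting_read_count,
    best_hit = x$protein_id, identity = x$identity, span_nt = x$span_nt,
    frame = x$frame, score = x$score
  )
}
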