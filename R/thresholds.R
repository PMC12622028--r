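#' Thresholds for the novel-TE discovery pipeline
#'
#' Collects every tunable of the discovery stages in one validated object.
#' Defaults follow the published workflow: reads with more than 5% sequence
#' divergence from the reference are treated as candidates, and assembled
#' contigs are retained only when their best TE-protein hit exceeds 80%
#' identity over more than 250 nt.
#'
#' @param max_divergence Mapped reads with divergence strictly above this
#'   fraction are extracted as candidates (default 0.05).
#' @param min_protein_identity Percent identity a contig's protein hit must
#'   strictly exceed (default 80).
#' @param min_alignment_span_nt Nucleotide span a contig's protein hit must
#'   strictly exceed (default 250).
#' @param assembler_k Odd k-mer size of the de Bruijn assembler (default 31).
#' @param assembler_min_kmer_coverage Minimum k-mer count kept in the
#'   assembly graph (default 2).
#' @param assembler_branch_ratio At a graph branch, edges whose k-mer count
#'   falls below this fraction of the best sibling are ignored (default 0.2);
#'   removes sequencing-error side branches without popping true bubbles.
#' @param contaminant_k K-mer size of the contaminant index (default 31).
#' @param contaminant_hit_fraction A read is dropped when at least this
#'   fraction of its canonical k-mers occurs in the contaminant index
#'   (default 0.5).
#' @param min_softclip_fraction Optional "poorly mapped" rule: when not `NA`,
#'   mapped reads with at least this fraction of soft-clipped bases are also
#'   extracted (default `NA`, off).
#' @return A list of class `"scan_thresholds"`.
#' @export
scan_thresholds <- function(max_divergence = 0.05,
                            min_protein_identity = 80,
                            min_alignment_span_nt = 250,
                            assembler_k = 31L,
                            assembler_min_kmer_coverage = 2L,
                            assembler_branch_ratio = 0.2,
                            contaminant_k = 31L,
                            contaminant_hit_fraction = 0.5,
                            min_softclip_fraction = NA_real_) {
  stopifnot(
    max_divergence > 0, max_divergence < 1,
    min_protein_identity > 0, min_protein_identity <= 100,
    min_alignment_span_nt >= 0,
    assembler_k >= 11L, assembler_k %% 2L == 1L,
    assembler_min_kmer_coverage >= 1L,
    assembler_branch_ratio >= 0, assembler_branch_ratio <= 1,
    contaminant_k >= 11L,
    contaminant_hit_fraction > 0, contaminant_hit_fraction <= 1
  )
  structure(
    list(
      max_divergence = max_divergence,
      min_protein_identity = min_protein_identity,
      min_alignment_span_nt = min_alignment_span_nt,
      assembler_k = as.integer(assembler_k),
      assembler_min_kmer_coverage = as.integer(assembler_min_kmer_coverage),
      assembler_branch_ratio = assembler_branch_ratio,
      contaminant_k = as.integer(contaminant_k),
      contaminant_hit_fraction = contaminant_hit_fraction,
      min_softclip_fraction = min_softclip_fraction
    ),
    class = "scan_thresholds"
  )
}

#' @export
print.scan_thresholds <- function(x, ...) {
  cat("Novel-TE scan thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
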