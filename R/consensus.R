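#' Read an aligned FASTA multiple sequence alignment
#'
#' @param path Aligned FASTA; all rows must share one length and the
#'   alignment must have at least two rows.
#' @return Tibble with columns `id`, `seq` (gapped, upper case) and an
#'   attribute `column_count`.
#' @export
read_msa <- function(path) {
  msa <- read_seqs(path, format = "fasta")
  validate_msa(msa)
}

validate_msa <- function(msa) {
  if (nrow(msa) < 2) abort("an alignment needs at least 2 rows")
  w <- unique(nchar(msa$seq))
  if (length(w) != 1) {
    abort(sprintf("alignment rows differ in length (%s)",
                  paste(w, collapse = ", ")))
  }
  attr(msa, "column_count") <- w
  msa
}

#' Majority-rule consensus of a multiple sequence alignment
#'
#' Assigns to each alignment column the most frequent nucleotide among
#' A/C/G/T (`N` never counts; ties broken in fixed alphabet order
#' A < C < G < T). Columns in which the gap is the single most frequent
#' symbol are dropped, so the consensus is ungapped; columns containing only
#' `N`/gap symbols (with the gap not in the majority) are emitted as `N`.
#' A per-column occupancy table makes segmental presence/absence variants
#' among the insertions visible instead of silently resolving them.
#'
#' @param msa Alignment tibble ([read_msa()]); gaps are `-`.
#' @return A list of class `"te_consensus"`: `consensus` (single-row
#'   sequence tibble) and `columns` (tibble with `position` on the
#'   consensus, `alignment_column`, `occupancy` = non-gap fraction, `base`).
#' @export
majority_consensus <- function(msa) {
  msa <- validate_msa(msa)
  mat <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(msa$seq))
  bases <- c("A", "C", "G", "T")
  base_counts <- mat[bases, , drop = FALSE]
  gap_counts <- if ("-" %in% rownames(mat)) mat["-", ] else rep(0L, ncol(mat))
  n_counts <- if ("N" %in% rownames(mat)) mat["N", ] else rep(0L, ncol(mat))
  top_base_count <- apply(base_counts, 2L, max)
  # a column survives unless the gap is strictly the most frequent symbol
  # (N counts as a symbol here even though it never wins a base call)
  keep <- gap_counts <= pmax(top_base_count, n_counts)
  only_missing <- top_base_count == 0
  call <- bases[apply(base_counts, 2L, which.max)]
  call[only_missing] <- "N"
  if (any(only_missing & keep)) {
    warn(sprintf("%d column(s) contain only N/gap symbols; emitted as N",
                 sum(only_missing & keep)))
  }
  cols <- which(keep)
  occupancy <- colSums(mat[setdiff(rownames(mat), "-"), cols, drop = FALSE]) /
    nrow(msa)
  list(
    consensus = tibble(id = "consensus", desc = "",
                       seq = paste(call[cols], collapse = "")),
    columns = tibble(
      position = seq_along(cols) - 1L,
      alignment_column = cols,
      occupancy = as.numeric(occupancy),
      base = call[cols]
    )
  ) |> structure(class = "te_consensus")
}

#' @export
print.te_consensus <- function(x, ...) {
  cat(sprintf("Majority-rule consensus: %d bp (%d of %d alignment columns kept)\n",
              nchar(x$consensus$seq),
              nrow(x$columns),
              max(x$columns$alignment_column)))
  lowocc <- sum(x$columns$occupancy < 0.5)
  if (lowocc > 0) {
    cat(sprintf("  %d consensus position(s) with occupancy < 0.5 (segmental variant?)\n",
                lowocc))
  }
  invisible(x)
}
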