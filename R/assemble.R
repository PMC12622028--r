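#' Assemble reads into unitigs with a de Bruijn graph
#'
#' Minimal, deterministic de Bruijn assembler: canonical k-mers are counted,
#' k-mers below `assembler_min_kmer_coverage` are removed, and contigs are
#' the maximal unambiguous paths (unitigs) of the remaining graph. At branch
#' points, edges whose k-mer count is below `assembler_branch_ratio` times
#' the best sibling are ignored, which removes sequencing-error side
#' branches (their abundance is bounded by the error rate) while leaving
#' genuine equal-abundance branches intact. No bubble popping and no
#' scaffolding. Contigs shorter than `2k` are dropped; output order is
#' length descending, then sequence, and each contig is reported in its
#' canonical orientation, so output is reproducible.
#'
#' @param reads Read tibble ([read_seqs()]); k-mers containing `N` are
#'   skipped.
#' @param thresholds A [scan_thresholds()] object (fields `assembler_k`,
#'   `assembler_min_kmer_coverage`, `assembler_branch_ratio`).
#' @return Tibble with columns `id`, `seq`, `length`, `mean_kmer_coverage`,
#'   `supporting_read_count` (reads sharing at least one k-mer with the
#'   contig).
#' @export
assemble_contigs <- function(reads, thresholds = scan_thresholds()) {
  k <- thresholds$assembler_k
  min_cov <- thresholds$assembler_min_kmer_coverage
  ratio <- thresholds$assembler_branch_ratio
  empty <- tibble(id = character(), seq = character(), length = integer(),
                  mean_kmer_coverage = numeric(),
                  supporting_read_count = integer())
  if (nrow(reads) == 0) return(empty)

  per_read <- lapply(reads$seq, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    km <- substring(s, 1:(n - k + 1L), k:n)
    km[!grepl("N", km, fixed = TRUE)]
  })
  all_kmers <- unlist(per_read, use.names = FALSE)
  if (length(all_kmers) == 0) return(empty)
  all_canon <- canonical(all_kmers)
  counts <- table(all_canon)
  keep <- counts >= min_cov
  if (!any(keep)) return(empty)
  K <- names(counts)[keep]                     # canonical k-mers, sorted
  cnt <- as.integer(counts[keep])
  m <- length(K)

  # oriented vertex set: canonical forms first, reverse complements after
  O <- c(K, revcomp(K))
  ocnt <- c(cnt, cnt)
  rc_idx <- c(seq_len(m) + m, seq_len(m))

  # successor candidates of every oriented k-mer (suffix + base)
  suff <- substring(O, 2L, k)
  bases <- c("A", "C", "G", "T")
  succ <- matrix(NA_integer_, nrow = 2L * m, ncol = 4L)
  for (b in seq_len(4L)) {
    succ[, b] <- match(paste0(suff, bases[b]), O)
  }

  # unique successor after relative-abundance pruning (NA if 0 or >1 remain)
  usucc <- rep(NA_integer_, 2L * m)
  scnt <- matrix(ocnt[succ], nrow = 2L * m)
  smax <- suppressWarnings(apply(scnt, 1L, max, na.rm = TRUE))
  for (i in which(is.finite(smax))) {
    ok <- which(!is.na(scnt[i, ]) & scnt[i, ] >= ratio * smax[i])
    if (length(ok) == 1L) usucc[i] <- succ[i, ok]
  }

  # u -> v is a unitig extension iff v is u's unique successor and u is v's
  # unique predecessor (checked through the reverse complement)
  can_extend <- function(u) {
    v <- usucc[u]
    if (is.na(v)) return(NA_integer_)
    back <- usucc[rc_idx[v]]
    if (is.na(back) || rc_idx[back] != u) return(NA_integer_)
    v
  }

  visited <- rep(FALSE, m)
  canon_of <- function(o) if (o > m) o - m else o
  walk <- function(start) {
    path <- integer(0)
    node <- start
    repeat {
      path <- c(path, node)
      visited[canon_of(node)] <<- TRUE
      nxt <- can_extend(node)
      if (is.na(nxt) || visited[canon_of(nxt)]) break
      node <- nxt
    }
    path
  }

  # linear unitigs start where backward extension is impossible
  is_start <- vapply(seq_len(2L * m), function(o) {
    nxt_back <- usucc[rc_idx[o]]
    if (is.na(nxt_back)) return(TRUE)
    pred <- rc_idx[nxt_back]
    na_v <- can_extend(pred)
    is.na(na_v) || na_v != o
  }, logical(1))

  paths <- list()
  for (o in which(is_start)) {
    if (visited[canon_of(o)]) next
    paths[[length(paths) + 1L]] <- walk(o)
  }
  # anything left is purely cyclic
  for (i in which(!visited)) {
    if (visited[i]) next
    paths[[length(paths) + 1L]] <- walk(i)
  }
  if (length(paths) == 0) return(empty)

  seqs <- vapply(paths, function(p) {
    paste0(O[p[1]], paste(substring(O[p[-1]], k, k), collapse = ""))
  }, character(1))
  covs <- vapply(paths, function(p) mean(ocnt[p]), numeric(1))
  seqs_c <- canonical(seqs)
  contigs <- tibble(seq = seqs_c, length = nchar(seqs_c),
                    mean_kmer_coverage = covs) %>%
    filter(.data$length >= 2L * k) %>%
    distinct(.data$seq, .keep_all = TRUE) %>%
    arrange(desc(.data$length), .data$seq) %>%
    mutate(id = sprintf("contig_%d", row_number()))
  if (nrow(contigs) == 0) return(empty)

  # supporting reads: reads sharing >= 1 canonical k-mer with the contig
  contig_kmers <- lapply(contigs$seq, function(s)
    unique(canonical(seq_kmers(s, k))))
  ck <- unlist(contig_kmers, use.names = FALSE)
  ck_contig <- rep(seq_len(nrow(contigs)), lengths(contig_kmers))
  read_id_per_kmer <- rep(seq_along(per_read), lengths(per_read))
  hit <- match(all_canon, ck)
  ok <- !is.na(hit)
  pairs <- unique(data.frame(read = read_id_per_kmer[ok],
                             contig = ck_contig[hit[ok]]))
  support <- tabulate(pairs$contig, nbins = nrow(contigs))
  contigs %>%
    mutate(supporting_read_count = support) %>%
    select("id", "seq", "length", "mean_kmer_coverage",
           "supporting_read_count")
}
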