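#' Read sequences from FASTA or FASTQ
#'
#' Returns one row per record with residues upper-cased and multi-line FASTA
#' bodies concatenated. Gzipped files are handled transparently.
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"` or `"fastq"`; default guessed from the extension.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header), `desc` (remainder of the header, `""` if none), `seq`, and for
#'   FASTQ `qual` (phred string, same length as `seq`).
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  if (!file.exists(path)) {
    abort(sprintf("sequence file not found: %s", path))
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    hdr <- names(ss)
    tibble(
      id = sub("\\s.*$", "", hdr),
      desc = ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), ""),
      seq = toupper(as.character(ss, use.names = FALSE))
    )
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) %% 4L != 0L) {
      abort(sprintf("FASTQ %s: line count not a multiple of 4", path))
    }
    i <- seq(1L, length(lines), by = 4L)
    hdr <- lines[i]
    if (any(substr(hdr, 1, 1) != "@")) {
      abort(sprintf("FASTQ %s: malformed header line", path))
    }
    hdr <- sub("^@", "", hdr)
    seqs <- toupper(lines[i + 1L])
    qual <- lines[i + 3L]
    bad <- which(nchar(qual) != nchar(seqs))
    if (length(bad) > 0) {
      abort(sprintf(
        "FASTQ %s: quality length differs from sequence length for record '%s'",
        path, sub("\\s.*$", "", hdr[bad[1]])
      ), class = "teinvader_format_error")
    }
    tibble(
      id = sub("\\s.*$", "", hdr),
      desc = ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), ""),
      seq = seqs,
      qual = qual
    )
  }
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs Tibble with columns `id`, `seq`, optionally `desc` and (for
#'   FASTQ) `qual`. Missing qualities are written as `"I"` runs.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_seqs <- function(seqs, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  hdr <- seqs$id
  if ("desc" %in% names(seqs)) {
    hdr <- ifelse(nzchar(seqs$desc), paste(seqs$id, seqs$desc), seqs$id)
  }
  if (format == "fasta") {
    ss <- Biostrings::BStringSet(seqs$seq)
    names(ss) <- hdr
    Biostrings::writeXStringSet(ss, path)
  } else {
    qual <- if ("qual" %in% names(seqs)) seqs$qual else
      strrep("I", nchar(seqs$seq))
    writeLines(
      as.vector(rbind(paste0("@", hdr), seqs$seq, "+", qual)),
      path
    )
  }
  invisible(path)
}

#' Read alignments from a text SAM file
#'
#' Parses the 11 mandatory SAM columns plus the `NM:i:` tag. The header is
#' optional; `@SQ` lines, when present, are exposed through the
#' `reference_lengths` attribute. Flag bit 0x4 marks unmapped reads, 0x10 the
#' reverse strand, 0x100/0x800 secondary/supplementary records.
#'
#' @param path Path to a SAM text file.
#' @return A tibble with columns `query_id`, `flag`, `reference_id`, `pos`
#'   (1-based leftmost), `mapq`, `cigar`, `seq`, `qual`, `edit_distance`
#'   (`NA` when no NM tag), `is_mapped`, `strand` (`"+"`/`"-"`),
#'   `is_secondary`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) abort(sprintf("SAM file not found: %s", path))
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  ref_len <- integer()
  sq <- lines[is_hdr & startsWith(lines, "@SQ")]
  if (length(sq) > 0) {
    fields <- strsplit(sq, "\t", fixed = TRUE)
    sn <- vapply(fields, function(f)
      sub("^SN:", "", grep("^SN:", f, value = TRUE)[1]), character(1))
    ln <- vapply(fields, function(f)
      as.integer(sub("^LN:", "", grep("^LN:", f, value = TRUE)[1])),
      integer(1))
    ref_len <- setNames(ln, sn)
  }
  body <- lines[!is_hdr & nzchar(lines)]
  if (length(body) == 0) {
    out <- tibble(
      query_id = character(), flag = integer(), reference_id = character(),
      pos = integer(), mapq = integer(), cigar = character(),
      seq = character(), qual = character(), edit_distance = integer(),
      is_mapped = logical(), strand = character(), is_secondary = logical()
    )
    attr(out, "reference_lengths") <- ref_len
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    ln_no <- which(!is_hdr & nzchar(lines))[which(nf < 11L)[1]]
    abort(sprintf("SAM %s line %d: fewer than 11 columns", path, ln_no),
          class = "teinvader_format_error")
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(col(2))
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag) == 0) NA_integer_ else as.integer(sub("^NM:i:", "", tag[1]))
  }, integer(1))
  out <- tibble(
    query_id = col(1),
    flag = flag,
    reference_id = col(3),
    pos = as.integer(col(4)),
    mapq = as.integer(col(5)),
    cigar = col(6),
    seq = toupper(col(10)),
    qual = col(11),
    edit_distance = nm,
    is_mapped = bitwAnd(flag, 4L) == 0L,
    strand = ifelse(bitwAnd(flag, 16L) == 0L, "+", "-"),
    is_secondary = bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L
  )
  attr(out, "reference_lengths") <- ref_len
  out
}

#' Write alignments to a text SAM file
#'
#' Inverse of [read_sam()]; used by the synthetic read simulator to emit
#' truth alignments.
#'
#' @param alignments Tibble as returned by [read_sam()] (columns `seq` and
#'   `qual` optional; `edit_distance` written as an `NM:i:` tag when not
#'   `NA`).
#' @param path Output path.
#' @param reference_lengths Named integer vector for `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, reference_lengths = NULL) {
  if (is.null(reference_lengths)) {
    reference_lengths <- attr(alignments, "reference_lengths")
  }
  hdr <- "@HD\tVN:1.6\tSO:unknown"
  if (length(reference_lengths) > 0) {
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d",
                          names(reference_lengths), reference_lengths))
  }
  seq <- if ("seq" %in% names(alignments)) alignments$seq else
    rep("*", nrow(alignments))
  qual <- if ("qual" %in% names(alignments)) alignments$qual else
    rep("*", nrow(alignments))
  nm <- ifelse(is.na(alignments$edit_distance), "",
               sprintf("\tNM:i:%d", alignments$edit_distance))
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
    alignments$query_id, alignments$flag, alignments$reference_id,
    alignments$pos, alignments$mapq, alignments$cigar, seq, qual, nm
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path TSV with header columns `sample_id`, `collection_year`,
#'   `region` (extra columns preserved).
#' @return A tibble; `collection_year` is validated against \[1700, current
#'   year\].
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "collection_year", "region")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    abort(sprintf("metadata %s: missing columns %s", path,
                  paste(miss, collapse = ", ")))
  }
  yr <- meta$collection_year
  bad <- which(yr < 1700 | yr > as.integer(format(Sys.Date(), "%Y")))
  if (length(bad) > 0) {
    abort(sprintf("metadata %s: implausible collection_year for sample '%s'",
                  path, meta$sample_id[bad[1]]))
  }
  meta
}

#' Write annotation features as GFF3
#'
#' Converts 0-based half-open feature coordinates (the package-internal
#' convention) to the 1-based closed GFF3 convention at this boundary.
#'
#' @param features Tibble with columns `seqid`, `type`, `start`, `end`
#'   (0-based half-open), optional `strand`, `score`, `attributes`.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "teinvader") {
  has <- function(col) col %in% names(features)
  strand <- if (has("strand")) features$strand else rep(".", nrow(features))
  score <- if (has("score"))
    ifelse(is.na(features$score), ".", format(features$score))
  else rep(".", nrow(features))
  attrs <- if (has("attributes")) features$attributes
  else rep(".", nrow(features))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                   features$seqid, source, features$type,
                   features$start + 1L, features$end, score, strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# -- small sequence utilities used across modules -----------------------------

#' Reverse complement of DNA strings
#'
#' `N` is its own complement. Vectorized over `x`.
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)),
               use.names = FALSE)
}

# canonical form: lexicographic minimum of a sequence and its reverse
# complement
canonical <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# all k-mers of each sequence, concatenated; sequences shorter than k
# contribute none
seq_kmers <- function(x, k) {
  unlist(lapply(x, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
}
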