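#' Configuration for a novel-TE discovery run
#'
#' Bundles inputs and thresholds. Inputs may be file paths (read with the
#' package's format readers) or in-memory tibbles; paths are checked before
#' any computation starts.
#'
#' @param alignments SAM path or alignment tibble (reads mapped to the
#'   reference genome).
#' @param reads FASTQ/FASTA path or read tibble (the read store).
#' @param te_proteins FASTA path or tibble of TE proteins (amino acids).
#' @param contaminants Optional FASTA path(s) or tibble of contaminant
#'   genomes.
#' @param thresholds A [scan_thresholds()] object.
#' @return A list of class `"scan_config"`.
#' @export
scan_config <- function(alignments, reads, te_proteins,
                        contaminants = NULL,
                        thresholds = scan_thresholds()) {
  for (nm in c("alignments", "reads", "te_proteins")) {
    x <- get(nm)
    if (is.character(x) && !all(file.exists(x))) {
      abort(sprintf("configuration error: %s file not found: %s", nm,
                    paste(x[!file.exists(x)], collapse = ", ")))
    }
  }
  if (is.character(contaminants) && !all(file.exists(contaminants))) {
    abort(sprintf("configuration error: contaminants file not found: %s",
                  paste(contaminants[!file.exists(contaminants)],
                        collapse = ", ")))
  }
  stopifnot(inherits(thresholds, "scan_thresholds"))
  structure(
    list(alignments = alignments, reads = reads, te_proteins = te_proteins,
         contaminants = contaminants, thresholds = thresholds),
    class = "scan_config"
  )
}

#' Discover novel, reference-absent TE candidates
#'
#' Runs the discovery stages in order: candidate read selection (unmapped or
#' divergent reads), contaminant filtering, de Bruijn unitig assembly,
#' six-frame translated search against the TE protein library, and the
#' identity/span candidate filter. The report keeps a conserved per-stage
#' read ledger (`reads_in = reads_out + reads_dropped` at every stage), and
#' an empty candidate list is a clean result, not an error.
#'
#' @param config A [scan_config()].
#' @return A list of class `"te_scan_report"`: `candidates` (tibble from
#'   [filter_te_candidates()]), `contigs`, `hits`, `stages` (tibble `stage`,
#'   `reads_in`, `reads_out`, `reads_dropped`), `thresholds`.
#' @export
detect_novel_te <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  th <- config$thresholds
  aln <- if (is.character(config$alignments)) read_sam(config$alignments)
  else config$alignments
  reads <- if (is.character(config$reads)) read_seqs(config$reads)
  else config$reads
  prots <- if (is.character(config$te_proteins)) read_seqs(config$te_proteins)
  else config$te_proteins
  if (nrow(prots) == 0) abort("configuration error: empty TE protein library")

  stages <- list()
  note <- function(stage, n_in, n_out) {
    stages[[length(stages) + 1L]] <<- tibble(
      stage = stage, reads_in = n_in, reads_out = n_out,
      reads_dropped = n_in - n_out
    )
  }

  candidates_reads <- select_candidate_reads(aln, reads, th)
  note("select_candidate_reads", nrow(reads), nrow(candidates_reads))

  if (!is.null(config$contaminants)) {
    cont <- if (is.character(config$contaminants)) {
      bind_rows(lapply(config$contaminants, read_seqs))
    } else config$contaminants
    idx <- contaminant_index(cont, k = th$contaminant_k)
    filtered <- filter_contaminants(candidates_reads, idx, th)
  } else {
    filtered <- candidates_reads
  }
  note("filter_contaminants", nrow(candidates_reads), nrow(filtered))

  contigs <- assemble_contigs(filtered, th)
  hits <- search_te_proteins(contigs, prots)
  candidates <- filter_te_candidates(hits, contigs, th)

  structure(
    list(candidates = candidates, contigs = contigs, hits = hits,
         stages = bind_rows(stages), thresholds = th),
    class = "te_scan_report"
  )
}

#' @export
print.te_scan_report <- function(x, ...) {
  cat("Novel-TE scan report\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-24s %6d -> %6d reads (%d dropped)\n",
                x$stages$stage[i], x$stages$reads_in[i],
                x$stages$reads_out[i], x$stages$reads_dropped[i]))
  }
  cat(sprintf("  contigs assembled: %d\n", nrow(x$contigs)))
  cat(sprintf("  candidates retained: %d\n", nrow(x$candidates)))
  if (nrow(x$candidates) > 0) {
    for (i in seq_len(nrow(x$candidates))) {
      cat(sprintf("    %s: %d bp, best hit %s (%.1f%% over %d nt)\n",
                  x$candidates$id[i], x$candidates$length[i],
                  x$candidates$best_hit[i], x$candidates$identity[i],
                  x$candidates$span_nt[i]))
    }
  }
  invisible(x)
}

#' Write a scan report to an output directory
#'
#' Writes `candidates.fasta`, `candidates.tsv` and `stages.tsv`.
#'
#' @param report A [detect_novel_te()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scan_report <- function(report, dir) {
  stopifnot(inherits(report, "te_scan_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (nrow(report$candidates) > 0) {
    write_seqs(report$candidates, file.path(dir, "candidates.fasta"))
  } else {
    writeLines(character(), file.path(dir, "candidates.fasta"))
  }
  readr::write_tsv(select(report$candidates, -"seq"),
                   file.path(dir, "candidates.tsv"))
  readr::write_tsv(report$stages, file.path(dir, "stages.tsv"))
  invisible(dir)
}
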