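#' Per-position coverage profiles from alignments
#'
#' Pileup depth per reference position: a position is covered by every
#' mapped, primary read whose reference-consuming CIGAR span (M/D/N/=/X)
#' overlaps it — deletions count as covered, clipped bases do not.
#'
#' @param alignments Alignment tibble ([read_sam()]).
#' @param reference_lengths Named integer vector of reference lengths;
#'   defaults to the `@SQ` header stored on the alignment tibble.
#' @return Tibble with columns `reference_id`, `pos` (0-based), `depth`,
#'   one row per position of every reference in `reference_lengths`.
#' @export
coverage_profile <- function(alignments, reference_lengths = NULL) {
  if (is.null(reference_lengths)) {
    reference_lengths <- attr(alignments, "reference_lengths")
  }
  if (is.null(reference_lengths) || length(reference_lengths) == 0) {
    abort("reference_lengths required (none stored on the alignments)")
  }
  aln <- filter(alignments, .data$is_mapped, !.data$is_secondary)
  unknown <- setdiff(unique(aln$reference_id), names(reference_lengths))
  if (length(unknown) > 0) {
    abort(sprintf("alignments reference unknown sequence '%s'", unknown[1]))
  }
  aln$ref_span <- cigar_ref_span(aln$cigar)
  over <- aln$pos + aln$ref_span - 1L > reference_lengths[aln$reference_id]
  if (any(over)) {
    abort(sprintf("read '%s' aligns past the end of reference '%s'",
                  aln$query_id[which(over)[1]],
                  aln$reference_id[which(over)[1]]))
  }
  purrr::map_dfr(names(reference_lengths), function(ref) {
    len <- reference_lengths[[ref]]
    sub <- aln[aln$reference_id == ref & aln$ref_span > 0L, , drop = FALSE]
    depth <- if (nrow(sub) == 0) {
      integer(len)
    } else {
      as.integer(IRanges::coverage(
        IRanges::IRanges(start = sub$pos, width = sub$ref_span),
        width = len
      ))
    }
    tibble(reference_id = ref, pos = seq_len(len) - 1L, depth = depth)
  })
}

#' Normalize TE coverage by single-copy-gene coverage
#'
#' Converts raw TE depth into haploid copy units by dividing every position
#' by the mean depth pooled over all single-copy-gene (SCG) positions. The
#' profile mean is the copy-number estimate: a TE present in c copies per
#' haploid genome attracts c times the depth of a single-copy gene.
#'
#' @param te Coverage tibble ([coverage_profile()]) for the TE consensus
#'   (one reference).
#' @param scgs Coverage tibble for one or more single-copy genes.
#' @param summary `"mean"` (default) or `"median"` position summary for the
#'   copy-number point estimate (median is robust to internal deletions).
#' @return A list of class `"normalized_profile"`: `profile` (tibble
#'   `reference_id`, `pos`, `depth`, `normalized_depth`), `scg_factor`,
#'   `copy_number` (summary of normalized depth), `copy_number_max`.
#' @export
normalize_by_scg <- function(te, scgs, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  stopifnot(length(unique(te$reference_id)) == 1L, nrow(scgs) > 0)
  scg_factor <- mean(scgs$depth)
  if (scg_factor == 0) {
    abort("single-copy-gene depth is zero everywhere; normalization undefined",
          class = "teinvader_normalization_error")
  }
  prof <- mutate(te, normalized_depth = .data$depth / scg_factor)
  cn <- if (summary == "mean") mean(prof$normalized_depth) else
    stats::median(prof$normalized_depth)
  structure(
    list(profile = prof, scg_factor = scg_factor, copy_number = cn,
         copy_number_max = max(prof$normalized_depth), summary = summary),
    class = "normalized_profile"
  )
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("Normalized coverage profile: %s (%d bp)\n",
              x$profile$reference_id[1], nrow(x$profile)))
  cat(sprintf("  SCG factor %.2f; copy number (%s) %.2f; max %.2f\n",
              x$scg_factor, x$summary, x$copy_number, x$copy_number_max))
  invisible(x)
}

#' Presence call from a normalized coverage profile
#'
#' A TE family is called present in a sample when at least
#' `breadth_threshold` (default 90%) of its consensus positions have
#' normalized coverage strictly greater than `depth_threshold` (default 1).
#' The depth comparison is strict, the breadth comparison inclusive.
#'
#' @param profile A [normalize_by_scg()] result.
#' @param sample_id Sample label for the output row.
#' @param breadth_threshold Fraction of positions required (default 0.9).
#' @param depth_threshold Normalized depth a position must exceed
#'   (default 1).
#' @return One-row tibble: `sample_id`, `copy_number`, `copy_number_max`,
#'   `breadth_above_one`, `present`.
#' @export
call_presence <- function(profile, sample_id = "sample",
                          breadth_threshold = 0.9, depth_threshold = 1.0) {
  stopifnot(inherits(profile, "normalized_profile"),
            nrow(profile$profile) > 0)
  breadth <- mean(profile$profile$normalized_depth > depth_threshold)
  tibble(
    sample_id = sample_id,
    copy_number = profile$copy_number,
    copy_number_max = profile$copy_number_max,
    breadth_above_one = breadth,
    present = breadth >= breadth_threshold
  )
}

#' Copy number and presence from a SAM file in one step
#'
#' Convenience wrapper: pileup over the TE consensus and the SCG references,
#' normalization, presence call.
#'
#' @param alignments Alignment tibble (reads mapped against a database of
#'   the TE consensus plus SCGs).
#' @param te_id Reference id of the TE consensus.
#' @param scg_ids Reference ids of the single-copy genes.
#' @param reference_lengths Named lengths (default: `@SQ` header).
#' @param sample_id Sample label.
#' @inheritParams call_presence
#' @inheritParams normalize_by_scg
#' @return A list: `call` (one-row tibble), `profile`
#'   (`normalized_profile`).
#' @export
estimate_copy_number <- function(alignments, te_id, scg_ids,
                                 reference_lengths = NULL,
                                 sample_id = "sample",
                                 breadth_threshold = 0.9,
                                 depth_threshold = 1.0,
                                 summary = "mean") {
  cov <- coverage_profile(alignments, reference_lengths)
  te_cov <- filter(cov, .data$reference_id == te_id)
  scg_cov <- filter(cov, .data$reference_id %in% scg_ids)
  if (nrow(te_cov) == 0) abort(sprintf("TE reference '%s' not found", te_id))
  if (nrow(scg_cov) == 0) abort("no SCG reference found")
  prof <- normalize_by_scg(te_cov, scg_cov, summary = summary)
  list(
    call = call_presence(prof, sample_id = sample_id,
                         breadth_threshold = breadth_threshold,
                         depth_threshold = depth_threshold),
    profile = prof
  )
}
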