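#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a scan report into its candidate table
#'
#' @param x A `te_scan_report`.
#' @param ... Unused.
#' @return Tibble of retained candidates (sequence column dropped).
#' @method tidy te_scan_report
#' @export
tidy.te_scan_report <- function(x, ...) {
  select(x$candidates, -"seq")
}

#' One-row summary of a scan run
#'
#' @param x A `te_scan_report`.
#' @param ... Unused.
#' @return Tibble with read counts per stage, contig and candidate totals.
#' @method glance te_scan_report
#' @export
glance.te_scan_report <- function(x, ...) {
  tibble(
    reads_total = x$stages$reads_in[1],
    reads_candidate = x$stages$reads_out[1],
    reads_after_contaminant_filter = x$stages$reads_out[nrow(x$stages)],
    n_contigs = nrow(x$contigs),
    n_candidates = nrow(x$candidates),
    best_hit = if (nrow(x$candidates) > 0) x$candidates$best_hit[1]
    else NA_character_
  )
}

#' Tidy a normalized coverage profile
#'
#' @param x A `normalized_profile`.
#' @param ... Unused.
#' @return Per-position tibble (`reference_id`, `pos`, `depth`,
#'   `normalized_depth`).
#' @method tidy normalized_profile
#' @export
tidy.normalized_profile <- function(x, ...) x$profile

#' One-row summary of a normalized profile
#'
#' @param x A `normalized_profile`.
#' @param ... Unused.
#' @return Tibble with `scg_factor`, `copy_number`, `copy_number_max`,
#'   `breadth_above_one`.
#' @method glance normalized_profile
#' @export
glance.normalized_profile <- function(x, ...) {
  tibble(
    scg_factor = x$scg_factor,
    copy_number = x$copy_number,
    copy_number_max = x$copy_number_max,
    breadth_above_one = mean(x$profile$normalized_depth > 1)
  )
}

#' Tidy an invasion summary
#'
#' @param x An `invasion_summary`.
#' @param ... Unused.
#' @return The (year, region) tibble.
#' @method tidy invasion_summary
#' @export
tidy.invasion_summary <- function(x, ...) x$by_year_region

#' One-row summary of an invasion summary
#'
#' @param x An `invasion_summary`.
#' @param ... Unused.
#' @return Tibble with overall first detection year, totals, and the number
#'   of regions reached.
#' @method glance invasion_summary
#' @export
glance.invasion_summary <- function(x, ...) {
  tibble(
    first_detection_year = x$first_detection_year,
    samples_total = sum(x$by_year_region$samples_total),
    samples_present = sum(x$by_year_region$samples_present),
    regions_reached = sum(!is.na(x$first_detection$first_detection_year))
  )
}

#' Tidy a ping-pong profile
#'
#' @param x A `pingpong_profile`.
#' @param ... Unused.
#' @return The overlap histogram tibble (`offset`, `count`).
#' @method tidy pingpong_profile
#' @export
tidy.pingpong_profile <- function(x, ...) x$overlap_counts

#' One-row summary of a ping-pong profile
#'
#' @param x A `pingpong_profile`.
#' @param ... Unused.
#' @return Tibble with `zscore_at_10`, `fraction_at_10`, `total_pairs`,
#'   `n_sense`, `n_antisense`.
#' @method glance pingpong_profile
#' @export
glance.pingpong_profile <- function(x, ...) {
  tibble(
    zscore_at_10 = x$zscore_at_10,
    fraction_at_10 = x$fraction_at_10,
    total_pairs = x$total_pairs,
    n_sense = x$n_sense,
    n_antisense = x$n_antisense
  )
}

#' Tidy an element model into a feature table
#'
#' @param x An `element_model`.
#' @param ... Unused.
#' @return Feature tibble (LTRs, ORFs, tandem repeats) in 0-based half-open
#'   coordinates.
#' @method tidy element_model
#' @export
tidy.element_model <- function(x, ...) element_features(x)

#' One-row summary of an element model
#'
#' @param x An `element_model`.
#' @param ... Unused.
#' @return Tibble with consensus length, LTR length/identity, ORF and
#'   repeat counts.
#' @method glance element_model
#' @export
glance.element_model <- function(x, ...) {
  tibble(
    consensus_length = nchar(x$consensus$seq),
    ltr_length = if (is.null(x$ltrs)) NA_integer_ else x$ltrs$length,
    ltr_identity = if (is.null(x$ltrs)) NA_real_ else x$ltrs$identity,
    n_orfs = nrow(x$orfs),
    n_internal_repeats = nrow(x$internal_repeats)
  )
}
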