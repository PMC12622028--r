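#' Spatio-temporal summary of a TE invasion
#'
#' Joins per-sample presence calls with collection metadata and tabulates,
#' for every (year, region) cell of the sampling frame, how many samples
#' were assayed and how many carried the element. Years inside the sampled
#' range with no samples are kept as zero-total rows so that sampling gaps
#' (e.g. a detection gap between two positive years) remain visible.
#'
#' @param calls Presence-call tibble ([call_presence()]); one row per
#'   sample, columns `sample_id`, `present`.
#' @param meta Metadata tibble ([read_sample_metadata()]); columns
#'   `sample_id`, `collection_year`, `region`. Duplicate sample ids are
#'   rejected, and every call must have metadata.
#' @return A list of class `"invasion_summary"`: `by_year_region` (tibble
#'   `year`, `region`, `samples_total`, `samples_present`,
#'   `fraction_present`, ordered year ascending then region alphabetical),
#'   `first_detection` (per-region first year with a present sample; `NA`
#'   when never detected), `first_detection_year` (overall; `NA` when the
#'   element is absent everywhere).
#' @export
summarize_invasion <- function(calls, meta) {
  if (anyDuplicated(meta$sample_id)) {
    abort(sprintf("duplicate sample_id in metadata: %s",
                  meta$sample_id[duplicated(meta$sample_id)][1]))
  }
  if (anyDuplicated(calls$sample_id)) {
    abort(sprintf("duplicate sample_id in calls: %s",
                  calls$sample_id[duplicated(calls$sample_id)][1]))
  }
  orphans <- setdiff(calls$sample_id, meta$sample_id)
  if (length(orphans) > 0) {
    abort(sprintf("presence calls without metadata: %s",
                  paste(orphans, collapse = ", ")))
  }
  joined <- calls %>%
    select("sample_id", "present") %>%
    left_join(select(meta, "sample_id", "collection_year", "region"),
              by = "sample_id")

  years <- seq(min(joined$collection_year), max(joined$collection_year))
  regions <- sort(unique(meta$region))
  cells <- joined %>%
    group_by(year = .data$collection_year, region = .data$region) %>%
    summarise(samples_total = n(),
              samples_present = sum(.data$present), .groups = "drop") %>%
    tidyr::complete(year = years, region = regions,
                    fill = list(samples_total = 0L, samples_present = 0L)) %>%
    mutate(fraction_present = if_else(.data$samples_total > 0,
                                      .data$samples_present / .data$samples_total,
                                      NA_real_)) %>%
    arrange(.data$year, .data$region)

  detected <- filter(cells, .data$samples_present > 0)
  first_det <- if (nrow(detected) == 0) {
    tibble(region = character(), first_detection_year = integer())
  } else {
    detected %>%
      group_by(.data$region) %>%
      summarise(first_detection_year = min(.data$year), .groups = "drop")
  }
  first_det <- tibble(region = regions) %>%
    left_join(first_det, by = "region")

  structure(
    list(
      by_year_region = cells,
      first_detection = first_det,
      first_detection_year = if (any(cells$samples_present > 0)) {
        min(cells$year[cells$samples_present > 0])
      } else NA_integer_
    ),
    class = "invasion_summary"
  )
}

#' @export
print.invasion_summary <- function(x, ...) {
  cat("Invasion summary\n")
  if (is.na(x$first_detection_year)) {
    cat("  element not detected in any sample\n")
  } else {
    cat(sprintf("  first detection: %d\n", x$first_detection_year))
  }
  sampled <- filter(x$by_year_region, .data$samples_total > 0)
  cat(sprintf("  %d sampled (year, region) cells across %d-%d\n",
              nrow(sampled), min(x$by_year_region$year),
              max(x$by_year_region$year)))
  invisible(x)
}

#' Wide year-by-region matrix of presence fractions
#'
#' @param summary An [summarize_invasion()] result.
#' @return Tibble with a `year` column and one column per region holding
#'   `fraction_present` (`NA` where nothing was sampled).
#' @export
invasion_matrix <- function(summary) {
  stopifnot(inherits(summary, "invasion_summary"))
  summary$by_year_region %>%
    select("year", "region", "fraction_present") %>%
    tidyr::pivot_wider(names_from = "region",
                       values_from = "fraction_present")
}
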