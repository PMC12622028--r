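#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_tile geom_segment geom_hline labs theme_minimal scale_fill_viridis_c
#'   facet_wrap
#' @export
ggplot2::autoplot

#' Plot a normalized coverage profile
#'
#' Per-position normalized depth (haploid copy units) along the consensus,
#' with the presence-call depth threshold drawn at 1.
#'
#' @param object A `normalized_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot normalized_profile
#' @export
autoplot.normalized_profile <- function(object, ...) {
  ggplot(object$profile, aes(x = .data$pos, y = .data$normalized_depth)) +
    geom_line(colour = "steelblue") +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "consensus position (bp)", y = "normalized depth (copies)",
         title = sprintf("%s: copy number %.1f",
                         object$profile$reference_id[1],
                         object$copy_number)) +
    theme_minimal()
}

#' Plot an invasion timeline
#'
#' Year-by-region tiles of the fraction of samples carrying the element;
#' unsampled cells stay blank, making sampling gaps visible.
#'
#' @param object An `invasion_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot invasion_summary
#' @export
autoplot.invasion_summary <- function(object, ...) {
  dat <- filter(object$by_year_region, .data$samples_total > 0)
  ggplot(dat, aes(x = .data$year, y = .data$region,
                  fill = .data$fraction_present)) +
    geom_tile() +
    scale_fill_viridis_c(name = "fraction present", limits = c(0, 1)) +
    labs(x = "collection year", y = NULL, title = "Invasion timeline") +
    theme_minimal()
}

#' Plot a ping-pong overlap histogram
#'
#' @param object A `pingpong_profile`.
#' @param ... Unused.
#' @return A ggplot object; the offset-10 bar is highlighted.
#' @method autoplot pingpong_profile
#' @export
autoplot.pingpong_profile <- function(object, ...) {
  dat <- mutate(object$overlap_counts, pingpong = .data$offset == 10L)
  ggplot(dat, aes(x = .data$offset, y = .data$count, fill = .data$pingpong)) +
    geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    labs(x = "5'-5' overlap (nt)", y = "weighted pair count",
         title = if (is.na(object$zscore_at_10)) "Ping-pong signature"
         else sprintf("Ping-pong signature (z = %.2f)",
                      object$zscore_at_10)) +
    theme_minimal()
}

#' Plot a self dot plot
#'
#' @param object A `dotplot` ([self_dotplot()]).
#' @param ... Unused.
#' @return A ggplot object (forward matches in black, reverse in red).
#' @method autoplot dotplot
#' @export
autoplot.dotplot <- function(object, ...) {
  ggplot(object$matches, aes(x = .data$x, y = .data$y,
                             colour = .data$strand)) +
    geom_point(size = 0.3) +
    ggplot2::scale_colour_manual(values = c(`+` = "black", `-` = "red")) +
    labs(x = "position (bp)", y = "position (bp)", title = "Self dot plot") +
    theme_minimal()
}

#' Plot an element model
#'
#' Linear map of the consensus with LTRs, ORFs and internal tandem repeats.
#'
#' @param object An `element_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot element_model
#' @export
autoplot.element_model <- function(object, ...) {
  feats <- element_features(object)
  if (nrow(feats) == 0) {
    feats <- tibble(seqid = object$consensus$id, type = "consensus",
                    start = 0L, end = nchar(object$consensus$seq),
                    strand = "+", attributes = "")
  }
  ggplot(feats, aes(x = .data$start, xend = .data$end, y = .data$type,
                    yend = .data$type, colour = .data$type)) +
    geom_segment(linewidth = 4, show.legend = FALSE) +
    ggplot2::xlim(0, nchar(object$consensus$seq)) +
    labs(x = "consensus position (bp)", y = NULL,
         title = sprintf("%s (%d bp)", object$consensus$id,
                         nchar(object$consensus$seq))) +
    theme_minimal()
}

#' Best-match scatter across assemblies
#'
#' Alignment length against identity of the best hit per assembly — the
#' standard view for spotting close relatives of an invading family among
#' screened species.
#'
#' @param best A [best_match_table()] tibble.
#' @return A ggplot object.
#' @export
plot_best_matches <- function(best) {
  ggplot(best, aes(x = .data$best_matched_length, y = .data$best_identity,
                   label = .data$assembly_id)) +
    geom_point(colour = "steelblue") +
    ggplot2::geom_text(nudge_y = 1.5, size = 3) +
    labs(x = "best match length (bp)", y = "best identity (%)",
         title = "Best consensus match per assembly") +
    theme_minimal()
}
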