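#' Screen a genome assembly for insertions of a TE consensus
#'
#' Seed-extend-chain homology search: exact `seed_k`-mer seeds between the
#' consensus and both strands of every contig are merged along diagonals,
#' extended ungapped with an X-drop rule, and collinear segments within
#' `merge_gap` bp are chained into one insertion hit. Per hit, identity is
#' matched bases over aligned columns of the chained segments (ungapped, so
#' interior unaligned gaps reduce `matched_length` but not identity), and
#' `matched_length` is the number of distinct consensus positions covered.
#' A hit is full length when it covers more than 80% of the consensus.
#'
#' @param assembly Sequence tibble ([read_seqs()]) of contigs.
#' @param consensus Consensus sequence (string or single-row tibble).
#' @param assembly_id Label for the assembly (default `"assembly"`).
#' @param seed_k Seed word size (default 13).
#' @param min_segment Minimum extended segment length kept, bp (default 50).
#' @param merge_gap Maximum gap bridged when chaining collinear segments
#'   (default 1000 bp).
#' @param seed_bridge Same-diagonal seed runs separated by at most this many
#'   bases are merged before extension (default 200).
#' @param full_length_fraction Consensus coverage above which a hit is full
#'   length (default 0.8, strict).
#' @param resolve_nested Drop hits whose contig span lies (at least 90%)
#'   inside a hit with a longer match on the same contig (default `TRUE`);
#'   removes the internal self-homology sub-hits (LTR-vs-LTR, tandem
#'   repeats) that any repeat with internal structure generates.
#' @return Tibble of hits: `assembly_id`, `contig_id`, `start`, `end`
#'   (0-based half-open on the forward strand of the contig), `strand`,
#'   `matched_length`, `identity`, `n_segments`, `full_length`; ordered by
#'   contig then start.
#' @export
screen_assembly <- function(assembly, consensus, assembly_id = "assembly",
                            seed_k = 13L, min_segment = 50L,
                            merge_gap = 1000L, seed_bridge = 200L,
                            full_length_fraction = 0.8,
                            resolve_nested = TRUE) {
  stopifnot(nrow(assembly) > 0)
  cons <- single_seq(consensus)
  clen <- nchar(cons)
  cchars <- strsplit(cons, "", fixed = TRUE)[[1]]
  cstarts <- 1:(clen - seed_k + 1L)
  cmap <- split(cstarts, substring(cons, cstarts, cstarts + seed_k - 1L))

  hits <- list()
  for (ci in seq_len(nrow(assembly))) {
    contig <- toupper(assembly$seq[ci])
    contig_len <- nchar(contig)
    if (contig_len < seed_k) next
    for (strand in c("+", "-")) {
      w <- if (strand == "+") contig else revcomp(contig)
      wchars <- strsplit(w, "", fixed = TRUE)[[1]]
      wstarts <- 1:(contig_len - seed_k + 1L)
      wk <- substring(w, wstarts, wstarts + seed_k - 1L)
      m <- match(wk, names(cmap))
      rows <- which(!is.na(m))
      if (length(rows) == 0) next
      seeds <- bind_rows(lapply(rows, function(i) {
        tibble(wpos = wstarts[i], cpos = cmap[[m[i]]])
      }))
      segs <- extend_seed_runs(seeds, wchars, cchars, seed_k,
                               seed_bridge, min_segment)
      if (nrow(segs) == 0) next
      chains <- chain_segments(segs, merge_gap)
      for (ch in chains) {
        wlo <- min(ch$wstart); whi <- max(ch$wend)
        hits[[length(hits) + 1L]] <- tibble(
          assembly_id = assembly_id,
          contig_id = assembly$id[ci],
          start = if (strand == "+") wlo else contig_len - whi,
          end = if (strand == "+") whi else contig_len - wlo,
          strand = strand,
          matched_length = interval_union_len(ch$cstart, ch$cend),
          identity = 100 * sum(ch$matches) / sum(ch$wend - ch$wstart),
          n_segments = nrow(ch)
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(assembly_id = character(), contig_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  matched_length = integer(), identity = numeric(),
                  n_segments = integer(), full_length = logical()))
  }
  out <- bind_rows(hits)
  if (resolve_nested) out <- drop_nested_hits(out)
  out %>%
    mutate(full_length = .data$matched_length > full_length_fraction * clen) %>%
    arrange(.data$contig_id, .data$start, .data$strand)
}

# remove hits ≥90% contained (by contig span) in a longer-matching hit on
# the same contig; keeps the dominant hit per insertion locus
drop_nested_hits <- function(hits) {
  keep <- rep(TRUE, nrow(hits))
  for (idx in split(seq_len(nrow(hits)), hits$contig_id)) {
    h <- hits[idx, , drop = FALSE]
    o <- order(-h$matched_length, -h$identity, h$start)
    kept <- integer(0)
    for (i in o) {
      contained <- FALSE
      for (j in kept) {
        ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j])
        if (ov >= 0.9 * (h$end[i] - h$start[i])) { contained <- TRUE; break }
      }
      if (contained) keep[idx[i]] <- FALSE else kept <- c(kept, i)
    }
  }
  hits[keep, , drop = FALSE]
}

# merge same-diagonal seeds into runs, X-drop extend each run, report
# segments as 0-based half-open [wstart, wend) / [cstart, cend) plus match
# counts. Coordinates are on the working strand w.
extend_seed_runs <- function(seeds, wchars, cchars, k, seed_bridge,
                             min_segment, xdrop = 12L) {
  seeds <- seeds %>%
    mutate(d = .data$wpos - .data$cpos) %>%
    arrange(.data$d, .data$wpos)
  runs <- seeds %>%
    group_by(.data$d) %>%
    mutate(run = cumsum(c(1L, diff(.data$wpos) > seed_bridge))) %>%
    group_by(.data$d, .data$run) %>%
    summarise(w1 = min(.data$wpos), w2 = max(.data$wpos) + k - 1L,
              .groups = "drop")
  wl <- length(wchars); cl <- length(cchars)
  out <- list()
  for (i in seq_len(nrow(runs))) {
    d <- runs$d[i]
    lo <- runs$w1[i]; hi <- runs$w2[i]     # 1-based inclusive on w
    # extend left
    score <- 0L; bestscore <- 0L; bestpos <- lo
    p <- lo - 1L
    while (p >= 1L && p - d >= 1L) {
      score <- score + if (wchars[p] == cchars[p - d] &&
                           wchars[p] != "N") 1L else -3L
      if (score > bestscore) { bestscore <- score; bestpos <- p }
      if (bestscore - score >= xdrop) break
      p <- p - 1L
    }
    lo <- bestpos
    # extend right
    score <- 0L; bestscore <- 0L; bestpos <- hi
    p <- hi + 1L
    while (p <= wl && p - d <= cl) {
      score <- score + if (wchars[p] == cchars[p - d] &&
                           wchars[p] != "N") 1L else -3L
      if (score > bestscore) { bestscore <- score; bestpos <- p }
      if (bestscore - score >= xdrop) break
      p <- p + 1L
    }
    hi <- bestpos
    len <- hi - lo + 1L
    if (len < min_segment) next
    matches <- sum(wchars[lo:hi] == cchars[(lo - d):(hi - d)] &
                     wchars[lo:hi] != "N")
    out[[length(out) + 1L]] <- tibble(
      wstart = lo - 1L, wend = hi, cstart = lo - d - 1L, cend = hi - d,
      matches = matches, d = d
    )
  }
  if (length(out) == 0) {
    return(tibble(wstart = integer(), wend = integer(), cstart = integer(),
                  cend = integer(), matches = integer(), d = integer()))
  }
  # overlapping runs on the same diagonal can arise from bridged seed sets;
  # keep the best-scoring representative per identical span
  bind_rows(out) %>% distinct(.data$wstart, .data$wend, .data$d,
                              .keep_all = TRUE)
}

# greedy collinear chaining of segments sorted by contig position
chain_segments <- function(segs, merge_gap) {
  segs <- arrange(segs, .data$wstart, .data$cstart)
  chains <- list()
  current <- segs[1, , drop = FALSE]
  for (i in seq_len(nrow(segs))[-1]) {
    prev <- current[nrow(current), ]
    nxt <- segs[i, , drop = FALSE]
    collinear <- nxt$wstart >= prev$wstart &&
      nxt$cstart >= prev$cstart &&
      nxt$wstart - prev$wend <= merge_gap &&
      nxt$cstart - prev$cend <= merge_gap
    if (collinear) {
      current <- bind_rows(current, nxt)
    } else {
      chains[[length(chains) + 1L]] <- current
      current <- nxt
    }
  }
  chains[[length(chains) + 1L]] <- current
  chains
}

interval_union_len <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0L; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    } else {
      cur_e <- max(cur_e, end[i])
    }
  }
  as.integer(total + (cur_e - cur_s))
}

#' Extract an insertion with flanking sequence
#'
#' Returns the hit extended by `flank` bp on both sides, clipped at contig
#' boundaries; minus-strand hits are reverse-complemented so the insertion
#' reads in consensus orientation (the flanks swap sides accordingly).
#'
#' @param assembly Sequence tibble containing the hit's contig.
#' @param hit One row of a [screen_assembly()] result.
#' @param flank Flank length in bp (default 3000).
#' @return Single-row sequence tibble whose id encodes assembly, contig,
#'   coordinates and strand.
#' @export
extract_with_flanks <- function(assembly, hit, flank = 3000L) {
  stopifnot(nrow(hit) == 1L)
  contig <- assembly$seq[match(hit$contig_id, assembly$id)]
  if (is.na(contig)) abort(sprintf("contig '%s' not in assembly", hit$contig_id))
  L <- nchar(contig)
  stopifnot(hit$start >= 0, hit$end <= L, hit$start < hit$end)
  lo <- max(0L, hit$start - flank)
  hi <- min(L, hit$end + flank)
  s <- substr(contig, lo + 1L, hi)
  lf <- hit$start - lo
  rf <- hi - hit$end
  if (hit$strand == "-") {
    s <- revcomp(s)
    tmp <- lf; lf <- rf; rf <- tmp
  }
  tibble(
    id = sprintf("%s|%s|%d-%d|%s", hit$assembly_id, hit$contig_id,
                 lo, hi, hit$strand),
    desc = sprintf("insertion %d-%d flank %d", hit$start, hit$end, flank),
    seq = s,
    left_flank = lf,
    right_flank = rf
  )
}

#' Keep only insertions bounded by two LTRs
#'
#' Runs terminal-repeat detection on a flank-extracted insertion and passes
#' it only when an LTR pair of at least `min_length` bp at `min_identity`%
#' identity is present — fragmented insertions and solo LTRs fail. On pass,
#' the insertion is trimmed to its LTR-to-LTR extent (flanks removed).
#'
#' @param insertion Single-row sequence tibble from [extract_with_flanks()]
#'   (its `left_flank`/`right_flank` columns locate the insertion inside
#'   the record; without them `flank` is assumed on both sides).
#' @param min_length Minimum LTR length (default 100 bp).
#' @param min_identity Minimum LTR pair identity (default 85).
#' @param flank Flank length assumed when the record carries no flank
#'   columns (default 3000).
#' @param margin Bases of flank kept around the hit when scanning for the
#'   repeats, allowing for imprecise hit boundaries (default 300).
#' @return A list: `pass` (flag), `trimmed` (single-row sequence tibble or
#'   `NULL`), `ltrs` (the repeat annotation, in window coordinates, or
#'   `NULL`).
#' @export
require_two_ltrs <- function(insertion, min_length = 100L,
                             min_identity = 85, flank = 3000L,
                             margin = 300L) {
  s <- single_seq(insertion)
  L <- nchar(s)
  lf <- if ("left_flank" %in% names(insertion)) insertion$left_flank[1] else
    min(flank, L)
  rf <- if ("right_flank" %in% names(insertion)) insertion$right_flank[1] else
    min(flank, L)
  w_lo <- max(0L, lf - margin)             # 0-based window on the record
  w_hi <- min(L, L - rf + margin)
  fail <- list(pass = FALSE, trimmed = NULL, ltrs = NULL)
  if (w_hi - w_lo < 2L * min_length) return(fail)
  window <- substr(s, w_lo + 1L, w_hi)
  ltrs <- detect_terminal_repeats(window, min_length = min_length,
                                  min_identity = min_identity)
  if (is.null(ltrs)) return(fail)
  list(
    pass = TRUE,
    trimmed = tibble(
      id = paste0(insertion$id[1], "|ltr_trimmed"),
      desc = "",
      seq = substr(window, ltrs$left_start + 1L, ltrs$right_end)
    ),
    ltrs = ltrs
  )
}

#' Best-match summary across assemblies
#'
#' One row per assembly: the hit maximizing `matched_length` (ties broken by
#' higher identity). Assemblies without hits are reported with zeros, so a
#' length-vs-identity scatter across species shows negatives too.
#'
#' @param hits Hit tibble ([screen_assembly()] results, possibly several
#'   assemblies bound together).
#' @param assembly_ids All screened assembly ids (default: those present in
#'   `hits`).
#' @return Tibble `assembly_id`, `best_matched_length`, `best_identity`,
#'   `n_hits`.
#' @export
best_match_table <- function(hits, assembly_ids = NULL) {
  if (is.null(assembly_ids)) assembly_ids <- unique(hits$assembly_id)
  best <- hits %>%
    group_by(.data$assembly_id) %>%
    arrange(desc(.data$matched_length), desc(.data$identity),
            .by_group = TRUE) %>%
    summarise(best_matched_length = .data$matched_length[1],
              best_identity = .data$identity[1],
              n_hits = n(), .groups = "drop")
  tibble(assembly_id = assembly_ids) %>%
    left_join(best, by = "assembly_id") %>%
    mutate(
      best_matched_length = if_else(is.na(.data$best_matched_length), 0L,
                                    .data$best_matched_length),
      best_identity = if_else(is.na(.data$best_identity), 0,
                              .data$best_identity),
      n_hits = if_else(is.na(.data$n_hits), 0L, .data$n_hits)
    ) %>%
    arrange(.data$assembly_id)
}

#' Count distinct insertions in a hit table
#'
#' Clusters hits on the same contig and strand whose consensus projections
#' overlap by at most 50% of the shorter projection (such hits are fragments
#' of one insertion split by the chainer), so a fragmented insertion is not
#' counted twice.
#'
#' @param hits Hit tibble from [screen_assembly()].
#' @param max_contig_gap Fragments farther apart than this on the contig are
#'   separate insertions regardless of projection (default 20000 bp).
#' @return Integer insertion count.
#' @export
count_insertions <- function(hits, max_contig_gap = 20000L) {
  if (nrow(hits) == 0) return(0L)
  total <- 0L
  for (key in split(seq_len(nrow(hits)),
                    paste(hits$contig_id, hits$strand))) {
    h <- hits[key, , drop = FALSE] %>% arrange(.data$start)
    n <- 1L
    for (i in seq_len(nrow(h))[-1]) {
      gap_ok <- h$start[i] - h$end[i - 1L] <= max_contig_gap
      ov <- min(h$end[i] - h$start[i], h$end[i - 1] - h$start[i - 1])
      proj_overlap <- overlap_fraction(h[i - 1L, ], h[i, ])
      if (!(gap_ok && proj_overlap <= 0.5)) n <- n + 1L
    }
    total <- total + n
  }
  total
}

# fraction of the shorter consensus projection shared by two hits; the hit
# table stores contig coordinates, so projections are approximated by the
# matched lengths anchored at each hit's span
overlap_fraction <- function(h1, h2) {
  ov <- min(h1$end, h2$end) - max(h1$start, h2$start)
  if (ov <= 0) return(0)
  ov / min(h1$end - h1$start, h2$end - h2$start)
}
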