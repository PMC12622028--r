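#' Detect long terminal repeats (LTRs)
#'
#' Searches for the longest pair of direct repeats anchored near the two
#' ends of an element: exact k-mer seeds between the first and last quarter
#' of the sequence propose diagonals, and each diagonal is scanned for the
#' longest ungapped interval whose identity stays at or above
#' `min_identity` (maximal: it cannot be lengthened without dropping below
#' the identity floor). Both repeats are on the + strand, as in an LTR
#' retroelement. Coordinates are 0-based half-open.
#'
#' @param seq A DNA sequence (single string) or single-row sequence tibble.
#' @param min_length Minimum repeat length in bp (default 100).
#' @param min_identity Minimum percent identity between the two repeats
#'   (default 95).
#' @param seed_k Seed k-mer size (default 13).
#' @return A one-row tibble (`left_start`, `left_end`, `right_start`,
#'   `right_end`, `length`, `identity`) or `NULL` when no qualifying pair
#'   exists.
#' @export
detect_terminal_repeats <- function(seq, min_length = 100L,
                                    min_identity = 95, seed_k = 13L) {
  s <- single_seq(seq)
  L <- nchar(s)
  if (L < 2L * min_length) {
    abort("sequence shorter than twice min_length")
  }
  q <- min_identity / 100
  head_end <- max(ceiling(L * 0.25), min_length)
  tail_start <- min(floor(L * 0.75) + 1L, L - min_length + 1L)
  head_kmers <- substring(s, 1:(head_end - seed_k + 1L),
                          seed_k:head_end)
  tail_pos <- tail_start:(L - seed_k + 1L)
  if (length(tail_pos) < 1L) return(NULL)
  tail_kmers <- substring(s, tail_pos, tail_pos + seed_k - 1L)
  hit <- match(tail_kmers, head_kmers)
  found <- which(!is.na(hit))
  if (length(found) == 0) return(NULL)
  diags <- sort(unique(tail_pos[found] - hit[found]))

  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  best <- NULL
  for (d in diags) {
    if (d < min_length) next  # overlapping copies are a tandem, not LTRs
    n <- L - d
    m <- as.numeric(sv[1:n] == sv[(1 + d):(d + n)] &
                      sv[1:n] != "N" & sv[(1 + d):(d + n)] != "N")
    iv <- longest_interval_above(m, q)
    if (is.null(iv) || iv$len < min_length) next
    ident <- 100 * iv$mean
    if (is.null(best) ||
        iv$len > best$length ||
        (iv$len == best$length && ident > best$identity)) {
      best <- list(left_start = iv$start - 1L, length = iv$len,
                   d = d, identity = ident)
    }
  }
  if (is.null(best)) return(NULL)
  tibble(
    left_start = best$left_start,
    left_end = best$left_start + best$length,
    right_start = best$left_start + best$d,
    right_end = best$left_start + best$d + best$length,
    length = best$length,
    identity = best$identity
  )
}

# longest contiguous interval of a 0/1 vector with mean >= q.
# Equivalent to the longest subarray of (m - q) with non-negative sum;
# solved with prefix sums and a decreasing-prefix stack.
longest_interval_above <- function(m, q) {
  t <- m - q
  n <- length(t)
  P <- c(0, cumsum(t))
  # candidate left endpoints: strictly decreasing prefix minima
  stack <- integer(0)
  for (i in seq_len(n + 1L)) {
    if (length(stack) == 0 || P[i] < P[stack[length(stack)]]) {
      stack <- c(stack, i)
    }
  }
  best_len <- 0L
  best_start <- NA_integer_
  j <- length(stack)
  for (b in (n + 1L):1L) {
    while (j >= 1L && P[stack[j]] <= P[b]) {
      len <- b - stack[j]
      if (len > best_len) {
        best_len <- len
        best_start <- stack[j]
      }
      j <- j - 1L
    }
    if (j < 1L) break
  }
  if (best_len == 0L) return(NULL)
  list(start = best_start, len = best_len,
       mean = mean(m[best_start:(best_start + best_len - 1L)]))
}

#' Self dot plot and internal repeat summary
#'
#' Reports all exact k-mer self-matches of a sequence (both strands,
#' excluding the trivial main diagonal), merges collinear runs into
#' segments, and summarizes tandem arrays as repeat regions with a unit
#' length and copy count.
#'
#' @param seq DNA sequence (string or single-row tibble).
#' @param k Word size (default 10).
#' @param max_join Merge same-diagonal matches separated by at most this
#'   many bases into one segment (default `k`).
#' @return A list of class `"dotplot"`: `matches` (tibble `x`, `y`,
#'   `strand`; 0-based start coordinates, upper triangle only), `segments`
#'   (merged collinear runs), `repeats` (tibble `start`, `end`,
#'   `unit_length`, `copy_count`).
#' @export
self_dotplot <- function(seq, k = 10L, max_join = k) {
  s <- single_seq(seq)
  L <- nchar(s)
  stopifnot(k <= L)
  starts <- 1:(L - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  idx <- split(starts, kmers)

  fwd <- purrr::map(idx[lengths(idx) > 1L], function(p) {
    g <- expand.grid(x = p, y = p)
    g[g$y > g$x, , drop = FALSE]
  })
  fwd <- if (length(fwd)) bind_rows(fwd) else
    data.frame(x = integer(), y = integer())
  rc_kmers <- revcomp(kmers)
  hit <- match(rc_kmers, names(idx))
  rev_rows <- which(!is.na(hit))
  rev <- if (length(rev_rows)) {
    bind_rows(lapply(rev_rows, function(i) {
      tibble(x = starts[i], y = idx[[hit[i]]])
    })) %>% filter(.data$y >= .data$x)
  } else tibble(x = integer(), y = integer())

  matches <- bind_rows(
    tibble(x = fwd$x, y = fwd$y, strand = "+"),
    tibble(x = rev$x, y = rev$y, strand = "-")
  ) %>%
    mutate(x = .data$x - 1L, y = .data$y - 1L) %>%
    arrange(.data$strand, .data$y - .data$x, .data$x)

  # merge same-diagonal forward runs into segments
  empty_segs <- tibble(d = integer(), x_start = integer(),
                       x_end = integer(), y_start = integer(),
                       y_end = integer(), n_words = integer())
  segs <- if (!any(matches$strand == "+")) empty_segs else matches %>%
    filter(.data$strand == "+") %>%
    mutate(d = .data$y - .data$x) %>%
    arrange(.data$d, .data$x) %>%
    group_by(.data$d) %>%
    mutate(run = cumsum(c(1L, diff(.data$x) > max_join))) %>%
    group_by(.data$d, .data$run) %>%
    summarise(x_start = min(.data$x), x_end = max(.data$x) + k,
              y_start = min(.data$y), y_end = max(.data$y) + k,
              n_words = n(), .groups = "drop") %>%
    select(-"run")

  repeats <- summarise_tandems(segs, k)
  structure(list(matches = matches, segments = segs, repeats = repeats,
                 k = k, length = L),
            class = "dotplot")
}

# cluster overlapping forward off-diagonal segments into tandem regions
summarise_tandems <- function(segs, k) {
  empty <- tibble(start = integer(), end = integer(),
                  unit_length = integer(), copy_count = integer())
  segs <- segs %>% filter(.data$d > 0, .data$d <= .data$x_end - .data$x_start + .data$d)
  # keep segments where the two copies touch or overlap (tandem geometry):
  # left copy [x_start, x_end), right copy [y_start, y_end), offset d
  segs <- segs %>% filter(.data$y_start <= .data$x_end + k)
  if (nrow(segs) == 0) return(empty)
  segs <- segs %>% arrange(.data$x_start)
  cluster <- integer(nrow(segs))
  cur_end <- -1L
  cid <- 0L
  for (i in seq_len(nrow(segs))) {
    if (segs$x_start[i] > cur_end) {
      cid <- cid + 1L
      cur_end <- segs$y_end[i]
    } else {
      cur_end <- max(cur_end, segs$y_end[i])
    }
    cluster[i] <- cid
  }
  segs %>%
    mutate(cluster = cluster) %>%
    group_by(.data$cluster) %>%
    summarise(start = min(.data$x_start), end = max(.data$y_end),
              unit_length = min(.data$d), .groups = "drop") %>%
    mutate(copy_count = as.integer(round((.data$end - .data$start) /
                                           .data$unit_length))) %>%
    filter(.data$copy_count >= 2L) %>%
    select("start", "end", "unit_length", "copy_count")
}

#' @export
print.dotplot <- function(x, ...) {
  cat(sprintf("Self dot plot (k=%d, %d bp): %d word matches, %d segments, %d tandem region(s)\n",
              x$k, x$length, nrow(x$matches), nrow(x$segments),
              nrow(x$repeats)))
  invisible(x)
}

#' Find open reading frames
#'
#' Scans all six frames for maximal ATG-to-stop spans of at least `min_aa`
#' codons (standard genetic code; the stop codon is included in the
#' coordinates but not in the amino-acid length). Reverse-strand ORFs are
#' reported in forward coordinates, 0-based half-open.
#'
#' @param seq DNA sequence (string or single-row tibble).
#' @param min_aa Minimum ORF length in codons, stop excluded (default 200).
#' @return Tibble with columns `start`, `end`, `strand`, `frame`,
#'   `aa_length`, `peptide`.
#' @export
find_orfs <- function(seq, min_aa = 200L) {
  s <- single_seq(seq)
  L <- nchar(s)
  out <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") s else revcomp(s)
    for (off in 0:2) {
      n_cod <- (L - off) %/% 3L
      if (n_cod < 1L) next
      cod_start <- off + 1L + 3L * (0:(n_cod - 1L))
      codons <- substring(w, cod_start, cod_start + 2L)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_atg <- codons == "ATG"
      prev_stop <- 0L
      for (st in which(is_stop)) {
        span <- which(is_atg[(prev_stop + 1L):(st - 1L)])
        if (length(span) > 0) {
          atg <- prev_stop + span[1]
          aa_len <- st - atg
          if (aa_len >= min_aa) {
            s0 <- off + 3L * (atg - 1L)        # 0-based on strand w
            e0 <- off + 3L * st                # includes the stop codon
            if (strand == "+") {
              start <- s0; end <- e0
            } else {
              start <- L - e0; end <- L - s0
            }
            pep <- suppressWarnings(as.character(Biostrings::translate(
              Biostrings::DNAString(substr(w, s0 + 1L, s0 + 3L * aa_len)),
              if.fuzzy.codon = "X")))
            out[[length(out) + 1L]] <- tibble(
              start = start, end = end, strand = strand,
              frame = (if (strand == "+") 1L else -1L) * (off + 1L),
              aa_length = aa_len, peptide = pep
            )
          }
        }
        prev_stop <- st
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  frame = integer(), aa_length = integer(),
                  peptide = character()))
  }
  bind_rows(out) %>% arrange(.data$start, .data$end, .data$strand)
}

#' Build the structural model of a TE consensus
#'
#' Combines [detect_terminal_repeats()], [find_orfs()] and [self_dotplot()]
#' into one annotated element. When a TE protein library is supplied, each
#' ORF's product is labelled by its best translated-search hit (e.g.
#' gag/pol/env).
#'
#' @param consensus Single-row sequence tibble (or plain string).
#' @param protein_db Optional protein tibble for ORF product labels.
#' @param min_orf_aa Minimum ORF length in codons (default 200).
#' @param ltr_min_length,ltr_min_identity LTR detection parameters.
#' @param dot_k Dot-plot word size (default 10).
#' @return A list of class `"element_model"`: `consensus`, `ltrs`, `orfs`
#'   (with `product_label`), `internal_repeats`, `dotplot`.
#' @export
annotate_element <- function(consensus, protein_db = NULL,
                             min_orf_aa = 200L,
                             ltr_min_length = 100L, ltr_min_identity = 95,
                             dot_k = 10L) {
  s <- single_seq(consensus)
  cons <- tibble(id = if (is.data.frame(consensus)) consensus$id[1] else "consensus",
                 seq = s)
  ltrs <- detect_terminal_repeats(cons$seq, min_length = ltr_min_length,
                                  min_identity = ltr_min_identity)
  orfs <- find_orfs(cons$seq, min_aa = min_orf_aa)
  orfs$product_label <- NA_character_
  if (!is.null(protein_db) && nrow(orfs) > 0) {
    hits <- search_te_proteins(
      tibble(id = sprintf("orf_%d", seq_len(nrow(orfs))),
             seq = substr(rep(cons$seq, nrow(orfs)), orfs$start + 1L, orfs$end)),
      protein_db, min_peptide_aa = 10L
    )
    best <- filter(hits, .data$is_best)
    lab <- setNames(best$protein_id, best$contig_id)
    orfs$product_label <- unname(lab[sprintf("orf_%d", seq_len(nrow(orfs)))])
  }
  dp <- self_dotplot(cons$seq, k = dot_k)
  structure(
    list(consensus = cons, ltrs = ltrs, orfs = orfs,
         internal_repeats = dp$repeats, dotplot = dp),
    class = "element_model"
  )
}

#' @export
print.element_model <- function(x, ...) {
  cat(sprintf("TE element model: %d bp consensus\n", nchar(x$consensus$seq)))
  if (is.null(x$ltrs)) {
    cat("  LTRs: none detected\n")
  } else {
    cat(sprintf("  LTRs: %d bp at %.1f%% identity ([%d,%d) / [%d,%d))\n",
                x$ltrs$length, x$ltrs$identity, x$ltrs$left_start,
                x$ltrs$left_end, x$ltrs$right_start, x$ltrs$right_end))
  }
  cat(sprintf("  ORFs: %d", nrow(x$orfs)))
  if (nrow(x$orfs) > 0 && any(!is.na(x$orfs$product_label))) {
    cat(sprintf(" (%s)", paste(stats::na.omit(x$orfs$product_label),
                               collapse = ", ")))
  }
  cat(sprintf("\n  internal tandem repeats: %d\n", nrow(x$internal_repeats)))
  invisible(x)
}

#' GFF3 feature table of an element model
#'
#' @param model An [annotate_element()] result.
#' @return Feature tibble suitable for [write_gff3()].
#' @export
element_features <- function(model) {
  id <- model$consensus$id
  feats <- list()
  if (!is.null(model$ltrs)) {
    feats[[1]] <- tibble(
      seqid = id, type = "long_terminal_repeat",
      start = c(model$ltrs$left_start, model$ltrs$right_start),
      end = c(model$ltrs$left_end, model$ltrs$right_end),
      strand = "+",
      attributes = sprintf("ID=LTR_%s;identity=%.2f", c("left", "right"),
                           model$ltrs$identity)
    )
  }
  if (nrow(model$orfs) > 0) {
    feats[[length(feats) + 1L]] <- tibble(
      seqid = id, type = "ORF",
      start = model$orfs$start, end = model$orfs$end,
      strand = model$orfs$strand,
      attributes = sprintf("ID=ORF_%d;product=%s", seq_len(nrow(model$orfs)),
                           ifelse(is.na(model$orfs$product_label), "unknown",
                                  model$orfs$product_label))
    )
  }
  if (nrow(model$internal_repeats) > 0) {
    feats[[length(feats) + 1L]] <- tibble(
      seqid = id, type = "tandem_repeat",
      start = model$internal_repeats$start,
      end = model$internal_repeats$end,
      strand = "+",
      attributes = sprintf("ID=tandem_%d;unit_length=%d;copy_count=%d",
                           seq_len(nrow(model$internal_repeats)),
                           model$internal_repeats$unit_length,
                           model$internal_repeats$copy_count)
    )
  }
  if (length(feats) == 0) {
    return(tibble(seqid = character(), type = character(), start = integer(),
                  end = integer(), strand = character(),
                  attributes = character()))
  }
  bind_rows(feats)
}

# accept either a plain string or a sequence tibble with one row
single_seq <- function(seq) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L)
    toupper(seq$seq[1])
  } else {
    stopifnot(is.character(seq), length(seq) == 1L)
    toupper(seq)
  }
}
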