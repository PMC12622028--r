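#' Parse a SAM CIGAR string
#'
#' Decomposes a CIGAR string into its ordered operations and reports how many
#' query and reference bases the alignment consumes. Query-consuming
#' operations are `M`, `I`, `S`, `=` and `X`; reference-consuming operations
#' are `M`, `D`, `=` and `X`. Hard clips (`H`) consume neither. The unmapped
#' sentinel `"*"` yields an empty operation table with zero spans.
#'
#' @param cigar_text A single CIGAR string (e.g. `"10S85M5I"`) or `"*"`.
#'
#' @return A list with elements `ops` (tibble with columns `op`, `len`),
#'   `query_span` and `ref_span` (integers).
#' @examples
#' parse_cigar("10S85M5I")
#' @export
parse_cigar <- function(cigar_text) {
  stopifnot(is.character(cigar_text), length(cigar_text) == 1L)
  if (is.na(cigar_text) || cigar_text == "*") {
    return(list(
      ops = tibble(op = character(), len = integer()),
      query_span = 0L, ref_span = 0L
    ))
  }
  toks <- gregexpr("[0-9]+[MIDNSHP=X]", cigar_text)[[1]]
  if (toks[1] == -1L ||
      sum(attr(toks, "match.length")) != nchar(cigar_text)) {
    # locate first character not covered by a valid token
    covered <- rep(FALSE, nchar(cigar_text))
    if (toks[1] != -1L) {
      for (i in seq_along(toks)) {
        covered[seq(toks[i], length.out = attr(toks, "match.length")[i])] <- TRUE
      }
    }
    bad <- which(!covered)[1]
    abort(sprintf(
      "malformed CIGAR '%s': unexpected character '%s' at offset %d",
      cigar_text, substr(cigar_text, bad, bad), bad
    ), class = "teinvader_parse_error")
  }
  tok <- regmatches(cigar_text, gregexpr("[0-9]+[MIDNSHP=X]", cigar_text))[[1]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", tok))
  op <- sub("^[0-9]+", "", tok)
  if (any(len < 1L)) {
    abort(sprintf("malformed CIGAR '%s': zero-length operation", cigar_text),
          class = "teinvader_parse_error")
  }
  list(
    ops = tibble(op = op, len = len),
    query_span = sum(len[op %in% c("M", "I", "S", "=", "X")]),
    ref_span = sum(len[op %in% c("M", "D", "N", "=", "X")])
  )
}

#' CIGAR span arithmetic (vectorized)
#'
#' @param cigar Character vector of CIGAR strings (`"*"` allowed).
#' @return Integer vector of query-consumed (`cigar_query_span()`),
#'   reference-consumed (`cigar_ref_span()`) or aligned
#'   (`cigar_aligned_len()`, operations M/=/X/I/D — the edit-distance
#'   denominator) base counts.
#' @export
cigar_query_span <- function(cigar) {
  cigar_span_sum(cigar, c("M", "I", "S", "=", "X"))
}

#' @rdname cigar_query_span
#' @export
cigar_ref_span <- function(cigar) {
  cigar_span_sum(cigar, c("M", "D", "N", "=", "X"))
}

#' @rdname cigar_query_span
#' @export
cigar_aligned_len <- function(cigar) {
  cigar_span_sum(cigar, c("M", "=", "X", "I", "D"))
}

# vectorized operation-length sum with a fast path for the ubiquitous
# single-run "<n>M" CIGAR; the general path goes through parse_cigar (and
# so keeps its validation)
cigar_span_sum <- function(cigar, keep) {
  out <- integer(length(cigar))
  star <- is.na(cigar) | cigar == "*"
  simple <- !star & grepl("^[0-9]+M$", cigar)
  if ("M" %in% keep) {
    out[simple] <- as.integer(sub("M$", "", cigar[simple]))
  }
  rest <- which(!star & !simple)
  if (length(rest) > 0) {
    out[rest] <- vapply(cigar[rest], function(x) {
      ops <- parse_cigar(x)$ops
      sum(ops$len[ops$op %in% keep])
    }, integer(1), USE.NAMES = FALSE)
  }
  out
}
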