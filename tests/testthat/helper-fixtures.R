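# shared fixtures, built in code at load time (kept small so the suite runs
# quickly; full-size constructions live in the acceptance tests)

# compact LTR retroelement: ~2.5 kb, 120 bp LTRs, three ORFs, 3x60 bp tandem
small_element <- function(seed = 1L) {
  make_te_element(seed = seed, ltr_length = 120L, gag_aa = 120L,
                  pol_aa = 260L, env_aa = 120L, utr_repeat_unit = 60L,
                  utr_repeat_copies = 3L, id = "mini_te")
}

random_dna <- function(n, seed) simulate_genome(n, seed = seed)$seq[1]

# independent brute-force local alignment oracle (Gotoh affine gaps,
# BLOSUM62; a gap of length L costs open + L * ext). Deliberately written
# as a plain dynamic program so it shares nothing with the package's
# alignment path.
sw_score_oracle <- function(a, b, open = 11, ext = 1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  S <- get("BLOSUM62", envir = env)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - (open + ext), F[i - 1, j] - ext)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + S[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_peptide <- function(n) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

# reverse-translate a peptide with fixed codons (keeps tests deterministic)
back_translate <- function(pep) {
  codon <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
             G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
             M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
             S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
  paste(codon[strsplit(pep, "")[[1]]], collapse = "")
}

# ATG + (n_codons - 1) random sense codons + TAA
random_orf_dna <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(sense, n_codons - 1L, replace = TRUE), "TAA"),
        collapse = "")
}

# minimal SAM line constructor for hand-built alignment fixtures
sam_line <- function(qname, flag, rname, pos, cigar, seq, nm = NULL,
                     mapq = 60L) {
  base <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  qname, flag, rname, pos, mapq, cigar, seq,
                  strrep("I", nchar(seq)))
  if (!is.null(nm)) base <- paste0(base, sprintf("\tNM:i:%d", nm))
  base
}

write_sam_fixture <- function(lines, refs = c(ref = 1000L),
                              path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  writeLines(c(hdr, lines), path)
  path
}
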