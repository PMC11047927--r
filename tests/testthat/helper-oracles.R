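# Shared fixtures and independent brute-force oracles used across the suite.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# minimal design: tiny frameworks, 1 NNB CDR1 position, 2 NNB CDR2
# positions, standard 7/11/15 NNB CDR3 classes
toy_design <- function() {
  library_design(
    frameworks = c("MA", "W", "G", "SS"),
    cdr1 = scheme_nnb(1),
    cdr2 = scheme_nnb(2),
    terminal_motif = "SS"
  )
}

# draw a random valid CDR tuple for a design (residues within schemes)
random_cdr_tuple <- function(design, cdr3_class = "short") {
  draw <- function(schemes)
    paste(vapply(schemes, function(s)
      sample(s$allowed, 1L), character(1)), collapse = "")
  list(draw(design$cdr1), draw(design$cdr2),
       draw(nanopanr:::cdr3_schemes(design, cdr3_class)))
}

# independent expected-AA-frequency oracle: walks all 64 concrete codons and
# accumulates the product of per-position inclusion probabilities
oracle_aa_frequencies <- function(pattern, code = standard_genetic_code()) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  bases <- c("A", "C", "G", "T")
  acc <- setNames(numeric(0), character(0))
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    p <- prod(vapply(1:3, function(i) {
      set <- IUPAC_NT[[letters[[i]]]]
      b <- c(b1, b2, b3)[[i]]
      if (b %in% set) 1 / length(set) else 0
    }, numeric(1)))
    if (p == 0) next
    aa <- code[[paste0(b1, b2, b3)]]
    if (!aa %in% names(acc)) acc[aa] <- 0
    acc[aa] <- acc[aa] + p
  }
  acc[sort(names(acc))]
}

# quadratic all-offsets merge oracle (same objective, naive R implementation)
oracle_merge <- function(s1, s2, min_overlap, max_mm_frac) {
  s2rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s2)))
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2rc, "")[[1]]
  n1 <- length(a); n2 <- length(b)
  best <- NULL
  for (L in seq(min_overlap, min(n1, n2))) {
    mm <- sum(a[(n1 - L + 1):n1] != b[1:L])
    if (mm > floor(max_mm_frac * L)) next
    cand <- list(L = L, matches = L - mm, mm = mm)
    if (is.null(best) || cand$matches > best$matches ||
        (cand$matches == best$matches && cand$L > best$L)) best <- cand
  }
  if (is.null(best)) return(list(ok = FALSE))
  list(ok = TRUE, overlap = best$L, mismatches = best$mm,
       merged = paste0(s1, substr(s2rc, best$L + 1, n2)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# brute-force candidate filter used as the oracle for select_candidates
oracle_filter <- function(records, min_pct, min_ratio) {
  keep <- records[records$pct_positive > min_pct & records$ratio > min_ratio, ]
  keep[order(-keep$pct_positive, keep$sequence), ]
}

# all-pairs Hamming distance (same-length strings only)
oracle_hamming <- function(x, y) {
  if (nchar(x) != nchar(y)) return(NA_integer_)
  sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
}
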