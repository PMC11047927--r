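# Paired-end amplicon read processing: merge -> trim -> translate ->
# intact/defect classification.

# default amplification primers flanking the diversified region in the
# synthetic amplicon layout (arbitrary fixed-locus sequences)
DEFAULT_P5 <- "ACGCACTAGTCAGGTGGTCA"
DEFAULT_P3 <- "CTAGCATCGGATCCAGTGAC"

READ_STATUSES <- c("intact", "length_mismatch", "premature_stop",
                   "frame_indel", "anchor_mismatch", "merge_failed",
                   "trim_failed")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Merge paired-end reads by overlap
#'
#' The second mate is reverse-complemented internally, then the overlap
#' length maximising the number of matching bases subject to a mismatch
#' fraction ceiling is chosen (ties broken toward the longest overlap).
#' Mismatching overlap bases are resolved toward the higher-quality base, or
#' toward mate 1 when no qualities are given.
#'
#' @param seq1,seq2 Character vectors of mate-1 / mate-2 sequences (mate 2 in
#'   its original orientation).
#' @param qual1,qual2 Optional Phred+33 quality strings.
#' @param min_overlap Minimum admissible overlap (bases), default 20.
#' @param max_mismatch_fraction Maximum mismatches per overlap base,
#'   default 0.1.
#' @return A `data.table` with columns `ok`, `merged`, `overlap`,
#'   `mismatches`; `ok == FALSE` rows are merge failures.
#' @export
merge_pairs <- function(seq1, seq2, qual1 = NULL, qual2 = NULL,
                        min_overlap = 20L, max_mismatch_fraction = 0.1) {
  stopifnot(length(seq1) == length(seq2))
  if (length(seq1) == 0L)
    return(data.table(ok = logical(), merged = character(),
                      overlap = integer(), mismatches = integer()))
  if (any(!nzchar(seq1)) || any(!nzchar(seq2)))
    stop("empty mate sequence")
  s2rc <- revcomp(seq2)
  q1 <- if (is.null(qual1)) character(0) else qual1
  q2 <- if (is.null(qual2)) character(0) else
    vapply(qual2, function(q) paste(rev(strsplit(q, "")[[1]]), collapse = ""),
           character(1), USE.NAMES = FALSE)
  res <- .merge_pairs_cpp(seq1, s2rc, as.integer(min_overlap),
                          max_mismatch_fraction, q1, q2)
  as.data.table(res)
}

#' Trim flanking primers from a merged amplicon
#'
#' Locates the 5' primer and then the 3' primer downstream of it, each
#' allowing up to `max_errors` substitutions (no indels), and returns the
#' region strictly between them.
#'
#' @param seq Character vector of merged nucleotide sequences.
#' @param p5,p3 Primer sequences.
#' @param max_errors Substitutions tolerated per primer, default 1.
#' @return `data.table` with columns `found`, `inner`.
#' @export
trim_primers <- function(seq, p5 = DEFAULT_P5, p3 = DEFAULT_P3,
                         max_errors = 1L) {
  if (!nzchar(p5) || !nzchar(p3)) stop("primers must be non-empty")
  if (length(seq) == 0L)
    return(data.table(found = logical(), inner = character()))
  as.data.table(.trim_primers_cpp(seq, toupper(p5), toupper(p3),
                                  as.integer(max_errors)))
}

#' Translate nucleotide regions in frame 0
#'
#' Sequences whose length is not a multiple of 3 are reported as frame
#' indels (`NA` translation). Stops render as `"*"`; codons containing
#' ambiguous bases render as `"X"`.
#'
#' @param nt Character vector of nucleotide sequences.
#' @param code Genetic code table (named character vector over the 64
#'   codons).
#' @return `data.table` with columns `aa` (NA when frame-shifted) and
#'   `frame_ok`.
#' @export
translate_region <- function(nt, code = standard_genetic_code()) {
  n <- length(nt)
  if (n == 0L) return(data.table(aa = character(), frame_ok = logical()))
  nt <- toupper(nt)
  frame_ok <- nchar(nt) %% 3L == 0L
  aa <- rep(NA_character_, n)
  aa[frame_ok & nchar(nt) == 0L] <- ""
  idx <- which(frame_ok & nchar(nt) > 0L)
  if (length(idx)) {
    gc <- Biostrings::GENETIC_CODE
    gc[] <- code[names(gc)]
    if (anyNA(gc)) stop("genetic code table is missing codons")
    dna <- Biostrings::DNAStringSet(nt[idx])
    aa[idx] <- as.character(
      Biostrings::translate(dna, genetic.code = gc,
                            if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  data.table(aa = aa, frame_ok = frame_ok)
}

#' Classify translated clones as intact or defective
#'
#' Applies the intact filter in fixed order: rendered length must match a
#' design class (`length_mismatch`), the sequence must be free of stop
#' symbols (`premature_stop`), and it must end with the design's terminal
#' motif (`anchor_mismatch`). Intact clones are assigned a CDR3 length class.
#'
#' @param aa Character vector of translated diversified-region sequences.
#' @param design A [library_design()].
#' @return `data.table` with columns `sequence`, `status`, `cdr3_class`
#'   (`NA` unless intact).
#' @export
classify_intact <- function(aa, design) {
  n <- length(aa)
  lens <- rendered_lengths(design)
  status <- rep("intact", n)
  cls <- names(lens)[match(nchar(aa), lens)]
  status[is.na(cls)] <- "length_mismatch"
  has_stop <- grepl("*", aa, fixed = TRUE)
  status[status == "intact" & has_stop] <- "premature_stop"
  motif_ok <- endsWith(aa, design$terminal_motif)
  status[status == "intact" & !motif_ok] <- "anchor_mismatch"
  cls[status != "intact"] <- NA_character_
  data.table(sequence = aa, status = status, cdr3_class = cls)
}

#' Repertoire count table
#'
#' Unique amino-acid sequences of the diversified region with read counts.
#'
#' @param sequences Character vector of unique sequences, or a named integer
#'   vector of counts.
#' @param counts Positive integer counts (recycled check), when `sequences`
#'   is a character vector.
#' @param sample_id Label carried in the attribute `sample_id`.
#' @return Object of class `repertoire_table` (a `data.table` with columns
#'   `sequence`, `count`).
#' @export
repertoire_table <- function(sequences, counts = NULL, sample_id = "sample") {
  if (is.null(counts)) {
    counts <- as.integer(sequences)
    sequences <- names(sequences)
  }
  counts <- as.integer(counts)
  if (length(sequences) != length(counts))
    stop("sequences and counts differ in length")
  if (anyDuplicated(sequences)) stop("sequences must be unique")
  if (length(counts) && any(counts <= 0L)) stop("counts must be positive")
  out <- data.table(sequence = as.character(sequences), count = counts)
  setorder(out, -count, sequence)
  structure(out, class = c("repertoire_table", class(out)),
            sample_id = sample_id, total = sum(counts))
}

#' @export
print.repertoire_table <- function(x, ...) {
  cat("repertoire_table '", attr(x, "sample_id"), "': ", nrow(x),
      " unique sequences, ", attr(x, "total"), " reads\n", sep = "")
  NextMethod()
}

read_fastq_seqs <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  info <- file.size(path)
  if (!is.na(info) && info == 0) return(character(0))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(x)
}

#' Process paired-end FASTQ files into a repertoire table
#'
#' Streams read pairs through merge, primer trimming, translation and the
#' intact filter, and tabulates unique intact amino-acid sequences. The
#' intact fraction is the number of intact reads divided by the number of
#' successfully merged *and* trimmed reads (merge/trim failures are excluded
#' from the denominator).
#'
#' @param fastq1,fastq2 Paths to the mate FASTQ files (plain or gzipped).
#' @param design A [library_design()].
#' @param p5,p3 Amplification primers flanking the diversified region.
#' @param min_overlap,max_mismatch_fraction Merge parameters, see
#'   [merge_pairs()].
#' @param max_primer_errors Substitutions tolerated per primer.
#' @param sample_id Label for the resulting repertoire.
#' @return List with elements `repertoire` ([repertoire_table()]),
#'   `counters` (named integer over all read statuses), `total_pairs`,
#'   `intact_fraction`, and `class_counts` (intact reads per CDR3 class).
#' @export
process_fastq <- function(fastq1, fastq2, design,
                          p5 = DEFAULT_P5, p3 = DEFAULT_P3,
                          min_overlap = 20L, max_mismatch_fraction = 0.1,
                          max_primer_errors = 1L, sample_id = "sample") {
  s1 <- read_fastq_seqs(fastq1)
  s2 <- read_fastq_seqs(fastq2)
  if (length(s1) != length(s2))
    stop("mate files differ in read count (", length(s1), " vs ",
         length(s2), ")")
  counters <- setNames(integer(length(READ_STATUSES)), READ_STATUSES)
  n <- length(s1)
  if (n == 0L) {
    return(list(repertoire = repertoire_table(character(0), integer(0),
                                              sample_id = sample_id),
                counters = counters, total_pairs = 0L,
                intact_fraction = NA_real_,
                class_counts = setNames(integer(length(design$cdr3_lengths)),
                                        names(design$cdr3_lengths))))
  }
  m <- merge_pairs(s1, s2, min_overlap = min_overlap,
                   max_mismatch_fraction = max_mismatch_fraction)
  counters[["merge_failed"]] <- sum(!m$ok)
  tr <- trim_primers(m$merged[m$ok], p5 = p5, p3 = p3,
                     max_errors = max_primer_errors)
  counters[["trim_failed"]] <- sum(!tr$found)
  inner <- tr$inner[tr$found]
  tl <- translate_region(inner, code = design$genetic_code)
  counters[["frame_indel"]] <- sum(!tl$frame_ok)
  cls <- classify_intact(tl$aa[tl$frame_ok], design)
  for (s in c("intact", "length_mismatch", "premature_stop",
              "anchor_mismatch"))
    counters[[s]] <- sum(cls$status == s)
  stopifnot(sum(counters) == n)

  intact <- cls[status == "intact"]
  denom <- n - counters[["merge_failed"]] - counters[["trim_failed"]]
  tab <- intact[, .(count = .N), by = sequence]
  class_counts <- setNames(integer(length(design$cdr3_lengths)),
                           names(design$cdr3_lengths))
  if (nrow(intact)) {
    cc <- intact[, .(n = .N), by = cdr3_class]
    class_counts[cc$cdr3_class] <- cc$n
  }
  list(repertoire = repertoire_table(tab$sequence, tab$count,
                                     sample_id = sample_id),
       counters = counters, total_pairs = n,
       intact_fraction = if (denom > 0) counters[["intact"]] / denom
                         else NA_real_,
       class_counts = class_counts)
}
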