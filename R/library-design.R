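# Library design: frameworks, per-position randomisation schemes, CDR3
# length classes, and the exact statistics they imply.

# deterministic residue -> codon map used when a nucleotide template is
# rendered (common E. coli codons; any consistent choice works because
# identity is defined at the amino-acid level downstream)
AA_TO_CODON <- c(
  A = "GCG", R = "CGT", N = "AAC", D = "GAT", C = "TGC", Q = "CAG",
  E = "GAA", G = "GGC", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCG", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAT", V = "GTG"
)

#' Define one diversified position
#'
#' A position within a CDR is either `fixed` (a single residue), `fully`
#' randomised (a degenerate codon encoding all 20 residues, e.g. NNB), or
#' `partial`ly randomised (a mixed-nucleotide codon allowing 2-6 residues).
#'
#' @param mode One of `"fixed"`, `"fully_randomized"`,
#'   `"partially_randomized"`.
#' @param codon For randomised modes, the 3-letter IUPAC pattern; ignored for
#'   fixed positions.
#' @param residue For fixed positions, the single allowed amino acid.
#' @param code Genetic code used to validate the allowed-residue counts.
#' @return A `position_scheme` list with fields `mode`, `codon`, `residue`,
#'   `allowed` (residues, stop excluded).
#' @export
position_scheme <- function(mode = c("fixed", "fully_randomized",
                                     "partially_randomized"),
                            codon = NULL, residue = NULL,
                            code = standard_genetic_code()) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(residue) || !grepl("^[A-Z]$", residue) ||
        !residue %in% names(AA_TO_CODON))
      stop("fixed position needs a single standard amino-acid residue")
    out <- list(mode = mode, codon = AA_TO_CODON[[residue]],
                residue = residue, allowed = residue)
  } else {
    codon <- validate_degenerate_codon(codon)
    allowed <- allowed_residues(codon, code)
    if (mode == "partially_randomized" &&
        (length(allowed) < 2L || length(allowed) > 6L))
      stop("partially randomized position must allow 2-6 amino acids, '",
           codon, "' allows ", length(allowed))
    if (mode == "fully_randomized" && length(allowed) < 20L)
      stop("fully randomized position must encode all 20 amino acids, '",
           codon, "' encodes ", length(allowed))
    out <- list(mode = mode, codon = codon, residue = NA_character_,
                allowed = allowed)
  }
  structure(out, class = "position_scheme")
}

#' Scheme-list builders
#'
#' `scheme_fixed("GST")` gives one fixed [position_scheme()] per residue;
#' `scheme_nnb(4)` gives a run of fully randomised NNB positions.
#'
#' @param residues Amino-acid string, one fixed position per character.
#' @param n Number of NNB positions.
#' @return List of [position_scheme()] objects.
#' @export
scheme_fixed <- function(residues) {
  lapply(strsplit(residues, "")[[1]], function(r)
    position_scheme("fixed", residue = r))
}

#' @rdname scheme_fixed
#' @export
scheme_nnb <- function(n) {
  replicate(n, position_scheme("fully_randomized", codon = "NNB"),
            simplify = FALSE)
}

#' Construct a nanobody library design
#'
#' Describes a single-framework synthetic library: four constant framework
#' segments, per-position randomisation schemes for CDR1 and CDR2, a set of
#' CDR3 length classes each consisting entirely of fully randomised (NNB)
#' codons, the molar weights with which the classes were ligated, and the
#' expected C-terminal motif of the sequenced region.
#'
#' @param frameworks Character vector of four amino-acid strings
#'   (FR1..FR4).
#' @param cdr1,cdr2 Lists of [position_scheme()] objects.
#' @param cdr3_lengths Named integer vector of NNB run lengths per class;
#'   default `c(short = 7, medium = 11, long = 15)`.
#' @param cdr3_weights Ligation weights per class, normalised to sum to 1;
#'   default the 1:2:1 short/medium/long molar mix.
#' @param terminal_motif C-terminal amino acids checked by the intact filter;
#'   default the FR4 tail `"VTVSS"`.
#' @param genetic_code Codon table; default [standard_genetic_code()].
#' @return An object of class `library_design`.
#' @export
library_design <- function(frameworks, cdr1, cdr2,
                           cdr3_lengths = c(short = 7L, medium = 11L,
                                            long = 15L),
                           cdr3_weights = c(short = 1, medium = 2, long = 1),
                           terminal_motif = "VTVSS",
                           genetic_code = standard_genetic_code()) {
  if (length(frameworks) != 4L || !is.character(frameworks))
    stop("frameworks must be four amino-acid strings FR1..FR4")
  names(frameworks) <- paste0("FR", 1:4)
  stopifnot(all(vapply(cdr1, inherits, TRUE, "position_scheme")),
            all(vapply(cdr2, inherits, TRUE, "position_scheme")))
  cdr3_lengths <- cdr3_lengths[sort(names(cdr3_lengths))]
  cdr3_weights <- cdr3_weights[names(cdr3_lengths)]
  if (anyNA(cdr3_weights) || any(cdr3_weights < 0) || sum(cdr3_weights) <= 0)
    stop("cdr3_weights must be non-negative, named like cdr3_lengths")
  cdr3_weights <- cdr3_weights / sum(cdr3_weights)
  if (anyDuplicated(cdr3_lengths))
    stop("CDR3 class lengths must be distinct (length-based class assignment)")
  if (!grepl("^[A-Z]+$", terminal_motif))
    stop("terminal_motif must be an amino-acid string")

  d <- structure(list(
    frameworks = frameworks,
    cdr1 = cdr1, cdr2 = cdr2,
    cdr3_lengths = as.integer(cdr3_lengths),
    cdr3_weights = cdr3_weights,
    terminal_motif = terminal_motif,
    genetic_code = genetic_code
  ), class = "library_design")
  names(d$cdr3_lengths) <- names(cdr3_lengths)

  # rendered amino-acid length per class must be unique
  if (anyDuplicated(rendered_lengths(d)))
    stop("rendered lengths per CDR3 class are not unique")
  full <- paste0(frameworks[["FR4"]])
  if (!endsWith(full, terminal_motif))
    stop("terminal_motif must be a suffix of FR4")
  d
}

#' @export
print.library_design <- function(x, ...) {
  cat("library_design:",
      sum(nchar(x$frameworks)), "framework residues;",
      length(x$cdr1), "CDR1 +", length(x$cdr2), "CDR2 positions;",
      "CDR3 classes", paste(sprintf("%s=%d", names(x$cdr3_lengths),
                                    x$cdr3_lengths), collapse = ", "),
      "\n")
  invisible(x)
}

cdr3_schemes <- function(design, class) {
  n <- design$cdr3_lengths[[class]]
  replicate(n, position_scheme("fully_randomized", codon = "NNB",
                               code = design$genetic_code),
            simplify = FALSE)
}

# randomised (non-fixed) schemes across CDR1+CDR2+CDR3(class)
randomized_schemes <- function(design, cdr3_class) {
  all <- c(design$cdr1, design$cdr2, cdr3_schemes(design, cdr3_class))
  Filter(function(s) s$mode != "fixed", all)
}

#' Rendered amino-acid length of each CDR3 class
#' @param design A [library_design()].
#' @return Named integer vector (class -> full-sequence length).
#' @export
rendered_lengths <- function(design) {
  base <- sum(nchar(design$frameworks)) + length(design$cdr1) +
    length(design$cdr2)
  setNames(base + design$cdr3_lengths, names(design$cdr3_lengths))
}

#' Probability that a library clone carries no stop codon
#'
#' Product over the randomised positions of one CDR3 class of
#' (1 - per-position stop fraction). Models stop codons only; assembly
#' indels are a separate process.
#'
#' @param design A [library_design()].
#' @param cdr3_class Class name (e.g. `"short"`).
#' @param amber_readthrough Treat TAG as Gln (amber suppression).
#' @return Probability in (0, 1].
#' @examples
#' # 7 NNB positions alone would give (47/48)^7
#' @export
stop_free_probability <- function(design, cdr3_class,
                                  amber_readthrough = FALSE) {
  if (!cdr3_class %in% names(design$cdr3_lengths))
    stop("unknown cdr3_class '", cdr3_class, "'")
  code <- if (amber_readthrough)
    standard_genetic_code(amber_readthrough = TRUE) else design$genetic_code
  scheme_list <- randomized_schemes(design, cdr3_class)
  prod(vapply(scheme_list, function(s) 1 - stop_fraction(s$codon, code),
              numeric(1)))
}

#' Theoretical amino-acid diversity of the design
#'
#' Product of allowed-residue counts (stop excluded) over all randomised
#' positions, per CDR3 class; the total is the class-weighted sum.
#'
#' @param design A [library_design()].
#' @return List with `per_class` (named numeric), `total`, and their log10s.
#' @export
theoretical_diversity <- function(design) {
  per_class <- vapply(names(design$cdr3_lengths), function(cl) {
    prod(vapply(randomized_schemes(design, cl),
                function(s) length(s$allowed), numeric(1)))
  }, numeric(1))
  total <- sum(design$cdr3_weights * per_class)
  list(per_class = per_class, total = total,
       log10_per_class = log10(per_class), log10_total = log10(total))
}

#' Render a full protein sequence from CDR residues
#'
#' Concatenates FR1 + CDR1 + FR2 + CDR2 + FR3 + CDR3 + FR4 after validating
#' every CDR residue against its position scheme.
#'
#' @param design A [library_design()].
#' @param cdrs List or character vector of three amino-acid strings
#'   (CDR1, CDR2, CDR3).
#' @return Single amino-acid string.
#' @export
render_template <- function(design, cdrs) {
  cdrs <- as.character(unlist(cdrs))
  if (length(cdrs) != 3L) stop("cdrs must supply CDR1, CDR2 and CDR3")
  check_cdr <- function(seq, schemes, label) {
    if (nchar(seq) != length(schemes))
      stop(label, " length ", nchar(seq), " does not match scheme length ",
           length(schemes))
    res <- strsplit(seq, "")[[1]]
    for (i in seq_along(res)) {
      if (!res[[i]] %in% schemes[[i]]$allowed)
        stop(label, " position ", i, ": residue '", res[[i]],
             "' not allowed by scheme")
    }
  }
  if (!nchar(cdrs[[3]]) %in% design$cdr3_lengths)
    stop("CDR3 length ", nchar(cdrs[[3]]), " matches no design class (",
         paste(design$cdr3_lengths, collapse = "/"), ")")
  cl <- names(design$cdr3_lengths)[match(nchar(cdrs[[3]]),
                                         design$cdr3_lengths)]
  check_cdr(cdrs[[1]], design$cdr1, "CDR1")
  check_cdr(cdrs[[2]], design$cdr2, "CDR2")
  check_cdr(cdrs[[3]], cdr3_schemes(design, cl), "CDR3")
  fr <- design$frameworks
  paste0(fr[["FR1"]], cdrs[[1]], fr[["FR2"]], cdrs[[2]], fr[["FR3"]],
         cdrs[[3]], fr[["FR4"]])
}

# nucleotide template segments (frameworks and fixed CDR positions reverse
# translated deterministically); randomised positions are NA and filled by
# the simulator
design_nt_segments <- function(design) {
  rt <- function(aa) paste(AA_TO_CODON[strsplit(aa, "")[[1]]], collapse = "")
  scheme_nt <- function(schemes)
    vapply(schemes, function(s)
      if (s$mode == "fixed") s$codon else NA_character_, character(1))
  list(frameworks = vapply(design$frameworks, rt, character(1)),
       cdr1 = scheme_nt(design$cdr1), cdr2 = scheme_nt(design$cdr2))
}

#' The package's default library design
#'
#' A generic single-framework VHH topology with three CDRs: CDR1 carries four
#' NNB sites plus two partially randomised mixed-nucleotide sites, CDR2 three
#' NNB sites plus two partially randomised sites, and CDR3 is a run of 7, 11
#' or 15 NNB codons (short/medium/long) ligated at 1:2:1 molar weights. The
#' exact identity of the partially randomised sites is a documented
#' assumption, configurable via [read_design_json()].
#'
#' @param cdr3_weights Optional override of the class weights.
#' @return A [library_design()].
#' @export
default_design <- function(cdr3_weights = c(short = 1, medium = 2, long = 1)) {
  library_design(
    frameworks = c(
      "QVQLVESGGGLVQAGGSLRLSCAAS",         # FR1
      "WFRQAPGKEREFVA",                    # FR2
      "YYADSVKGRFTISRDNAKNTVYLQMNSLKPEDTAVYYCAA", # FR3
      "WGQGTQVTVSS"                        # FR4
    ),
    cdr1 = c(
      scheme_fixed("G"),
      scheme_nnb(4),
      list(position_scheme("partially_randomized", codon = "KMT")), # A/D/S/Y
      scheme_fixed("M"),
      list(position_scheme("partially_randomized", codon = "VRC"))  # D/G/H/N/R/S
    ),
    cdr2 = c(
      scheme_nnb(3),
      list(position_scheme("partially_randomized", codon = "KMT")),
      scheme_fixed("GST"),
      list(position_scheme("partially_randomized", codon = "VRC"))
    ),
    cdr3_weights = cdr3_weights
  )
}

#' Write a library design to JSON
#' @param design A [library_design()].
#' @param path Output file.
#' @export
write_design_json <- function(design, path) {
  enc_schemes <- function(schemes)
    lapply(schemes, function(s)
      list(mode = s$mode,
           codon = if (s$mode == "fixed") NULL else s$codon,
           residue = if (s$mode == "fixed") s$residue else NULL))
  obj <- list(
    frameworks = as.list(design$frameworks),
    cdr1 = enc_schemes(design$cdr1),
    cdr2 = enc_schemes(design$cdr2),
    cdr3_lengths = as.list(design$cdr3_lengths),
    cdr3_weights = as.list(design$cdr3_weights),
    terminal_motif = design$terminal_motif
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a library design from JSON
#' @param path JSON file written by [write_design_json()] or hand-authored in
#'   the same shape.
#' @param genetic_code Optional codon-table override.
#' @return A [library_design()].
#' @export
read_design_json <- function(path, genetic_code = standard_genetic_code()) {
  obj <- jsonlite::read_json(path)
  dec_schemes <- function(lst)
    lapply(lst, function(s) {
      if (identical(s$mode, "fixed"))
        position_scheme("fixed", residue = s$residue, code = genetic_code)
      else position_scheme(s$mode, codon = s$codon, code = genetic_code)
    })
  library_design(
    frameworks = unlist(obj$frameworks),
    cdr1 = dec_schemes(obj$cdr1),
    cdr2 = dec_schemes(obj$cdr2),
    cdr3_lengths = unlist(obj$cdr3_lengths),
    cdr3_weights = unlist(obj$cdr3_weights),
    terminal_motif = obj$terminal_motif,
    genetic_code = genetic_code
  )
}
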