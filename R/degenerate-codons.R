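# Degenerate-codon algebra: IUPAC expansion and exact amino-acid expectations.

#' IUPAC nucleotide degeneracy table
#'
#' Named list mapping each single-letter IUPAC nucleotide code to the set of
#' concrete bases it denotes, e.g. `N = c("A","C","G","T")`,
#' `B = c("C","G","T")`.
#'
#' @export
IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' The standard genetic code
#'
#' Returns the codon-to-residue table used throughout the package, a named
#' character vector of length 64 with `"*"` for the three stop codons
#' (standard code, NCBI translation table 1).
#'
#' @param amber_readthrough If `TRUE`, the amber codon TAG is reassigned to
#'   glutamine (Q), modelling display in an amber-suppressor *E. coli* strain
#'   such as TG1. Default `FALSE`: all three stops count as stops.
#' @return Named character vector, names are codons.
#' @export
standard_genetic_code <- function(amber_readthrough = FALSE) {
  code <- Biostrings::GENETIC_CODE
  code <- setNames(as.character(code), names(code))
  if (amber_readthrough) code[["TAG"]] <- "Q"
  code
}

#' Read a genetic code from a two-column file
#'
#' Plain-text override of the codon table: whitespace- or tab-separated
#' `codon residue` rows, `*` marking stop codons. All 64 codons must be
#' present.
#'
#' @param path File path.
#' @return Named character vector as in [standard_genetic_code()].
#' @export
read_codon_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("codon", "aa"),
                           colClasses = "character")
  tab$codon <- toupper(tab$codon)
  if (any(duplicated(tab$codon))) stop("duplicated codons in codon table")
  if (length(tab$codon) != 64L || !setequal(tab$codon, names(Biostrings::GENETIC_CODE)))
    stop("codon table must define all 64 codons")
  setNames(tab$aa, tab$codon)
}

validate_degenerate_codon <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern))
    stop("degenerate codon pattern must be a single string")
  pattern <- toupper(pattern)
  if (nchar(pattern) != 3L)
    stop("degenerate codon pattern must have length 3, got '", pattern, "'")
  letters <- strsplit(pattern, "")[[1]]
  bad <- setdiff(letters, names(IUPAC_NT))
  if (length(bad))
    stop("invalid IUPAC nucleotide code '", bad[[1]], "' in pattern '",
         pattern, "'")
  pattern
}

#' Expand a degenerate codon to its concrete codons
#'
#' The Cartesian product of the per-letter IUPAC degeneracies, so e.g. `NNB`
#' expands to 4 x 4 x 3 = 48 codons and `NNK` to 32.
#'
#' @param pattern 3-letter IUPAC string (e.g. `"NNB"`).
#' @return Character vector of concrete codons (no duplicates).
#' @examples
#' length(expand_degenerate_codon("NNB")) # 48
#' @export
expand_degenerate_codon <- function(pattern) {
  pattern <- validate_degenerate_codon(pattern)
  letters <- strsplit(pattern, "")[[1]]
  sets <- lapply(letters, function(l) IUPAC_NT[[l]])
  grid <- expand.grid(sets[[3]], sets[[2]], sets[[1]],
                      stringsAsFactors = FALSE)
  sort(paste0(grid[[3]], grid[[2]], grid[[1]]))
}

#' Expected amino-acid frequencies of a degenerate codon
#'
#' Each concrete codon in the expansion is taken as equiprobable (uniform
#' nucleotide mixing); the returned fractions are codon multiplicities over
#' the expansion size. Stops are reported under `"*"`.
#'
#' @param pattern 3-letter IUPAC string.
#' @param code Genetic code table, default [standard_genetic_code()].
#' @return Named numeric vector over the residues that occur (plus `"*"` when
#'   a stop codon is in the expansion); sums to 1.
#' @examples
#' f <- expected_aa_frequencies("NNB")
#' f[["W"]] # 1/48
#' f[["*"]] # 1/48 (TAG only)
#' @export
expected_aa_frequencies <- function(pattern, code = standard_genetic_code()) {
  codons <- expand_degenerate_codon(pattern)
  aa <- code[codons]
  if (anyNA(aa)) stop("genetic code table is missing codons")
  tab <- table(aa)
  setNames(as.numeric(tab) / length(codons), names(tab))
}

# residues (stop excluded) a scheme's codon can encode
allowed_residues <- function(pattern, code = standard_genetic_code()) {
  f <- expected_aa_frequencies(pattern, code)
  sort(setdiff(names(f), "*"))
}

stop_fraction <- function(pattern, code = standard_genetic_code()) {
  f <- expected_aa_frequencies(pattern, code)
  if ("*" %in% names(f)) unname(f[["*"]]) else 0
}
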