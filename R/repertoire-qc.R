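# Repertoire quality control: CDR extraction, positional composition,
# observed/expected comparison, occurrence spectrum, CDR3 class mix.

#' Extract CDR sequences from an intact clone
#'
#' CDR boundaries follow directly from the design's constant frameworks
#' (single-framework library), located by exact match of the flanking
#' framework segments; the CDR3 class is assigned from the rendered length.
#'
#' @param seq Character vector of intact amino-acid sequences.
#' @param design A [library_design()].
#' @return `data.table` with columns `cdr1`, `cdr2`, `cdr3`, `cdr3_class`.
#' @export
extract_cdrs <- function(seq, design) {
  lens <- rendered_lengths(design)
  cls <- names(lens)[match(nchar(seq), lens)]
  if (anyNA(cls))
    stop("anchor_mismatch: sequence length matches no design class")
  fr <- design$frameworks
  n1 <- nchar(fr[["FR1"]]); c1 <- length(design$cdr1)
  n2 <- nchar(fr[["FR2"]]); c2 <- length(design$cdr2)
  n3 <- nchar(fr[["FR3"]])
  c3 <- design$cdr3_lengths[cls]
  cdr1 <- substr(seq, n1 + 1L, n1 + c1)
  cdr2 <- substr(seq, n1 + c1 + n2 + 1L, n1 + c1 + n2 + c2)
  off3 <- n1 + c1 + n2 + c2 + n3
  cdr3 <- substr(seq, off3 + 1L, off3 + c3)
  # verify the framework anchors really are where the design says
  anchors_ok <- startsWith(seq, fr[["FR1"]]) &
    substr(seq, n1 + c1 + 1L, n1 + c1 + n2) == fr[["FR2"]] &
    substr(seq, n1 + c1 + n2 + c2 + 1L, off3) == fr[["FR3"]] &
    substr(seq, off3 + c3 + 1L, nchar(seq)) == fr[["FR4"]]
  if (!all(anchors_ok))
    stop("anchor_mismatch: framework segments not found in ",
         sum(!anchors_ok), " sequence(s)")
  data.table(cdr1 = cdr1, cdr2 = cdr2, cdr3 = cdr3, cdr3_class = cls)
}

#' Positional residue composition of a repertoire
#'
#' Read-weighted residue frequencies at every randomised (non-fixed) CDR
#' position, computed per CDR3 class.
#'
#' @param rep A [repertoire_table()] of intact sequences.
#' @param design A [library_design()].
#' @param weighting `"reads"` (each read one vote, default) or `"unique"`
#'   (each unique sequence one vote).
#' @return `composition_matrix`: a `data.table` with columns `cdr3_class`,
#'   `cdr`, `position` (1-based within the CDR), `mode`, `residue`,
#'   `fraction`; fractions sum to 1 within each (class, cdr, position).
#' @export
position_composition <- function(rep, design,
                                 weighting = c("reads", "unique")) {
  weighting <- match.arg(weighting)
  if (!nrow(rep)) stop("empty repertoire")
  w <- if (weighting == "reads") rep$count else rep(1L, nrow(rep))
  cdrs <- extract_cdrs(rep$sequence, design)
  out <- list()
  for (cl in unique(cdrs$cdr3_class)) {
    sel <- cdrs$cdr3_class == cl
    wcl <- w[sel]
    schemes <- list(cdr1 = design$cdr1, cdr2 = design$cdr2,
                    cdr3 = cdr3_schemes(design, cl))
    for (cdr_name in names(schemes)) {
      seqs <- cdrs[[cdr_name]][sel]
      sch <- schemes[[cdr_name]]
      for (p in seq_along(sch)) {
        if (sch[[p]]$mode == "fixed") next
        res <- substr(seqs, p, p)
        agg <- tapply(wcl, res, sum)
        out[[length(out) + 1L]] <- data.table(
          cdr3_class = cl, cdr = cdr_name, position = p,
          mode = sch[[p]]$mode,
          residue = names(agg), fraction = as.numeric(agg) / sum(wcl))
      }
    }
  }
  comp <- rbindlist(out)
  structure(comp, class = c("composition_matrix", class(comp)))
}

#' Compare observed composition to the design expectation
#'
#' For the fully randomised sites of one CDR3 class, computes per-residue
#' observed/expected ratios averaged over sites, and the per-position total
#' variation distance. Stops cannot occur in intact sequences, so the
#' expectation is renormalised over the 20 residues.
#'
#' @param comp A [position_composition()] result.
#' @param design A [library_design()].
#' @param cdr3_class Class to compare (default `"short"`).
#' @return List with `ratios` (named over the 20 residues; observed/expected
#'   averaged over fully randomised sites), `tv` (`data.table` of
#'   per-position total variation distances), and `max_tv`.
#' @export
compare_to_expected <- function(comp, design, cdr3_class = "short") {
  sel <- comp$cdr3_class == cdr3_class & comp$mode == "fully_randomized"
  obs <- comp[which(sel), ]
  if (!nrow(obs)) stop("no fully randomized positions for class '",
                       cdr3_class, "'")
  if (any(!obs$residue %in% c(names(AA_TO_CODON), "X", "*")))
    stop("residue absent from expectation table")
  schemes <- list(cdr1 = design$cdr1, cdr2 = design$cdr2,
                  cdr3 = cdr3_schemes(design, cdr3_class))
  aas <- sort(names(AA_TO_CODON))
  ratio_acc <- setNames(numeric(length(aas)), aas)
  tv <- list()
  keys <- unique(obs[, c("cdr", "position")])
  for (i in seq_len(nrow(keys))) {
    cdr_name <- keys$cdr[[i]]; p <- keys$position[[i]]
    sch <- schemes[[cdr_name]][[p]]
    ef <- expected_aa_frequencies(sch$codon, design$genetic_code)
    ef <- ef[setdiff(names(ef), "*")]
    ef <- ef / sum(ef)                       # renormalise without stop
    expv <- setNames(numeric(length(aas)), aas)
    expv[names(ef)] <- ef
    o <- obs[obs$cdr == cdr_name & obs$position == p, ]
    obsv <- setNames(numeric(length(aas)), aas)
    obsv[o$residue[o$residue %in% aas]] <-
      o$fraction[o$residue %in% aas]
    obsv <- obsv / sum(obsv)
    ratio_acc <- ratio_acc + obsv / expv
    tv[[length(tv) + 1L]] <- data.table(
      cdr = cdr_name, position = p, tv = 0.5 * sum(abs(obsv - expv)))
  }
  tv <- rbindlist(tv)
  list(ratios = ratio_acc / nrow(keys), tv = tv, max_tv = max(tv$tv))
}

#' Occurrence spectrum of a repertoire
#'
#' Fractions of *unique* sequences observed exactly once, twice, three
#' times, or more than three times.
#'
#' @param rep A [repertoire_table()].
#' @return Named numeric vector `c("1", "2", "3", ">3")` summing to 1.
#' @export
occurrence_spectrum <- function(rep) {
  if (!nrow(rep)) stop("empty repertoire")
  bucket <- cut(rep$count, c(0, 1, 2, 3, Inf), labels = c("1", "2", "3", ">3"))
  out <- table(bucket) / nrow(rep)
  setNames(as.numeric(out), names(out))
}

#' CDR3 length-class proportions
#'
#' Read-weighted fraction of intact reads in each CDR3 class.
#'
#' @param rep A [repertoire_table()] of intact sequences.
#' @param design A [library_design()].
#' @return Named numeric vector over the design's classes, summing to 1.
#' @export
cdr3_class_proportions <- function(rep, design) {
  lens <- rendered_lengths(design)
  cls <- names(lens)[match(nchar(rep$sequence), lens)]
  if (anyNA(cls)) stop("repertoire contains non-intact lengths")
  agg <- tapply(rep$count, factor(cls, levels = names(lens)), sum,
                default = 0L)
  setNames(as.numeric(agg) / sum(rep$count), names(lens))
}
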