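# Panning-pool analytics: per-pool percentages, the positive/negative
# specificity ratio, candidate selection, homolog families, phage ELISA.

#' Annotate a repertoire as a panning pool
#'
#' @param rep A [repertoire_table()].
#' @param round Round label (e.g. `3L` or `"round3"`).
#' @param pool `"positive"` or `"negative"`.
#' @return `pool_table`: the repertoire with a `pct` column
#'   (count / total x 100).
#' @export
pool_table <- function(rep, round = NA, pool = c("positive", "negative")) {
  pool <- match.arg(pool)
  total <- sum(rep$count)
  if (total <= 0L) stop("zero-total pool")
  out <- data.table(sequence = rep$sequence, count = rep$count,
                    pct = rep$count / total * 100)
  structure(out, class = c("pool_table", class(out)),
            round = round, pool = pool, total = total)
}

#' Positive/negative specificity scores
#'
#' For every sequence in the positive pool, the ratio of its percentage in
#' the positive pool to its percentage in the negative pool. A sequence
#' absent from the negative pool gets a pseudocount: its negative percentage
#' is `pseudocount / (negative total + pseudocount) * 100`.
#'
#' @param pos,neg [pool_table()]s from the same round.
#' @param pseudocount Reads added to an absent negative count, default 1.
#' @return `data.table` with columns `sequence`, `pct_positive`,
#'   `pct_negative`, `ratio`, `rank_by_abundance`.
#' @export
specificity_scores <- function(pos, neg, pseudocount = 1) {
  if (attr(pos, "total") <= 0 || attr(neg, "total") <= 0)
    stop("zero-total pool")
  neg_total <- attr(neg, "total")
  idx <- match(pos$sequence, neg$sequence)
  neg_count <- neg$count[idx]
  pct_neg <- ifelse(is.na(neg_count),
                    pseudocount / (neg_total + pseudocount) * 100,
                    neg_count / neg_total * 100)
  out <- data.table(sequence = pos$sequence,
                    pct_positive = pos$pct,
                    pct_negative = pct_neg,
                    ratio = pos$pct / pct_neg)
  setorder(out, -pct_positive, sequence)
  out[, rank_by_abundance := seq_len(.N)]
  out[]
}

#' Select candidate binders
#'
#' Strict thresholds on abundance in the positive pool and on the
#' specificity ratio; output sorted by positive-pool percentage descending,
#' ties by sequence.
#'
#' @param records Output of [specificity_scores()].
#' @param min_pct_positive Abundance gate in percent (strict `>`), default
#'   0.01.
#' @param min_ratio Ratio gate (strict `>`), default 10.
#' @return Filtered, sorted `data.table`.
#' @export
select_candidates <- function(records, min_pct_positive = 0.01,
                              min_ratio = 10) {
  out <- records[records$pct_positive > min_pct_positive &
                   records$ratio > min_ratio, ]
  setorder(out, -pct_positive, sequence)
  out[]
}

#' Greedy homolog-family clustering by Hamming distance
#'
#' Repeatedly takes the most abundant unassigned candidate as a family seed
#' and assigns every unassigned candidate with the same concatenated-CDR
#' length within `max_distance` substitutions of the seed.
#'
#' @param candidates Output of [select_candidates()] (needs `sequence` and
#'   `pct_positive`).
#' @param design A [library_design()] used to extract the CDRs.
#' @param max_distance Maximum Hamming distance to the seed, default 2.
#' @return The input with added columns `family` (integer id, 1 = most
#'   abundant seed), `is_seed`, `dist_to_seed`.
#' @export
cluster_by_hamming <- function(candidates, design, max_distance = 2L) {
  out <- as.data.table(candidates)
  setorder(out, -pct_positive, sequence)
  n <- nrow(out)
  out[, `:=`(family = NA_integer_, is_seed = FALSE,
             dist_to_seed = NA_integer_)]
  if (n == 0L) return(out[])
  cdrs <- extract_cdrs(out$sequence, design)
  key <- paste0(cdrs$cdr1, cdrs$cdr2, cdrs$cdr3)
  fam <- 0L
  assigned <- rep(FALSE, n)
  while (any(!assigned)) {
    seed_i <- which(!assigned)[1L]        # rows pre-sorted by abundance
    fam <- fam + 1L
    d <- .hamming_to_seed_cpp(key[[seed_i]], key)
    memb <- which(!assigned & !is.na(d) & d <= max_distance)
    assigned[memb] <- TRUE
    out$family[memb] <- fam
    out$dist_to_seed[memb] <- d[memb]
    out$is_seed[seed_i] <- TRUE
  }
  out[]
}

#' Per-round enrichment trajectory of one sequence
#'
#' @param pools List of [pool_table()]s (one per round, in order).
#' @param sequence Amino-acid sequence to track.
#' @return `data.table` with columns `round`, `pct` (0 when absent) and
#'   `rank` (`NA` when absent; rank 1 = most abundant).
#' @export
track_enrichment <- function(pools, sequence) {
  rows <- lapply(seq_along(pools), function(i) {
    p <- pools[[i]]
    ord <- order(-p$pct, p$sequence)
    rk <- match(sequence, p$sequence[ord])
    data.table(round = if (!is.null(attr(p, "round")) &&
                           !is.na(attr(p, "round"))) attr(p, "round") else i,
               pct = if (is.na(rk)) 0 else p$pct[ord][rk],
               rank = rk)
  })
  rbindlist(rows)
}

#' Single-clone phage-ELISA specificity call
#'
#' Score = antigen-well absorbance / blocked-control absorbance. A clone is
#' a specific binder iff the control absorbance is below `max_control` and
#' the score exceeds `min_score` (both strict). A zero control absorbance
#' yields an infinite score; the call is then made on the antigen well alone
#' (antigen > `max_control * min_score`) and flagged.
#'
#' @param absorbance_antigen,absorbance_control A450 readings (vectorised).
#' @param max_control Control-well ceiling, default 0.1.
#' @param min_score Score threshold, default 5.
#' @return `data.table` with columns `score`, `is_specific`,
#'   `zero_control_flag`.
#' @export
phage_elisa_call <- function(absorbance_antigen, absorbance_control,
                             max_control = 0.1, min_score = 5) {
  if (any(absorbance_antigen < 0) || any(absorbance_control < 0))
    stop("absorbances must be non-negative")
  zero <- absorbance_control == 0
  score <- ifelse(zero, Inf, absorbance_antigen / absorbance_control)
  specific <- ifelse(zero,
                     absorbance_antigen > max_control * min_score,
                     absorbance_control < max_control & score > min_score)
  data.table(score = score, is_specific = specific,
             zero_control_flag = zero)
}
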