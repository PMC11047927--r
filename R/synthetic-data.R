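# Seeded generators for every input the pipeline consumes: library clones,
# paired FASTQ reads with assembly defects, multi-round panning pools with
# planted binders, dose-response plates, and noisy sensorgrams. Every
# generator is a pure function of (config, seed) and returns ground truth
# alongside the data.

with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Simulation configuration
#'
#' Bundles the generator's tunables with their defaults: a library whose
#' clone-level defect rates emulate error-prone assembly PCR (roughly 60-65%
#' of reads defective once NNB-intrinsic stop codons are included), Novaseq
#'-like 2 x 250 bp reads with a small substitution rate, a three-round
#' panning scheme with planted specific and sticky (nonspecifically
#' enriching) clones, and plate/sensorgram noise levels.
#'
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @param n_clones Library size (distinct clones), default 20000.
#' @param depth Read pairs per FASTQ sample, default 50000.
#' @param indel_rate Per-clone probability of a frameshifting 1-2 nt
#'   assembly indel, default 0.42.
#' @param stop_injection_rate Per-clone probability of an assembly-derived
#'   premature stop beyond the NNB-intrinsic ones, default 0.04.
#' @param terminal_corruption_rate Per-clone probability of a corrupted
#'   C-terminal motif, default 0.04.
#' @param substitution_rate Per-base sequencing substitution probability,
#'   default 0.001.
#' @param class_weights CDR3 class ligation weights, default 1:2:1.
#' @param read_length Read length in bases, default 250.
#' @param panning List of panning parameters: `rounds` (3), `bottleneck`
#'   (1e5 eluted phages per round), `n_background` (1e4), `n_specific` (5),
#'   `e_spec` (50), `n_sticky` (50), `e_bg` (30), `ngs_depth` (2e5).
#' @param plate_cv Coefficient of variation of plate responses, default
#'   0.05.
#' @param sensor_noise_sd Gaussian noise on sensorgrams, nm, default 0.005.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_clones = 20000L, depth = 50000L,
                              indel_rate = 0.42,
                              stop_injection_rate = 0.04,
                              terminal_corruption_rate = 0.04,
                              substitution_rate = 0.001,
                              class_weights = c(short = 1, medium = 2,
                                                long = 1),
                              read_length = 250L,
                              panning = list(),
                              plate_cv = 0.05,
                              sensor_noise_sd = 0.005) {
  if (missing(seed)) stop("a seed is mandatory")
  rates <- c(indel_rate, stop_injection_rate, terminal_corruption_rate,
             substitution_rate, plate_cv)
  if (any(rates < 0) || any(rates[1:4] > 1)) stop("rates must lie in [0,1]")
  pan <- modifyList(list(rounds = 3L, bottleneck = 1e5, n_background = 1e4,
                         n_specific = 5L, e_spec = 50, n_sticky = 50L,
                         e_bg = 30, ngs_depth = 2e5), panning)
  structure(list(seed = as.integer(seed), n_clones = as.integer(n_clones),
                 depth = as.integer(depth), indel_rate = indel_rate,
                 stop_injection_rate = stop_injection_rate,
                 terminal_corruption_rate = terminal_corruption_rate,
                 substitution_rate = substitution_rate,
                 class_weights = class_weights / sum(class_weights),
                 read_length = as.integer(read_length),
                 panning = pan, plate_cv = plate_cv,
                 sensor_noise_sd = sensor_noise_sd),
            class = "simulation_config")
}

# draw one concrete codon per scheme position, vectorised over n clones;
# returns an n-vector of nucleotide strings
sample_cdr_nt <- function(schemes, n) {
  cols <- lapply(schemes, function(s) {
    if (s$mode == "fixed") rep(s$codon, n)
    else sample(expand_degenerate_codon(s$codon), n, replace = TRUE)
  })
  do.call(paste0, cols)
}

mutate_string_at <- function(x, pos, repl) {
  paste0(substr(x, 1, pos - 1L), repl, substr(x, pos + nchar(repl), nchar(x)))
}

#' Simulate a synthetic nanobody library at the nucleotide level
#'
#' Clones are drawn from the design: NNB and partially randomised codons are
#' sampled uniformly from their expansions (so stop codons arise at the
#' NNB-intrinsic rate), CDR3 classes follow the configured ligation weights,
#' and assembly defects (frameshifting indels, injected premature stops,
#' terminal-motif corruption) are applied at the configured per-clone rates.
#'
#' @param config A [simulation_config()].
#' @param design A [library_design()].
#' @return `data.table` ground truth with one row per clone: `clone_id`,
#'   `cdr3_class`, `nt` (diversified-region nucleotides, post-defect), `aa`
#'   (`NA` when frame-shifted), `defect` (`none`, `indel`, `stop_injected`,
#'   `terminal`, `nnb_stop`) and `intact`.
#' @export
simulate_library <- function(config, design = default_design()) {
  with_seed(config$seed, {
    n <- config$n_clones
    cls <- sample(names(design$cdr3_lengths), n, replace = TRUE,
                  prob = config$class_weights[names(design$cdr3_lengths)])
    seg <- design_nt_segments(design)
    cdr1 <- sample_cdr_nt(design$cdr1, n)
    cdr2 <- sample_cdr_nt(design$cdr2, n)
    cdr3 <- character(n)
    for (cl in names(design$cdr3_lengths)) {
      i <- which(cls == cl)
      if (length(i))
        cdr3[i] <- sample_cdr_nt(cdr3_schemes(design, cl), length(i))
    }
    nt <- paste0(seg$frameworks[["FR1"]], cdr1, seg$frameworks[["FR2"]],
                 cdr2, seg$frameworks[["FR3"]], cdr3,
                 seg$frameworks[["FR4"]])
    defect <- rep("none", n)

    # assembly indels: remove or duplicate 1-2 nt at a random position
    ind <- runif(n) < config$indel_rate
    if (any(ind)) {
      w <- which(ind)
      del <- runif(length(w)) < 0.5
      k <- sample(1:2, length(w), replace = TRUE)
      pos <- floor(runif(length(w)) * (nchar(nt[w]) - 3L)) + 2L
      nt[w] <- ifelse(del,
                      paste0(substr(nt[w], 1, pos - 1L),
                             substr(nt[w], pos + k, nchar(nt[w]))),
                      paste0(substr(nt[w], 1, pos),
                             substr(nt[w], pos - k + 1L, pos),
                             substr(nt[w], pos + 1L, nchar(nt[w]))))
      defect[w] <- "indel"
    }
    # injected premature stops: overwrite one CDR3 codon with TAA/TGA
    stp <- defect == "none" & runif(n) < config$stop_injection_rate
    if (any(stp)) {
      w <- which(stp)
      off <- nchar(seg$frameworks[["FR1"]]) + nchar(cdr1[w]) +
        nchar(seg$frameworks[["FR2"]]) + nchar(cdr2[w]) +
        nchar(seg$frameworks[["FR3"]])
      codon_i <- vapply(design$cdr3_lengths[cls[w]],
                        function(m) sample.int(m, 1L), integer(1))
      nt[w] <- mutate_string_at(nt[w], off + (codon_i - 1L) * 3L + 1L,
                                sample(c("TAA", "TGA"), length(w),
                                       replace = TRUE))
      defect[w] <- "stop_injected"
    }
    # corrupted terminal motif: scramble the last two codons
    trm <- defect == "none" & runif(n) < config$terminal_corruption_rate
    if (any(trm)) {
      w <- which(trm)
      nt[w] <- paste0(substr(nt[w], 1, nchar(nt[w]) - 6L), "GGTGGC")
      defect[w] <- "terminal"
    }

    tl <- translate_region(nt, code = design$genetic_code)
    nnb_stop <- defect == "none" & tl$frame_ok &
      grepl("*", tl$aa, fixed = TRUE)
    defect[nnb_stop] <- "nnb_stop"
    out <- data.table(clone_id = sprintf("clone_%06d", seq_len(n)),
                      cdr3_class = cls, nt = nt, aa = tl$aa,
                      defect = defect, intact = defect == "none")
    out
  })
}

#' Simulate paired-end FASTQ reads from a clone table
#'
#' Reads are sampled from clones proportionally to their `weight` column
#' (uniform when absent); the amplicon is 5' primer + clone nucleotides +
#' 3' primer; mate 2 is reverse-complemented; per-base substitutions are
#' injected at the configured rate. Qualities are constant (`I`).
#'
#' @param clones `data.table` from [simulate_library()] (columns `clone_id`,
#'   `nt`, `intact`; optional `weight`).
#' @param depth Number of read pairs.
#' @param fastq1,fastq2 Output paths (plain text or `.gz`).
#' @param read_length Read length, default 250.
#' @param substitution_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param p5,p3 Primers in the amplicon layout.
#' @param min_overlap Configuration check: the two mates must overlap by at
#'   least this many bases on the longest amplicon.
#' @return Invisibly, a `data.table` ground truth with one row per read
#'   pair: `read_id`, `clone_id`, `intact`.
#' @export
simulate_fastq <- function(clones, depth, fastq1, fastq2,
                           read_length = 250L, substitution_rate = 0.001,
                           seed = 1L, p5 = DEFAULT_P5, p3 = DEFAULT_P3,
                           min_overlap = 20L) {
  with_seed(seed, {
    amplicon <- paste0(p5, clones$nt, p3)
    alen <- nchar(amplicon)
    if (max(alen) > 2L * read_length - min_overlap)
      stop("amplicon too long for the configured read length and overlap")
    if (depth == 0L) {
      writeLines(character(0), fastq1)
      writeLines(character(0), fastq2)
      return(invisible(data.table(read_id = character(),
                                  clone_id = character(),
                                  intact = logical())))
    }
    w <- if ("weight" %in% names(clones)) clones$weight
         else rep(1, nrow(clones))
    idx <- sample.int(nrow(clones), depth, replace = TRUE, prob = w)
    amp <- amplicon[idx]
    len <- alen[idx]
    r1 <- substr(amp, 1L, pmin(read_length, len))
    r2 <- revcomp(substr(amp, pmax(1L, len - read_length + 1L), len))
    inject <- function(reads) {
      nsub <- rbinom(length(reads), nchar(reads), substitution_rate)
      for (i in which(nsub > 0L)) {
        pos <- sample.int(nchar(reads[[i]]), nsub[[i]])
        for (p in pos) {
          orig <- substr(reads[[i]], p, p)
          substr(reads[[i]], p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                     orig), 1L)
        }
      }
      reads
    }
    r1 <- inject(r1); r2 <- inject(r2)
    ids <- sprintf("read_%07d_%s", seq_len(depth), clones$clone_id[idx])
    write_fq <- function(path, reads) {
      con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
      on.exit(close(con))
      writeLines(paste0("@", ids, "\n", reads, "\n+\n",
                        strrep("I", nchar(reads))), con)
    }
    write_fq(fastq1, r1)
    write_fq(fastq2, r2)
    invisible(data.table(read_id = ids, clone_id = clones$clone_id[idx],
                         intact = clones$intact[idx]))
  })
}

#' Simulate multi-round panning with planted binders
#'
#' Starts from a uniform pool of intact background clones plus planted
#' specific binders (target-driven enrichment factor `e_spec`) and sticky
#' clones (nonspecific factor `e_bg` acting in both wells). Each round the
#' antigen well samples a finite elution bottleneck multinomially with
#' per-clone weight `freq * (1 + e_spec) * (1 + e_bg)`; the control well
#' uses `freq * (1 + e_bg)`. NGS count tables are multinomial reads from the
#' final-round wells (and from each positive round for trajectory
#' tracking).
#'
#' @param config A [simulation_config()] (fields under `panning`).
#' @param design A [library_design()] used to draw the clone sequences.
#' @return List with `positive_pools` (list of [pool_table()]s, one per
#'   round), `negative_pool` (final round), and `truth` (`data.table` of
#'   `sequence`, `role` in background/specific/sticky, `e_spec`, `e_bg`).
#' @export
simulate_panning <- function(config, design = default_design()) {
  pan <- config$panning
  if (pan$bottleneck <= 0) stop("elution bottleneck must be positive")
  with_seed(config$seed, {
    n <- pan$n_background + pan$n_specific + pan$n_sticky
    # draw distinct intact clones (short class for compactness of the pool)
    schemes <- c(design$cdr1, design$cdr2, cdr3_schemes(design, "short"))
    draw_aa <- function(m) {
      # residues drawn within each scheme's allowed set, so the rendered
      # sequences are valid by construction (render_template round-trip is
      # exercised in the test suite)
      cols <- lapply(schemes, function(s)
        sample(s$allowed, m, replace = TRUE))
      cdr_all <- do.call(paste0, cols)
      n1 <- length(design$cdr1); n2 <- length(design$cdr2)
      fr <- design$frameworks
      paste0(fr[["FR1"]], substr(cdr_all, 1, n1), fr[["FR2"]],
             substr(cdr_all, n1 + 1, n1 + n2), fr[["FR3"]],
             substr(cdr_all, n1 + n2 + 1, nchar(cdr_all)), fr[["FR4"]])
    }
    seqs <- character(0)
    while (length(seqs) < n) seqs <- unique(c(seqs, draw_aa(n)))
    seqs <- seqs[seq_len(n)]
    role <- c(rep("background", pan$n_background),
              rep("specific", pan$n_specific),
              rep("sticky", pan$n_sticky))
    e_spec <- ifelse(role == "specific", pan$e_spec, 0)
    e_bg <- ifelse(role == "sticky", pan$e_bg, 0)

    freq <- rep(1 / n, n)
    positive_pools <- vector("list", pan$rounds)
    neg_pool <- NULL
    for (r in seq_len(pan$rounds)) {
      w_pos <- freq * (1 + e_spec) * (1 + e_bg)
      counts_pos <- as.integer(rmultinom(1, pan$bottleneck,
                                         w_pos / sum(w_pos)))
      if (r == pan$rounds) {
        w_neg <- freq * (1 + e_bg)
        counts_neg <- as.integer(rmultinom(1, pan$bottleneck,
                                           w_neg / sum(w_neg)))
        ngs_neg <- as.integer(rmultinom(1, pan$ngs_depth,
                                        counts_neg / sum(counts_neg)))
        keep <- ngs_neg > 0L
        neg_pool <- pool_table(
          repertoire_table(seqs[keep], ngs_neg[keep],
                           sample_id = sprintf("round%d_negative", r)),
          round = r, pool = "negative")
      }
      freq <- counts_pos / sum(counts_pos)
      ngs_pos <- as.integer(rmultinom(1, pan$ngs_depth, freq))
      keep <- ngs_pos > 0L
      positive_pools[[r]] <- pool_table(
        repertoire_table(seqs[keep], ngs_pos[keep],
                         sample_id = sprintf("round%d_positive", r)),
        round = r, pool = "positive")
    }
    list(positive_pools = positive_pools, negative_pool = neg_pool,
         truth = data.table(sequence = seqs, role = role,
                            e_spec = e_spec, e_bg = e_bg))
  })
}

#' The paper-style 5-fold dose ladder
#'
#' @param top_dose Highest dose in molar, default 10 uM.
#' @param n Number of points, default 8 (10 uM down to 128 pM).
#' @return Numeric vector of doses, descending.
#' @export
dose_preset_5fold <- function(top_dose = 10e-6, n = 8L) {
  top_dose / 5^(seq_len(n) - 1L)
}

#' Simulate a dose-response plate
#'
#' Responses are the three-parameter logistic evaluated at the doses, each
#' multiplied by `1 + N(0, cv)` noise, replicate-resolved.
#'
#' @param bottom,top,ec50 True curve parameters (`ec50` in molar).
#' @param doses Molar doses, default [dose_preset_5fold()].
#' @param replicates Replicates per dose, default 3.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return `data.table` with columns `dose_M`, `response`, `replicate`;
#'   the true parameters are attached as attribute `truth`.
#' @export
simulate_plate <- function(bottom, top, ec50, doses = dose_preset_5fold(),
                           replicates = 3L, cv = 0.05, seed = 1L) {
  stopifnot(cv >= 0)
  with_seed(seed, {
    d <- rep(doses, each = replicates)
    mu <- logistic3_eval(d, bottom, top, ec50)
    resp <- mu * (1 + rnorm(length(d), 0, cv))
    out <- data.table(dose_M = d, response = resp,
                      replicate = rep(seq_len(replicates), length(doses)))
    attr(out, "truth") <- c(bottom = bottom, top = top, ec50 = ec50)
    out
  })
}

#' Simulate noisy 1:1 sensorgrams at several concentrations
#'
#' [simulate_sensorgram()] plus i.i.d. Gaussian noise, with the published
#' four-concentration three-fold-style dilution scheme (900/300/100/33 nM)
#' as the default.
#'
#' @param ka,kd,rmax True kinetic parameters.
#' @param concentrations Analyte concentrations in molar.
#' @param noise_sd Gaussian noise standard deviation, nm.
#' @param seed Integer seed.
#' @param t_assoc,t_dissoc,dt Trace timing, s (defaults 300/600/1).
#' @return List of sensorgram `data.table`s; true parameters attached as
#'   attribute `truth`.
#' @export
simulate_sensorgrams_noisy <- function(ka, kd, rmax,
                                       concentrations = c(900, 300, 100,
                                                          33) * 1e-9,
                                       noise_sd = 0.005, seed = 1L,
                                       t_assoc = 300, t_dissoc = 600,
                                       dt = 1) {
  stopifnot(noise_sd >= 0)
  with_seed(seed, {
    out <- lapply(concentrations, function(cc) {
      sg <- simulate_sensorgram(ka, kd, rmax, cc, t_assoc, t_dissoc, dt)
      sg$response_nm <- sg$response_nm + rnorm(nrow(sg), 0, noise_sd)
      sg
    })
    attr(out, "truth") <- c(ka = ka, kd = kd, rmax = rmax)
    out
  })
}
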