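test_that("merge_pairs reconstructs clean fragments", {
  # fragment ACGTTGCAAGGT sequenced as 8-mer mates overlapping by 4
  m <- merge_pairs("ACGTTGCA", revcomp("TGCAAGGT"), min_overlap = 4)
  expect_true(m$ok)
  expect_identical(m$merged, "ACGTTGCAAGGT")
  expect_identical(m$overlap, 4L)
  expect_identical(m$mismatches, 0L)
  # identical mates with full overlap collapse to one copy
  m2 <- merge_pairs("ACGTACGTACGT", revcomp("ACGTACGTACGT"),
                    min_overlap = 4)
  expect_true(m2$ok)
  expect_identical(m2$merged, "ACGTACGTACGT")
  expect_identical(m2$overlap, 12L)
})

test_that("merge_pairs resolves overlap mismatches toward quality", {
  s1 <- "AAAACCCC"; frag2 <- "CCGCTTTT"   # overlap CCCC vs CCGC: 1 mismatch
  m <- merge_pairs(s1, revcomp(frag2), min_overlap = 4,
                   max_mismatch_fraction = 0.3)
  expect_true(m$ok)
  expect_identical(m$mismatches, 1L)
  expect_identical(m$merged, "AAAACCCCTTTT")   # mate 1 wins without quals
  mq <- merge_pairs(s1, revcomp(frag2),
                    qual1 = "IIIIII!I", qual2 = "IIIIIIII",
                    min_overlap = 4, max_mismatch_fraction = 0.3)
  expect_identical(mq$merged, "AAAACCGCTTTT") # higher mate-2 quality wins
})

test_that("merge_pairs agrees with the brute-force oracle", {
  set.seed(7)
  fails <- 0L
  for (i in 1:100) {
    n1 <- sample(20:60, 1); n2 <- sample(20:60, 1)
    if (i %% 2 == 0) {           # true overlapping fragments
      frag <- random_dna(n1 + n2 - sample(8:15, 1))
      s1 <- substr(frag, 1, n1)
      s2 <- revcomp(substr(frag, nchar(frag) - n2 + 1, nchar(frag)))
    } else {                      # unrelated sequences
      s1 <- random_dna(n1); s2 <- random_dna(n2)
    }
    got <- merge_pairs(s1, s2, min_overlap = 8,
                       max_mismatch_fraction = 0.1)
    want <- oracle_merge(s1, s2, 8, 0.1)
    expect_identical(got$ok, want$ok)
    if (want$ok) {
      expect_identical(got$overlap, as.integer(want$overlap))
      expect_identical(got$merged, want$merged)
      expect_identical(got$mismatches, as.integer(want$mismatches))
    } else fails <- fails + 1L
  }
  expect_gt(fails, 30L)  # unrelated random pairs mostly fail to merge
})

test_that("trim_primers locates primers with bounded substitutions", {
  x <- "AAAACGCGTGCAGTCA"
  expect_identical(trim_primers(x, "AAAA", "GTCA", 0)$inner, "CGCGTGCA")
  # one substitution in p5 still trims at max_errors 1
  y <- "ATAACGCGTGCAGTCA"
  expect_false(trim_primers(y, "AAAA", "GTCA", 0)$found)
  tr <- trim_primers(y, "AAAA", "GTCA", 1)
  expect_true(tr$found)
  expect_identical(tr$inner, "CGCGTGCA")
  # missing p3
  expect_false(trim_primers("AAAACGCGTGCA", "AAAA", "GTCA", 1)$found)
  expect_error(trim_primers(x, "", "GTCA"), "non-empty")
})

test_that("translate_region translates frame 0 and flags frame indels", {
  tl <- translate_region(c("ATGTGGTAG", "ATGTGGTAGG", ""))
  expect_identical(tl$aa, c("MW*", NA, ""))
  expect_identical(tl$frame_ok, c(TRUE, FALSE, TRUE))
  # ambiguous bases render as X
  expect_identical(translate_region("ATGNNGTGG")$aa, "MXW")
})

test_that("classify_intact applies rules in order", {
  d <- toy_design()
  s <- render_template(d, list("K", "LL", "NPQRSTV"))
  cls <- classify_intact(s, d)
  expect_identical(cls$status, "intact")
  expect_identical(cls$cdr3_class, "short")
  # one internal residue replaced by a stop
  s_stop <- sub("NPQ", "N*Q", s)
  expect_identical(classify_intact(s_stop, d)$status, "premature_stop")
  # one residue deleted
  s_del <- sub("LL", "L", s)
  expect_identical(classify_intact(s_del, d)$status, "length_mismatch")
  # corrupted terminal motif
  s_term <- sub("SS$", "GG", s)
  expect_identical(classify_intact(s_term, d)$status, "anchor_mismatch")
})

test_that("renderer and intact filter round-trip on random valid tuples", {
  d <- default_design()
  set.seed(11)
  for (i in 1:40) {
    cl <- sample(names(d$cdr3_lengths), 1)
    tup <- random_cdr_tuple(d, cl)
    s <- render_template(d, tup)
    got <- classify_intact(s, d)
    expect_identical(got$status, "intact")
    expect_identical(got$cdr3_class, cl)
    # and CDR extraction inverts the renderer
    cdrs <- extract_cdrs(s, d)
    expect_identical(unname(unlist(cdrs[, 1:3])), unlist(tup))
  }
})

test_that("process_fastq round-trips a defect-free error-free run", {
  d <- default_design()
  cfg <- simulation_config(seed = 3, n_clones = 200, depth = 1500,
                           indel_rate = 0, stop_injection_rate = 0,
                           terminal_corruption_rate = 0,
                           substitution_rate = 0)
  clones <- simulate_library(cfg, d)
  intact_clones <- clones[clones$intact, ]
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  truth <- simulate_fastq(intact_clones, 1500, f1, f2,
                          substitution_rate = 0, seed = 4)
  res <- process_fastq(f1, f2, d)
  expect_equal(res$intact_fraction, 1.0)
  expect_identical(sum(res$counters), 1500L)
  expect_identical(unname(res$counters[["intact"]]), 1500L)
  # counts reproduce the sampled clone abundances exactly
  want <- table(intact_clones$aa[match(truth$clone_id,
                                       intact_clones$clone_id)])
  got <- setNames(res$repertoire$count, res$repertoire$sequence)
  expect_equal(got[names(want)], setNames(as.integer(want), names(want)))
})

test_that("intact-fraction denominator excludes merge and trim failures", {
  d <- default_design()
  cfg <- simulation_config(seed = 9, n_clones = 300, depth = 2000)
  clones <- simulate_library(cfg, d)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  truth <- simulate_fastq(clones, 2000, f1, f2, seed = 10,
                          substitution_rate = 0.001)
  res <- process_fastq(f1, f2, d)
  expect_identical(sum(res$counters), res$total_pairs)
  denom <- res$total_pairs - res$counters[["merge_failed"]] -
    res$counters[["trim_failed"]]
  expect_equal(res$intact_fraction,
               unname(res$counters[["intact"]] / denom))
  expect_equal(res$intact_fraction, mean(truth$intact), tolerance = 0.05)
})

test_that("process_fastq handles empty input", {
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), f1); writeLines(character(0), f2)
  res <- process_fastq(f1, f2, default_design())
  expect_identical(res$total_pairs, 0L)
  expect_true(all(res$counters == 0L))
  expect_true(is.na(res$intact_fraction))
  expect_identical(nrow(res$repertoire), 0L)
})
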