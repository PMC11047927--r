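test_that("extract_cdrs inverts the renderer and shares CDR1/2", {
  d <- toy_design()
  got <- extract_cdrs(render_template(d, list("K", "LL", "NPQRSTV")), d)
  expect_identical(got$cdr1, "K")
  expect_identical(got$cdr2, "LL")
  expect_identical(got$cdr3, "NPQRSTV")
  # two sequences differing only in CDR3 share CDR1/CDR2
  s2 <- render_template(d, list("K", "LL", "AAAAAAAAAAA"))
  both <- extract_cdrs(c(render_template(d, list("K", "LL", "NPQRSTV")),
                         s2), d)
  expect_identical(both$cdr1, c("K", "K"))
  expect_identical(both$cdr2, c("LL", "LL"))
  expect_identical(both$cdr3_class, c("short", "medium"))
  expect_identical(nchar(both$cdr3[2]), 11L)
  expect_error(extract_cdrs("MAKW", d), "anchor_mismatch")
})

test_that("position_composition weights reads and sums to one", {
  d <- toy_design()
  s1 <- render_template(d, list("K", "LL", "NPQRSTV"))
  s2 <- render_template(d, list("R", "LL", "NPQRSTV"))
  rep1 <- repertoire_table(c(s1, s2), c(3L, 1L))
  comp <- position_composition(rep1, d)
  cdr1pos <- comp[comp$cdr == "cdr1" & comp$position == 1, ]
  expect_equal(setNames(cdr1pos$fraction, cdr1pos$residue),
               c(K = 0.75, R = 0.25))
  # every (class, cdr, position) block sums to 1
  sums <- tapply(comp$fraction,
                 paste(comp$cdr3_class, comp$cdr, comp$position), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # single-sequence repertoire gives indicator distributions
  comp1 <- position_composition(repertoire_table(s1, 5L), d)
  expect_true(all(comp1$fraction == 1))
  # unique weighting ignores counts
  compu <- position_composition(rep1, d, weighting = "unique")
  cdr1u <- compu[compu$cdr == "cdr1" & compu$position == 1, ]
  expect_equal(setNames(cdr1u$fraction, cdr1u$residue),
               c(K = 0.5, R = 0.5))
  expect_error(position_composition(repertoire_table(character(0),
                                                     integer(0)), d),
               "empty")
})

test_that("composition of NNB-sampled repertoires converges to expectation", {
  d <- toy_design()
  cfg <- function(n, seed) simulation_config(seed = seed, n_clones = n,
                                             indel_rate = 0,
                                             stop_injection_rate = 0,
                                             terminal_corruption_rate = 0)
  make_rep <- function(n, seed) {
    cl <- simulate_library(cfg(n, seed), d)
    cl <- cl[cl$intact, ]
    tab <- table(cl$aa)
    repertoire_table(names(tab), as.integer(tab))
  }
  rep_small <- make_rep(2000, 21)
  rep_big <- make_rep(20000, 22)
  cmp_small <- compare_to_expected(position_composition(rep_small, d), d)
  cmp_big <- compare_to_expected(position_composition(rep_big, d), d)
  expect_lt(cmp_big$max_tv, cmp_small$max_tv)  # TV shrinks with depth
  # per-residue fractions near expectation within binomial error at depth
  f <- expected_aa_frequencies("NNB")
  fr <- f[setdiff(names(f), "*")] / (1 - f[["*"]])
  n_short <- sum(rep_big$count[nchar(rep_big$sequence) ==
                                 rendered_lengths(d)[["short"]]])
  comp <- position_composition(rep_big, d)
  pos1 <- comp[comp$cdr3_class == "short" & comp$cdr == "cdr1" &
                 comp$position == 1, ]
  for (r in pos1$residue) {
    se <- sqrt(fr[[r]] * (1 - fr[[r]]) / n_short)
    expect_lt(abs(pos1$fraction[pos1$residue == r] - fr[[r]]), 4 * se + 1e-3)
  }
})

test_that("compare_to_expected gives unit ratios on exact expectation", {
  d <- toy_design()
  f <- expected_aa_frequencies("NNB")
  fr <- f[setdiff(names(f), "*")] / (1 - f[["*"]])
  comp <- data.table::data.table(
    cdr3_class = "short", cdr = "cdr1", position = 1L,
    mode = "fully_randomized", residue = names(fr),
    fraction = as.numeric(fr))
  got <- compare_to_expected(comp, d)
  expect_equal(unname(got$ratios[names(fr)]),
               rep(1, length(fr)), tolerance = 1e-12)
  expect_equal(got$max_tv, 0, tolerance = 1e-12)
  # doubling one residue (others rescaled) doubles its ratio at that site
  f2 <- fr; f2[["W"]] <- 2 * fr[["W"]]
  f2 <- f2 / sum(f2)
  comp2 <- data.table::data.table(
    cdr3_class = "short", cdr = "cdr1", position = 1L,
    mode = "fully_randomized", residue = names(f2),
    fraction = as.numeric(f2))
  got2 <- compare_to_expected(comp2, d)
  expect_equal(unname(got2$ratios[["W"]] / got2$ratios[["A"]]), 2,
               tolerance = 1e-12)
})

test_that("compare_to_expected is invariant to uniform count scaling", {
  d <- toy_design()
  set.seed(31)
  seqs <- vapply(1:50, function(i)
    render_template(d, random_cdr_tuple(d, "short")), character(1))
  seqs <- unique(seqs)
  counts <- sample(1:5, length(seqs), replace = TRUE)
  a <- compare_to_expected(position_composition(
    repertoire_table(seqs, counts), d), d)
  b <- compare_to_expected(position_composition(
    repertoire_table(seqs, counts * 7L), d), d)
  expect_equal(a$ratios, b$ratios)
  expect_equal(a$max_tv, b$max_tv)
})

test_that("occurrence_spectrum buckets unique sequences", {
  rep1 <- repertoire_table(c("A", "B", "C", "D"), c(1L, 2L, 3L, 4L))
  expect_equal(occurrence_spectrum(rep1),
               c("1" = 0.25, "2" = 0.25, "3" = 0.25, ">3" = 0.25))
  rep2 <- repertoire_table(c("A", "B", "C"), c(1L, 1L, 1L))
  expect_equal(unname(occurrence_spectrum(rep2)[["1"]]), 1)
  expect_equal(sum(occurrence_spectrum(rep1)), 1)
})

test_that("sparse sampling of a huge pool is dominated by singletons", {
  # 1e4 reads over 1e6 equiprobable clones: Poisson rate 0.01, so virtually
  # every observed sequence appears <= 3 times
  set.seed(41)
  draws <- sample.int(1e6, 1e4, replace = TRUE)
  tab <- table(draws)
  rep1 <- repertoire_table(paste0("c", names(tab)), as.integer(tab))
  spec <- occurrence_spectrum(rep1)
  expect_gt(sum(spec[c("1", "2", "3")]), 0.99)
})

test_that("cdr3_class_proportions recovers configured weights", {
  d <- toy_design()
  s_short <- render_template(d, list("K", "LL", "NPQRSTV"))
  expect_equal(cdr3_class_proportions(repertoire_table(s_short, 4L), d),
               c(long = 0, medium = 0, short = 1))
  # 3:1:1 short/medium/long configured in the generator, recovered
  dd <- default_design()
  cfg <- simulation_config(seed = 51, n_clones = 30000,
                           class_weights = c(short = 3, medium = 1,
                                             long = 1))
  cl <- simulate_library(cfg, dd)
  cl <- cl[cl$intact, ]
  tab <- table(cl$aa)
  props <- cdr3_class_proportions(repertoire_table(names(tab),
                                                   as.integer(tab)), dd)
  # intact filtering skews toward short (fewer NNB stop sites), so compare
  # against the stop-free-adjusted expectation
  w <- c(short = 3, medium = 1, long = 1) / 5
  adj <- w * vapply(names(w), function(cl2)
    stop_free_probability(dd, cl2), numeric(1))
  adj <- adj / sum(adj)
  expect_equal(props[names(adj)], adj, tolerance = 0.02)
})
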