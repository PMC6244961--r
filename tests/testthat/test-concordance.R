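test_that("reactive-antigen counting respects locus filters and boundaries", {
  panel <- toy_panel(c("A*01:01", "B*07:02", "B*08:01", "Cw*01:02"))
  prof <- toy_profile(c(10, 600, 500, 499.9), panel)
  expect_equal(count_reactive(prof), 2)          # 500 counts, 499.9 does not
  expect_equal(count_reactive(prof, "B"), 2)
  expect_equal(count_reactive(prof, "A"), 0)
  expect_equal(count_reactive(toy_profile(c(0, 0, 0, 0), panel)), 0)
})

test_that("vendor tallies compare per-serum counts and drop silent sera", {
  alleles <- c("A*01:01", "A*02:01", "B*07:02")
  quartets <- list(
    toy_quartet(list(LS.IgHPolyFab = c(600, 700, 0),
                     LC.IgHPolyFab = c(600, 0, 0)), alleles, "S1"),
    toy_quartet(list(LS.IgHPolyFab = c(600, 0, 0),
                     LC.IgHPolyFab = c(600, 0, 0)), alleles, "S2"),
    toy_quartet(list(LS.IgHPolyFab = c(0, 0, 0),
                     LC.IgHPolyFab = c(0, 0, 0)), alleles, "S3"))
  t <- tally_beadsets(quartets, "A", "IgHPolyFab")
  expect_equal(c(t$n_gt, t$n_eq, t$n_lt), c(1, 1, 0))
  expect_equal(t$n_sera, 2)  # the all-negative serum is excluded
  expect_equal(t$n_gt + t$n_eq + t$n_lt, t$n_sera)
  empty <- tally_beadsets(list(), "A", "IgHPolyFab")
  expect_equal(c(empty$n_gt, empty$n_eq, empty$n_lt), c(0, 0, 0))
})

test_that("exact sign test matches brute-force enumeration", {
  # 5 pairs all one-sided: p = 1/32
  s <- sign_test_exact(2:6, 1:5)
  expect_equal(s$p_greater, 0.03125)
  # single pair
  expect_equal(sign_test_exact(2, 1)$p_greater, 0.5)
  # balanced signs: two-sided p = 1
  expect_equal(sign_test_exact(c(2, 2, 2, 0, 0, 0), c(1, 1, 1, 1, 1, 1))$p_two_sided, 1)

  set.seed(21)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    x <- sample(0:5, n, replace = TRUE)
    y <- sample(0:5, n, replace = TRUE)
    if (all(x == y)) next
    got <- sign_test_exact(x, y)
    oracle <- brute_force_sign_test(x, y)
    expect_equal(got$p_greater, oracle$p_greater)
    expect_equal(got$p_less, oracle$p_less)
    # cross-check against the binomial test on untied pairs
    d <- (x - y)[x != y]
    expect_equal(got$p_greater,
                 stats::binom.test(sum(d > 0), length(d),
                                   alternative = "greater")$p.value)
  }
})

test_that("exact signed-rank test equals 2^n brute force, ties included", {
  # n = 5, all differences one sign: one-sided minimum 1/32
  w <- wilcoxon_signed_rank_exact(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))
  expect_equal(w$p_greater, 0.03125)
  expect_true(w$exact)

  set.seed(22)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    x <- sample(0:8, n, replace = TRUE)
    y <- sample(0:8, n, replace = TRUE)
    if (all(x == y)) next
    got <- wilcoxon_signed_rank_exact(x, y)
    oracle <- brute_force_signed_rank(x, y)
    expect_equal(got$statistic, oracle$v)
    expect_equal(got$p_greater, oracle$p_greater)
    expect_equal(got$p_less, oracle$p_less)
    expect_equal(got$p_two_sided, oracle$p_two_sided)
    # mirrored pairs give the identical two-sided p
    mirrored <- wilcoxon_signed_rank_exact(y, x)
    expect_equal(mirrored$p_two_sided, got$p_two_sided)
  }
})

test_that("signed-rank test agrees with stats::wilcox.test when tie-free", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    got <- wilcoxon_signed_rank_exact(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE,
                              alternative = "greater")
    expect_equal(got$p_greater, ref$p.value)
    ref2 <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(got$p_two_sided, ref2$p.value)
  }
  expect_error(wilcoxon_signed_rank_exact(c(1, 2), c(1, 2)), "non-zero")
})

test_that("large-sample signed-rank p uses a continuity-corrected approximation", {
  set.seed(24)
  x <- rnorm(40, mean = 0.4)
  y <- rnorm(40)
  got <- wilcoxon_signed_rank_exact(x, y)
  expect_false(got$exact)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE,
                            alternative = "greater")
  expect_equal(got$p_greater, ref$p.value, tolerance = 1e-10)
})

test_that("serum grouping follows breadth and cross-platform strength rules", {
  alleles <- c("A*23:01", "A*24:02", "A*25:01", "A*26:01", "A*29:01",
               "A*30:01", "A*31:01", "A*32:01")
  # broad low-MFI LS-only reactivity: 1A
  q <- toy_quartet(list(
    LS.IgHPolyFab = c(600, 700, 800, 650, 720, 0, 0, 0),
    LS.FcMonoIgG = c(200, 250, 300, 210, 260, 0, 0, 0),
    LC.IgHPolyFab = rep(0, 8), LC.FcMonoIgG = rep(0, 8)), alleles)
  expect_equal(classify_serum_group(q), "1A")
  # strong on both vendors, broad: 1C
  q <- toy_quartet(list(
    LS.IgHPolyFab = c(rep(4000, 6), 0, 0), LS.FcMonoIgG = c(rep(5000, 6), 0, 0),
    LC.IgHPolyFab = c(rep(3500, 6), 0, 0), LC.FcMonoIgG = c(rep(5200, 6), 0, 0)),
    alleles)
  expect_equal(classify_serum_group(q), "1C")
  # strong on one vendor only, narrow: 2B
  q <- toy_quartet(list(
    LS.IgHPolyFab = c(2000, 1500, 0, 0, 0, 0, 0, 0), LS.FcMonoIgG = rep(0, 8),
    LC.IgHPolyFab = rep(0, 8), LC.FcMonoIgG = c(600, 0, 0, 0, 0, 0, 0, 0)),
    alleles)
  expect_equal(classify_serum_group(q), "2B")
  # all negative
  q <- toy_quartet(list(
    LS.IgHPolyFab = rep(0, 8), LS.FcMonoIgG = rep(0, 8),
    LC.IgHPolyFab = rep(0, 8), LC.FcMonoIgG = rep(0, 8)), alleles)
  expect_equal(classify_serum_group(q), "nonreactive")
  # exactly five positives sits in Group 1 (range endpoint included)
  q <- toy_quartet(list(
    LS.IgHPolyFab = c(rep(600, 5), 0, 0, 0), LS.FcMonoIgG = rep(0, 8),
    LC.IgHPolyFab = rep(0, 8), LC.FcMonoIgG = rep(0, 8)), alleles)
  expect_equal(classify_serum_group(q), "1A")
})

test_that("group label is invariant to bead order and all-negative padding", {
  alleles <- c("A*23:01", "A*24:02", "A*25:01", "B*07:02", "B*08:01", "B*13:02")
  mfis <- list(LS.IgHPolyFab = c(2000, 1500, 700, 0, 0, 0),
               LS.FcMonoIgG = c(900, 800, 100, 0, 0, 0),
               LC.IgHPolyFab = rep(0, 6), LC.FcMonoIgG = rep(0, 6))
  base <- classify_serum_group(toy_quartet(mfis, alleles))
  perm <- sample(seq_along(alleles))
  shuffled <- classify_serum_group(
    toy_quartet(lapply(mfis, `[`, perm), alleles[perm]))
  expect_equal(shuffled, base)
  padded <- classify_serum_group(
    toy_quartet(lapply(mfis, c, 0), c(alleles, "Cw*01:02")))
  expect_equal(padded, base)
})

test_that("cohort summary assembles counts, tallies, tests and groups", {
  alleles <- c("A*23:01", "A*24:02", "A*25:01", "A*26:01", "A*29:01", "A*30:01")
  quartets <- lapply(1:6, function(i) {
    toy_quartet(list(
      LS.IgHPolyFab = c(rep(700, 5), 0) + i * 10, LS.FcMonoIgG = rep(100, 6),
      LC.IgHPolyFab = c(600, rep(0, 5)), LC.FcMonoIgG = rep(0, 6)),
      alleles, serum_id = paste0("S", i))
  })
  s <- summarize_concordance(quartets)
  expect_named(s, c("counts", "tallies", "medians", "tests", "groups"))
  expect_equal(nrow(s$groups), 6)
  tal <- s$tallies[s$tallies$secondary == "IgHPolyFab", ]
  expect_equal(sum(tal$n_gt), 6)  # LS > LC for every serum at locus A
  # every serum reacts more broadly on LS: one-sided Wilcoxon at its minimum
  p <- s$tests$p_wilcoxon_greater[s$tests$secondary == "IgHPolyFab"]
  expect_equal(p, 1 / 2^6)
  expect_equal(glance(s)$n_reactive_sera, 6)
})
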