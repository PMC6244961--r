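demo_hap_table <- function() {
  frequency_table(system.file("extdata", "freq_haplotypes_synthetic.csv",
                              package = "hlasab"))
}

demo_locus_table <- function() {
  frequency_table(system.file("extdata", "freq_per_locus_synthetic.csv",
                              package = "hlasab"))
}

test_that("positive beads expand to allele-level plus base-group labels", {
  panel <- toy_panel(c("A*02:03", "B*57:01", "Cw*07:02"))
  prof <- toy_profile(c(600, 700, 100), panel)
  ua <- expand_unacceptable(prof)
  expect_setequal(ua$antigens, c("A0203", "A2", "B5701", "B57"))
  expect_equal(nrow(ua$excluded), 0)
  # every allele-level entry's base group is present
  expect_true(all(c("A2", "B57") %in% ua$antigens))
})

test_that("DRB3/4/5 positives list DR52/DR53/DR51 and DQ pairs split by chain", {
  drb_panel <- hla_panel(tibble::tibble(
    bead_id = c("1", "2", "NC"),
    bead = c("DRB4*01:03", "DQB1*03:01\\DQA1*05:01", NA),
    control = c("none", "none", "negative_control")), vendor = "LS")
  prof <- toy_profile(c(600, 800), drb_panel)
  ua <- expand_unacceptable(prof)
  expect_true("DR53" %in% ua$antigens)
  # DQB1 chain is listable, DQA1 chain is excluded (recorded, not dropped)
  expect_true(all(c("DQ0301", "DQ7") %in% ua$antigens))
  expect_equal(ua$excluded$allele, "DQA1*05:01")
})

test_that("DP-only reactivity yields an empty set with excluded records", {
  dp_panel <- hla_panel(tibble::tibble(
    bead_id = c("1", "NC"), bead = c("DPB1*23:01\\DPA1*02:01", NA),
    control = c("none", "negative_control")), vendor = "LS")
  ua <- expand_unacceptable(toy_profile(900, dp_panel))
  expect_equal(length(ua$antigens), 0)
  expect_setequal(ua$excluded$allele, c("DPB1*23:01", "DPA1*02:01"))
})

test_that("sub-cutoff beads are not listed and the boundary is at-or-above", {
  panel <- toy_panel(c("A*02:03", "B*57:01"))
  ua <- expand_unacceptable(toy_profile(c(500, 499.9), panel))
  expect_setequal(ua$antigens, c("A0203", "A2"))
  # an unmapped allele at a listable locus is a hard error, not a drop
  odd <- toy_panel("A*99:99")
  expect_error(expand_unacceptable(toy_profile(600, odd)), "mapping")
})

test_that("frequency-table validation enforces weights and sums", {
  bad <- tibble::tibble(mode = "haplotype", population = "p1", weight = 0.5,
                        haplotype = c("A1", "A2"), frequency = c(0.5, 0.5))
  expect_error(frequency_table(bad), "weights")
  bad2 <- tibble::tibble(mode = "haplotype", population = "p1", weight = 1,
                         haplotype = c("A1", "A2"), frequency = c(0.6, 0.5))
  expect_error(frequency_table(bad2), "sum to 1")
  expect_s3_class(demo_hap_table(), "frequency_table")
  expect_s3_class(demo_locus_table(), "frequency_table")
})

test_that("empty unacceptable set gives cPRA 0 and full-coverage gives 1", {
  ft <- demo_hap_table()
  expect_equal(cpra_haplotype(character(), ft)$cpra, 0)
  lt <- demo_locus_table()
  expect_equal(cpra_per_locus(character(), lt)$cpra, 0)
  # all antigens of one locus unacceptable: every donor carries two hits
  all_a <- unique(lt$antigen[lt$locus == "A"])
  expect_equal(cpra_per_locus(all_a, lt)$cpra, 1)
})

test_that("single-locus cPRA equals the closed form 1 - (1 - f)^2", {
  f <- 0.3
  ft <- frequency_table(tibble::tibble(
    mode = "haplotype", population = "p1", weight = 1,
    haplotype = c("A1", "A2", "A3"), frequency = c(f, 0.5, 0.2)))
  expect_equal(cpra_haplotype("A1", ft)$cpra, 1 - (1 - f)^2)
  lt <- frequency_table(tibble::tibble(
    mode = "per_locus_antigen", population = "p1", weight = 1, locus = "A",
    antigen = c("A1", "A2", "A3"), frequency = c(f, 0.5, 0.2)))
  expect_equal(cpra_per_locus("A1", lt)$cpra, 1 - (1 - f)^2)
  # the two engines agree exactly on a single-locus table
  expect_equal(cpra_haplotype(c("A1", "A2"), ft)$cpra,
               cpra_per_locus(c("A1", "A2"), lt)$cpra)
})

test_that("Monte Carlo oracle is deterministic under a fixed seed", {
  ft <- demo_hap_table()
  ua <- c("A2", "B44")
  a <- simulate_donors_oracle(ua, ft, n_draws = 2000, seed = 5)
  b <- simulate_donors_oracle(ua, ft, n_draws = 2000, seed = 5)
  expect_identical(a$cpra, b$cpra)
  expect_equal(simulate_donors_oracle(character(), ft, 100, 1)$cpra, 0)
})

test_that("oracle recovers the closed form within 3 standard errors", {
  f <- 0.3
  ft <- frequency_table(tibble::tibble(
    mode = "haplotype", population = "p1", weight = 1,
    haplotype = c("A1", "A2"), frequency = c(f, 1 - f)))
  res <- simulate_donors_oracle("A1", ft, n_draws = 2e4, seed = 9)
  expect_lt(abs(res$cpra - 0.51), 3 * res$se)
})

random_hap_table <- function() {
  loci <- list(A = c("A1", "A2", "A3"), B = c("B7", "B8", "B44"),
               C = c("Cw4", "Cw7"))
  haps <- expand.grid(loci, stringsAsFactors = FALSE)
  hap_labels <- apply(as.matrix(haps), 1, paste, collapse = "~")
  w <- runif(2)
  w <- w / sum(w)
  dplyr::bind_rows(lapply(1:2, function(p) {
    f <- runif(length(hap_labels))
    tibble::tibble(mode = "haplotype", population = paste0("p", p),
                   weight = w[p], haplotype = hap_labels,
                   frequency = f / sum(f))
  }))
}

test_that("haplotype engine matches the donor oracle on random tables", {
  set.seed(31)
  for (i in 1:10) {
    ft <- frequency_table(random_hap_table())
    ua <- sample(c("A1", "A2", "B7", "B8", "Cw4"), sample(1:3, 1))
    engine <- cpra_haplotype(ua, ft)$cpra
    oracle <- simulate_donors_oracle(ua, ft, n_draws = 2e4, seed = i)
    se <- max(oracle$se, 1e-6)
    expect_lt(abs(engine - oracle$cpra), 3 * se)
  }
})

test_that("adding an antigen never decreases cPRA (both engines)", {
  set.seed(32)
  ft <- frequency_table(random_hap_table())
  lt <- demo_locus_table()
  pool_h <- c("A1", "A2", "A3", "B7", "B8", "B44", "Cw4", "Cw7")
  pool_l <- unique(lt$antigen)
  for (i in 1:15) {
    ua <- sample(pool_h, sample(0:4, 1))
    extra <- sample(setdiff(pool_h, ua), 1)
    expect_gte(cpra_haplotype(c(ua, extra), ft)$cpra,
               cpra_haplotype(ua, ft)$cpra)
    ua_l <- sample(pool_l, sample(0:4, 1))
    extra_l <- sample(setdiff(pool_l, ua_l), 1)
    expect_gte(cpra_per_locus(c(ua_l, extra_l), lt)$cpra,
               cpra_per_locus(ua_l, lt)$cpra)
  }
})

test_that("identical populations collapse to the single-population cPRA", {
  one <- tibble::tibble(mode = "haplotype", population = "p1", weight = 1,
                        haplotype = c("A1~B7", "A2~B8"), frequency = c(0.4, 0.6))
  two <- dplyr::bind_rows(
    dplyr::mutate(one, population = "p1", weight = 0.3),
    dplyr::mutate(one, population = "p2", weight = 0.7))
  ua <- "A1"
  expect_equal(cpra_haplotype(ua, frequency_table(two))$cpra,
               cpra_haplotype(ua, frequency_table(one))$cpra)
})

test_that("cpra results carry tidy() and glance() methods", {
  res <- cpra_haplotype(c("A2", "B44"), demo_hap_table())
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)  # one row per population
  gl <- glance(res)
  expect_equal(gl$cpra_pct, 100 * res$cpra)
  # weighted combination reproducible from per-population values
  expect_equal(res$cpra, sum(td$weight * td$cpra))
})
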