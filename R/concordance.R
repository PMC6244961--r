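#' Assemble the four-condition profile set for one serum
#'
#' One serum is measured under four conditions: two vendor panels (LS, LC)
#' crossed with two secondary detection antibodies (FcMonoIgG, IgHPolyFab).
#' This restricts all four profiles to the antigens common to the two
#' panels, so that intraindividual comparisons never involve vendor-unique
#' beads.
#'
#' @param profiles A list of four `serum_profile` objects (one per
#'   vendor x secondary condition) for the same serum, or a single data
#'   frame already stacking them.
#' @param panel_ls,panel_lc The two [hla_panel()] objects.
#' @return A tibble of class `condition_quartet` with columns `serum_id`,
#'   `vendor`, `secondary`, `bead`, `locus`, `hla_class`, `normalized_mfi`,
#'   `positive`, restricted to common antigens; positivity cutoff carried
#'   as an attribute.
#' @export
condition_quartet <- function(profiles, panel_ls, panel_lc) {
  if (is.data.frame(profiles)) {
    cutoff <- attr(profiles, "cutoff") %||% 500
    stacked <- tibble::as_tibble(profiles)
  } else {
    cutoffs <- unique(vapply(profiles, function(p) attr(p, "cutoff") %||% 500,
                             numeric(1)))
    dilutions <- unique(vapply(profiles, function(p) attr(p, "dilution") %||% 0.1,
                               numeric(1)))
    if (length(cutoffs) != 1 || length(dilutions) != 1) {
      abort("all four profiles must share one cutoff and one dilution")
    }
    cutoff <- cutoffs
    stacked <- dplyr::bind_rows(lapply(profiles, tibble::as_tibble))
  }
  if (length(unique(stacked$serum_id)) != 1) {
    abort("a condition quartet holds exactly one serum")
  }
  common <- common_alleles(panel_ls, panel_lc)
  out <- stacked[stacked$bead %in% common$bead, ]
  conds <- unique(out[c("vendor", "secondary")])
  structure(out, cutoff = cutoff,
            complete = nrow(conds) == 4,
            class = c("condition_quartet", class(out)))
}

#' Count reactive antigens in a profile
#'
#' @param profile A `serum_profile` or `condition_quartet` slice (any data
#'   frame with `locus` and `positive` columns).
#' @param locus Optional locus filter; with `NULL`, counts over all loci.
#' @return Integer count of positive antigens.
#' @export
count_reactive <- function(profile, locus = NULL) {
  x <- profile
  if (!is.null(locus)) {
    x <- x[x$locus %in% locus, ]
  }
  sum(x$positive, na.rm = TRUE)
}

#' Tally vendor-panel wins across a cohort
#'
#' For each serum (quartet), compares the number of reactive common antigens
#' at a locus between the LS and LC panels under one secondary antibody, and
#' tallies sera into LS > LC, LS = LC and LS < LC. Sera with no reactive
#' antigen in either condition are excluded from the tally.
#'
#' @param quartets A list of [condition_quartet()] objects.
#' @param locus Locus to compare (e.g. `"A"`).
#' @param secondary `"FcMonoIgG"` or `"IgHPolyFab"`.
#' @return A one-row tibble with `locus`, `secondary`, `n_gt`, `n_eq`,
#'   `n_lt`, `n_sera` (sera entering the tally).
#' @export
tally_beadsets <- function(quartets, locus, secondary) {
  counts <- purrr::map(quartets, function(q) {
    sub <- q[q$secondary == secondary, ]
    c(ls = count_reactive(sub[sub$vendor == "LS", ], locus),
      lc = count_reactive(sub[sub$vendor == "LC", ], locus))
  })
  counts <- purrr::keep(counts, ~ sum(.x) > 0)
  ls <- purrr::map_dbl(counts, "ls")
  lc <- purrr::map_dbl(counts, "lc")
  tibble::tibble(locus = locus, secondary = secondary,
                 n_gt = sum(ls > lc), n_eq = sum(ls == lc),
                 n_lt = sum(ls < lc), n_sera = length(counts))
}

new_sab_htest <- function(method, statistic, n_used, p_greater, p_less,
                          p_two_sided, exact) {
  structure(list(method = method, statistic = statistic, n_used = n_used,
                 p_greater = p_greater, p_less = p_less,
                 p_two_sided = p_two_sided, exact = exact),
            class = "sab_htest")
}

#' @export
print.sab_htest <- function(x, ...) {
  cat(sprintf("%s (%s): n = %d, statistic = %g\n", x$method,
              if (x$exact) "exact" else "normal approximation",
              x$n_used, x$statistic))
  cat(sprintf("  p (x > y) = %.5g, p (x < y) = %.5g, two-sided = %.5g\n",
              x$p_greater, x$p_less, x$p_two_sided))
  invisible(x)
}

#' @export
tidy.sab_htest <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic, n = x$n_used,
                 p.greater = x$p_greater, p.less = x$p_less,
                 p.value = x$p_two_sided, exact = x$exact)
}

#' Exact paired sign test
#'
#' Drops tied pairs and refers the number of positive differences to the
#' exact Binomial(n, 1/2) null. The two-sided p-value doubles the smaller
#' tail (capped at 1).
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return An object of class `sab_htest` with one-sided (`p_greater`,
#'   `p_less`) and two-sided p-values; `statistic` is the number of pairs
#'   with `x > y` among the `n_used` untied pairs.
#' @examples
#' sign_test_exact(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))$p_greater  # 0.03125
#' @export
sign_test_exact <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) {
    abort("sign test needs at least one non-tied pair")
  }
  s <- sum(d > 0)
  p_greater <- pbinom(s - 1, n, 0.5, lower.tail = FALSE)
  p_less <- pbinom(s, n, 0.5)
  new_sab_htest("paired sign test", statistic = s, n_used = n,
                p_greater = p_greater, p_less = p_less,
                p_two_sided = min(1, 2 * min(p_greater, p_less)),
                exact = TRUE)
}

# Null distribution of the positive-rank sum over all 2^n sign assignments
# of the ranked |differences|.  Mid-ranks are multiples of 1/2, so doubling
# them gives an integer convolution; returns counts over 0..sum(2*ranks).
signed_rank_null_counts <- function(ranks2) {
  counts <- rep(0, sum(ranks2) + 1)
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon signed-rank test for paired data
#'
#' Paired signed-rank test with the conventional handling of ties: zero
#' differences are dropped and tied absolute differences receive mid-ranks.
#' For `n <= exact_limit` untied pairs the p-values are exact, computed from
#' the full null distribution of the positive-rank sum over all `2^n` sign
#' assignments (so they remain exact under mid-ranks, where the classical
#' tabulated distribution does not apply). Larger samples use the normal
#' approximation with tie correction and continuity correction. The null
#' distribution is symmetric, so the two-sided p-value is the probability of
#' a rank sum at least as far from its mean as the one observed.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_limit Largest n for which the exact distribution is
#'   enumerated (default 25).
#' @return An object of class `sab_htest`; `statistic` is the positive-rank
#'   sum `V`.
#' @examples
#' wilcoxon_signed_rank_exact(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))$p_greater
#' @export
wilcoxon_signed_rank_exact <- function(x, y, exact_limit = 25) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) {
    abort("signed-rank test needs at least one non-zero difference")
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    counts <- signed_rank_null_counts(ranks2)
    total <- 2^n
    v2 <- as.integer(round(2 * v))
    s2 <- sum(ranks2)
    p_greater <- sum(counts[(v2 + 1):(s2 + 1)]) / total
    p_less <- sum(counts[1:(v2 + 1)]) / total
    # symmetric null: two-sided mass at least as extreme as |v - mean|
    mirror <- s2 - v2
    lo <- min(v2, mirror)
    hi <- max(v2, mirror)
    p_two <- if (lo == hi) {
      1
    } else {
      (sum(counts[1:(lo + 1)]) + sum(counts[(hi + 1):(s2 + 1)])) / total
    }
    new_sab_htest("Wilcoxon signed-rank test", statistic = v, n_used = n,
                  p_greater = p_greater, p_less = p_less,
                  p_two_sided = min(1, p_two), exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    z_g <- (v - mu - 0.5) / sigma
    z_l <- (v - mu + 0.5) / sigma
    p_greater <- pnorm(z_g, lower.tail = FALSE)
    p_less <- pnorm(z_l)
    new_sab_htest("Wilcoxon signed-rank test", statistic = v, n_used = n,
                  p_greater = p_greater, p_less = p_less,
                  p_two_sided = min(1, 2 * min(p_greater, p_less)),
                  exact = FALSE)
  }
}

#' Classify a serum's cross-platform reactivity pattern
#'
#' Operationalizes the reactivity grouping used to describe sera measured on
#' both vendor panels with both secondary antibodies. The group number
#' encodes breadth: Group 1 sera react with at least `group1_min` common
#' antigens (default 5) in the condition with the maximum count, Group 2
#' with fewer (but at least one). The letter encodes cross-platform
#' consistency of strong reactions, via `H(v)`, the number of common
#' antigens on vendor `v` whose normalized MFI (maximum over the two
#' secondaries) is at or above `high_cutoff`:
#' \itemize{
#'   \item `C`: `H(LS) >= 2` and `H(LC) >= 2` (strong on both panels);
#'   \item `B`: exactly one vendor has `H >= 2`;
#'   \item `A`: positives exist but neither vendor reaches two strong beads.
#' }
#'
#' @param quartet A [condition_quartet()].
#' @param high_cutoff MFI threshold for a "strong" reaction (default 1000).
#' @param group1_min Minimum positive-antigen count for Group 1 (default 5).
#' @return A single string: `"nonreactive"`, `"1A"`, `"1B"`, `"1C"`,
#'   `"2A"`, `"2B"` or `"2C"`.
#' @export
classify_serum_group <- function(quartet, high_cutoff = 1000, group1_min = 5) {
  conds <- expand.grid(vendor = c("LS", "LC"),
                       secondary = unique(quartet$secondary),
                       stringsAsFactors = FALSE)
  n_pos <- purrr::map2_int(conds$vendor, conds$secondary, function(v, s) {
    count_reactive(quartet[quartet$vendor == v & quartet$secondary == s, ])
  })
  if (all(n_pos == 0)) {
    return("nonreactive")
  }
  h <- vapply(c(LS = "LS", LC = "LC"), function(v) {
    sub <- quartet[quartet$vendor == v, ]
    if (nrow(sub) == 0) {
      return(0L)
    }
    best <- dplyr::summarise(dplyr::group_by(sub, .data$bead),
                             mfi = max(.data$normalized_mfi), .groups = "drop")
    sum(best$mfi >= high_cutoff)
  }, integer(1))
  letter <- if (all(h >= 2)) "C" else if (any(h >= 2)) "B" else "A"
  number <- if (max(n_pos) >= group1_min) "1" else "2"
  paste0(number, letter)
}

#' Cohort concordance summary
#'
#' Per-locus reactive counts, vendor-win tallies, median positive MFIs and
#' paired-test p-values for a cohort of sera measured under all four
#' conditions.
#'
#' @param quartets A list of [condition_quartet()] objects.
#' @param loci Loci to summarise (default: loci present in the data).
#' @return A list of class `concordance_summary` with tibbles `counts`
#'   (per serum x condition x locus), `tallies` (per locus x secondary),
#'   `medians` (per serum x condition), `tests` (per locus x secondary:
#'   exact Wilcoxon and sign-test p-values for LS vs LC reactive counts) and
#'   `groups` (per-serum reactivity group).
#' @export
summarize_concordance <- function(quartets, loci = NULL) {
  stacked <- dplyr::bind_rows(lapply(quartets, tibble::as_tibble))
  loci <- loci %||% sort(unique(stacked$locus))
  counts <- dplyr::summarise(
    dplyr::group_by(stacked[stacked$locus %in% loci, ],
                    .data$serum_id, .data$vendor, .data$secondary, .data$locus),
    n_reactive = sum(.data$positive), .groups = "drop")
  tallies <- dplyr::bind_rows(lapply(loci, function(l) {
    dplyr::bind_rows(lapply(unique(stacked$secondary), function(s) {
      tally_beadsets(quartets, l, s)
    }))
  }))
  medians <- dplyr::summarise(
    dplyr::group_by(stacked, .data$serum_id, .data$vendor, .data$secondary),
    median_positive_mfi = median_positive_mfi(dplyr::pick(dplyr::everything())),
    .groups = "drop")
  tests <- dplyr::bind_rows(lapply(loci, function(l) {
    dplyr::bind_rows(lapply(unique(stacked$secondary), function(s) {
      per_serum <- lapply(quartets, function(q) {
        sub <- q[q$secondary == s & q$locus == l, ]
        c(ls = count_reactive(sub[sub$vendor == "LS", ]),
          lc = count_reactive(sub[sub$vendor == "LC", ]))
      })
      per_serum <- purrr::keep(per_serum, ~ sum(.x) > 0)
      ls <- purrr::map_dbl(per_serum, "ls")
      lc <- purrr::map_dbl(per_serum, "lc")
      if (length(ls) == 0 || all(ls == lc)) {
        return(tibble::tibble(locus = l, secondary = s, n_sera = length(ls),
                              p_wilcoxon_greater = NA_real_,
                              p_wilcoxon_two_sided = NA_real_,
                              p_sign_greater = NA_real_))
      }
      w <- wilcoxon_signed_rank_exact(ls, lc)
      sg <- sign_test_exact(ls, lc)
      tibble::tibble(locus = l, secondary = s, n_sera = length(ls),
                     p_wilcoxon_greater = w$p_greater,
                     p_wilcoxon_two_sided = w$p_two_sided,
                     p_sign_greater = sg$p_greater)
    }))
  }))
  groups <- tibble::tibble(
    serum_id = vapply(quartets, function(q) q$serum_id[1], character(1)),
    group = vapply(quartets, classify_serum_group, character(1)))
  structure(list(counts = counts, tallies = tallies, medians = medians,
                 tests = tests, groups = groups),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("<concordance_summary>\n")
  cat("Reactivity groups:\n")
  print(x$groups)
  cat("Vendor tallies (LS vs LC reactive counts):\n")
  print(x$tallies)
  invisible(x)
}

#' @export
glance.concordance_summary <- function(x, ...) {
  tibble::tibble(n_sera = nrow(x$groups),
                 n_reactive_sera = sum(x$groups$group != "nonreactive"),
                 n_loci = length(unique(x$tallies$locus)))
}

#' @export
tidy.concordance_summary <- function(x, ...) {
  x$tests
}
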