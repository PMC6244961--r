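#' UNOS-style label for an allele
#'
#' Compact allele-level labels of the form used on unacceptable-antigen
#' lists: `A*02:03` becomes `A0203`, `Cw*07:02` becomes `Cw0702`,
#' `DRB1*04:01` becomes `DR0401`, `DQB1*03:01` becomes `DQ0301`.
#'
#' @param allele Character vector of allele labels.
#' @return Character vector of compact labels.
#' @export
unos_label <- function(allele) {
  parsed <- parse_allele(allele)
  prefix <- c(A = "A", B = "B", C = "Cw", DRB1 = "DR", DQB1 = "DQ")[parsed$locus]
  ifelse(is.na(prefix), NA_character_,
         paste0(prefix, parsed$field1, parsed$field2))
}

#' Expand positive beads into an unacceptable-antigen set
#'
#' Applies the listing rules used when transcribing single-antigen-bead
#' positives into a cPRA calculator: every bead with normalized MFI at or
#' above `cutoff` contributes both its allele-level label and its serologic
#' base-antigen group (e.g. a positive A*02:03 bead lists both `A0203` and
#' `A2`); a positive DRB3/DRB4/DRB5 bead lists DR52/DR53/DR51. Reactivities
#' carried only by DQA1-, DPA1- or DPB1-chain alleles cannot be listed and
#' are recorded under `excluded` rather than silently dropped. For paired
#' DQ beads, the DQB1 chain is listed and the DQA1 chain excluded.
#'
#' @param profile A `serum_profile`.
#' @param map An [antigen_map()]; an unmapped allele at a listable locus is
#'   an error (the map must cover the panel).
#' @param cutoff Listing cutoff in normalized MFI units (default 500).
#' @return An object of class `unacceptable_set`: a list with `antigens`
#'   (sorted character vector of labels), `excluded` (tibble of positive
#'   alleles dropped by rule) and `cutoff`.
#' @export
expand_unacceptable <- function(profile, map = antigen_map(), cutoff = 500) {
  stopifnot(is.data.frame(profile))
  pos <- profile[call_positive(profile$normalized_mfi, cutoff), ]
  alleles <- stats::na.omit(c(parse_bead(pos$bead)$allele_1,
                              parse_bead(pos$bead)$allele_2))
  antigens <- character()
  excluded <- tibble::tibble(allele = character(), reason = character())
  if (length(alleles) > 0) {
    parsed <- parse_allele(alleles)
    for (i in seq_len(nrow(parsed))) {
      loc <- parsed$locus[i]
      al <- parsed$allele[i]
      if (loc %in% ALPHA_LOCI || loc == "DPB1") {
        excluded <- dplyr::bind_rows(excluded, tibble::tibble(
          allele = al, reason = "locus not considered by cPRA listing"))
      } else if (loc %in% names(DRB345_MAP)) {
        antigens <- c(antigens, DRB345_MAP[[loc]])
      } else {
        base <- base_antigen(al, map)
        if (is.na(base)) {
          abort(paste0("allele at a listable locus has no base-antigen ",
                       "mapping: ", al))
        }
        antigens <- c(antigens, unos_label(al), base)
      }
    }
  }
  structure(list(antigens = sort(unique(antigens)),
                 excluded = excluded, cutoff = cutoff),
            class = "unacceptable_set")
}

#' @export
print.unacceptable_set <- function(x, ...) {
  cat(sprintf("<unacceptable_set> %d antigen labels (cutoff %g MFI)\n",
              length(x$antigens), x$cutoff))
  if (length(x$antigens)) cat(" ", paste(x$antigens, collapse = ", "), "\n")
  if (nrow(x$excluded)) {
    cat(sprintf("  %d positive allele(s) excluded by rule\n", nrow(x$excluded)))
  }
  invisible(x)
}

#' Read or validate a population frequency table
#'
#' Frequency tables come in two modes. `haplotype` mode gives per-population
#' haplotype frequencies, each haplotype written as base antigens joined by
#' `~` (e.g. `"A1~B8~Cw7"`). `per_locus_antigen` mode gives per-population,
#' per-locus antigen frequencies and assumes linkage equilibrium across
#' loci. Population weights must sum to 1, and frequencies must sum to 1
#' within each population (per locus in per-locus mode), to within 1e-9.
#'
#' @param x A path to a CSV file or a data frame with columns `mode`,
#'   `population`, `weight`, then `haplotype`,`frequency` or
#'   `locus`,`antigen`,`frequency`.
#' @return A validated tibble of class `frequency_table` with a `mode`
#'   attribute.
#' @export
frequency_table <- function(x) {
  df <- if (is.character(x)) {
    readr::read_csv(x, col_types = readr::cols(
      mode = "c", population = "c", weight = "d", frequency = "d",
      .default = "c"))
  } else {
    tibble::as_tibble(x)
  }
  mode <- unique(df$mode)
  if (length(mode) != 1 || !mode %in% c("haplotype", "per_locus_antigen")) {
    abort("frequency table must have a single mode: haplotype or per_locus_antigen")
  }
  need <- if (mode == "haplotype") c("population", "weight", "haplotype", "frequency")
          else c("population", "weight", "locus", "antigen", "frequency")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("frequency table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  w <- unique(df[c("population", "weight")])
  if (anyDuplicated(w$population)) {
    abort("a population must have a single weight")
  }
  if (abs(sum(w$weight) - 1) > 1e-9) {
    abort("population weights must sum to 1")
  }
  grp <- if (mode == "haplotype") "population" else c("population", "locus")
  sums <- dplyr::summarise(dplyr::group_by(df, dplyr::across(dplyr::all_of(grp))),
                           total = sum(.data$frequency), .groups = "drop")
  if (any(abs(sums$total - 1) > 1e-9)) {
    abort("frequencies must sum to 1 within each population (per locus)")
  }
  if (any(df$frequency < 0)) {
    abort("frequencies must be non-negative")
  }
  structure(df, mode = mode, class = c("frequency_table", class(df)))
}

split_haplotype <- function(h) strsplit(h, "~", fixed = TRUE)

new_cpra_result <- function(cpra, per_population, method,
                            n_draws = NA_integer_, seed = NA_integer_,
                            se = NA_real_) {
  structure(list(cpra = cpra, per_population = per_population,
                 method = method, n_draws = n_draws, seed = seed, se = se),
            class = "cpra_result")
}

#' @export
print.cpra_result <- function(x, ...) {
  cat(sprintf("<cpra_result> cPRA = %.4f (%.1f%%), method = %s\n",
              x$cpra, 100 * x$cpra, x$method))
  if (!is.na(x$n_draws)) {
    cat(sprintf("  %d donor draws (seed %d), SE = %.4g\n",
                x$n_draws, x$seed, x$se))
  }
  invisible(x)
}

#' @export
tidy.cpra_result <- function(x, ...) {
  x$per_population
}

#' @export
glance.cpra_result <- function(x, ...) {
  tibble::tibble(cpra = x$cpra, cpra_pct = 100 * x$cpra, method = x$method,
                 n_draws = x$n_draws, se = x$se)
}

ua_antigens <- function(ua) {
  if (inherits(ua, "unacceptable_set")) ua$antigens else as.character(ua)
}

#' cPRA from haplotype frequencies
#'
#' The calculated panel-reactive antibody is the probability that a random
#' donor carries at least one unacceptable antigen. With haplotype
#' frequencies and Hardy-Weinberg pairing, a donor is acceptable when both
#' haplotypes avoid every unacceptable antigen, so per population
#' P(acceptable) equals the squared total frequency of acceptable
#' haplotypes; the reported cPRA is 1 minus the population-weighted mean of
#' P(acceptable). Haplotypes are specified as base antigens, so allele-level
#' entries in the unacceptable set match only through their base group
#' (which [expand_unacceptable()] always includes when mapped).
#'
#' @param ua An [expand_unacceptable()] result or character vector of
#'   antigen labels.
#' @param ft A `haplotype`-mode [frequency_table()].
#' @return A `cpra_result` with the weighted cPRA as a fraction in `[0, 1]`
#'   and a per-population tibble.
#' @export
cpra_haplotype <- function(ua, ft) {
  ft <- frequency_table(ft)
  if (attr(ft, "mode") != "haplotype") {
    abort("cpra_haplotype() needs a haplotype-mode frequency table")
  }
  antigens <- ua_antigens(ua)
  hit <- purrr::map_lgl(split_haplotype(ft$haplotype),
                        ~ any(.x %in% antigens))
  per_pop <- dplyr::summarise(
    dplyr::group_by(ft, .data$population, .data$weight),
    acceptable_mass = sum(.data$frequency[!hit[dplyr::cur_group_rows()]]),
    .groups = "drop")
  per_pop$p_acceptable <- per_pop$acceptable_mass^2
  per_pop$cpra <- 1 - per_pop$p_acceptable
  cpra <- 1 - sum(per_pop$weight * per_pop$p_acceptable)
  new_cpra_result(cpra, per_pop, "haplotype_hwe")
}

#' cPRA from per-locus antigen frequencies
#'
#' Linkage-equilibrium variant of [cpra_haplotype()]: loci are treated as
#' independent, so per population P(acceptable) is the product over loci of
#' `(1 - F_l)^2`, where `F_l` is the summed frequency of unacceptable
#' antigens at locus `l`.
#'
#' @inheritParams cpra_haplotype
#' @param ft A `per_locus_antigen`-mode [frequency_table()].
#' @return A `cpra_result`.
#' @export
cpra_per_locus <- function(ua, ft) {
  ft <- frequency_table(ft)
  if (attr(ft, "mode") != "per_locus_antigen") {
    abort("cpra_per_locus() needs a per_locus_antigen-mode frequency table")
  }
  antigens <- ua_antigens(ua)
  per_locus <- dplyr::summarise(
    dplyr::group_by(ft, .data$population, .data$weight, .data$locus),
    f_unacceptable = sum(.data$frequency[.data$antigen %in% antigens]),
    .groups = "drop")
  per_pop <- dplyr::summarise(
    dplyr::group_by(per_locus, .data$population, .data$weight),
    p_acceptable = prod((1 - .data$f_unacceptable)^2), .groups = "drop")
  per_pop$cpra <- 1 - per_pop$p_acceptable
  cpra <- 1 - sum(per_pop$weight * per_pop$p_acceptable)
  new_cpra_result(cpra, per_pop, "per_locus_le")
}

with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Monte Carlo donor-sampling oracle for cPRA
#'
#' Estimates the cPRA by direct simulation: donors are drawn by sampling a
#' population according to the weights, then two haplotypes (haplotype mode)
#' or one genotype per locus (per-locus mode) i.i.d. from that population's
#' frequencies; the estimate is the fraction of donors carrying at least one
#' unacceptable antigen. Serves as an independent check on the closed-form
#' engines.
#'
#' @inheritParams cpra_haplotype
#' @param ft A [frequency_table()] of either mode.
#' @param n_draws Number of simulated donors.
#' @param seed Integer seed; a fixed seed gives a bit-identical repeat.
#' @return A `cpra_result` with the estimate, its binomial standard error,
#'   `n_draws` and `seed`.
#' @export
simulate_donors_oracle <- function(ua, ft, n_draws = 1e5, seed = 1) {
  ft <- frequency_table(ft)
  stopifnot(n_draws >= 1)
  antigens <- ua_antigens(ua)
  mode <- attr(ft, "mode")
  pops <- unique(ft[c("population", "weight")])
  hits <- with_local_seed(seed, {
    pop_draw <- sample(pops$population, n_draws, replace = TRUE,
                       prob = pops$weight)
    unlist(lapply(split(seq_len(n_draws), pop_draw), function(idx) {
      sub <- ft[ft$population == unique(pop_draw[idx]), ]
      n <- length(idx)
      if (mode == "haplotype") {
        hap_hit <- purrr::map_lgl(split_haplotype(sub$haplotype),
                                  ~ any(.x %in% antigens))
        h1 <- sample(hap_hit, n, replace = TRUE, prob = sub$frequency)
        h2 <- sample(hap_hit, n, replace = TRUE, prob = sub$frequency)
        h1 | h2
      } else {
        hit_any <- rep(FALSE, n)
        for (l in unique(sub$locus)) {
          at <- sub[sub$locus == l, ]
          ag_hit <- at$antigen %in% antigens
          a1 <- sample(ag_hit, n, replace = TRUE, prob = at$frequency)
          a2 <- sample(ag_hit, n, replace = TRUE, prob = at$frequency)
          hit_any <- hit_any | a1 | a2
        }
        hit_any
      }
    }), use.names = FALSE)
  })
  est <- mean(hits)
  se <- sqrt(est * (1 - est) / n_draws)
  new_cpra_result(est, tibble::tibble(population = "pooled", cpra = est),
                  "monte_carlo", n_draws = as.integer(n_draws),
                  seed = as.integer(seed), se = se)
}
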