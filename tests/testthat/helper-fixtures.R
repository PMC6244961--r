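# Small builders shared across test files.

toy_panel <- function(alleles, vendor = "LS", lot = "toy",
                      with_positive_control = TRUE) {
  ids <- sprintf("%s-%03d", vendor, seq_along(alleles))
  beads <- tibble::tibble(
    bead_id = c(ids, "NC", if (with_positive_control) "PC"),
    bead = c(alleles, NA, if (with_positive_control) NA),
    control = c(rep("none", length(alleles)), "negative_control",
                if (with_positive_control) "positive_control"))
  hla_panel(beads, vendor = vendor, lot = lot)
}

# Profile with chosen normalized MFIs, bypassing raw-file plumbing.
toy_profile <- function(mfi, panel, serum_id = "S1", secondary = "IgHPolyFab",
                        cutoff = 500) {
  beads <- panel[panel$control == "none", ]
  stopifnot(length(mfi) == nrow(beads))
  out <- tibble::tibble(
    serum_id = serum_id, vendor = attr(panel, "vendor"),
    secondary = secondary, bead_id = beads$bead_id, bead = beads$bead,
    locus = beads$locus_1, hla_class = beads$hla_class,
    normalized_mfi = mfi, positive = mfi >= cutoff)
  structure(out, cutoff = cutoff, dilution = 0.1,
            class = c("serum_profile", class(out)))
}

# Quartet over identical toy LS/LC panels from a named list of MFI vectors
# keyed "LS.FcMonoIgG", "LS.IgHPolyFab", "LC.FcMonoIgG", "LC.IgHPolyFab".
toy_quartet <- function(mfis, alleles, serum_id = "S1", cutoff = 500) {
  ls <- toy_panel(alleles, "LS")
  lc <- toy_panel(alleles, "LC")
  profiles <- lapply(names(mfis), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    panel <- if (parts[1] == "LS") ls else lc
    toy_profile(mfis[[nm]], panel, serum_id = serum_id,
                secondary = parts[2], cutoff = cutoff)
  })
  condition_quartet(profiles, ls, lc)
}

# Brute-force oracles: enumerate every sign assignment explicitly.
brute_force_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  list(v = v_obs,
       p_greater = mean(v_all >= v_obs),
       p_less = mean(v_all <= v_obs),
       p_two_sided = mean(abs(v_all - mu) >= abs(v_obs - mu)))
}

brute_force_sign_test <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  s_obs <- sum(d > 0)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  s_all <- rowSums(signs)
  list(p_greater = mean(s_all >= s_obs),
       p_less = mean(s_all <= s_obs))
}
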