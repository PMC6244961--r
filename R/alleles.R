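#' Parse HLA allele labels
#'
#' Parses WHO-style two-field allele labels as printed on single-antigen-bead
#' panel sheets (e.g. `"B*57:01"`, `"DQB1*03:01"`). The serologic `"Cw"`
#' prefix is accepted as a display alias of locus C and is retained in the
#' canonical form, so parsing followed by formatting round-trips panel labels
#' exactly.
#'
#' @param x Character vector of allele labels. Backslash-joined pair labels
#'   (`"DQB1*x\\DQA1*y"`) are rejected here; use [parse_bead()] for those.
#' @return A tibble with one row per input: `allele` (canonical label),
#'   `locus`, `field1`, `field2`, and `hla_class` (`"I"` or `"II"`).
#' @examples
#' parse_allele(c("A*02:03", "Cw*07:02", "DRB1*14:54"))
#' @export
parse_allele <- function(x) {
  if (length(x) == 0) {
    return(tibble::tibble(allele = character(), locus = character(),
                          field1 = character(), field2 = character(),
                          hla_class = character()))
  }
  if (!is.character(x) || anyNA(x) || any(!nzchar(x))) {
    abort("allele labels must be non-empty, non-missing strings")
  }
  if (any(grepl("\\\\", x))) {
    bad <- x[grepl("\\\\", x)]
    abort(paste0("paired bead label(s) not accepted by parse_allele(); ",
                 "use parse_bead(): ", paste(head(bad, 3), collapse = ", ")))
  }
  m <- regmatches(x, regexec("^([A-Za-z0-9]+)\\*([0-9]{2,3}):([0-9]{2,3})$", x))
  bad <- x[lengths(m) != 4]
  if (length(bad) > 0) {
    abort(paste0("malformed allele label(s): ",
                 paste(head(bad, 5), collapse = ", "),
                 " (expected e.g. \"B*57:01\")"))
  }
  raw_locus <- vapply(m, `[[`, character(1), 2)
  field1 <- vapply(m, `[[`, character(1), 3)
  field2 <- vapply(m, `[[`, character(1), 4)
  locus <- ifelse(raw_locus == "Cw", "C", raw_locus)
  unknown <- unique(raw_locus[!locus %in% SAB_LOCI])
  if (length(unknown) > 0) {
    abort(paste0("unknown HLA locus token(s): ",
                 paste(unknown, collapse = ", ")))
  }
  tibble::tibble(
    allele = format_allele(locus, field1, field2),
    locus = locus,
    field1 = field1,
    field2 = field2,
    hla_class = ifelse(locus %in% CLASS_I_LOCI, "I", "II")
  )
}

#' Format an allele from its parts
#'
#' Locus C is rendered with the serologic `"Cw"` prefix used throughout the
#' bundled panel fixtures.
#'
#' @param locus,field1,field2 Character vectors of equal length.
#' @return Canonical allele labels.
#' @export
format_allele <- function(locus, field1, field2) {
  prefix <- ifelse(locus == "C", "Cw", locus)
  paste0(prefix, "*", field1, ":", field2)
}

#' Parse single-antigen bead labels
#'
#' A bead carries either one allele (class I and DRB beads) or a
#' beta/alpha-chain pair joined by a backslash (DQ and DP beads, e.g.
#' `"DQB1*02:02\\DQA1*03:02"`). Pair order is normalized to beta chain first.
#'
#' @param x Character vector of bead labels.
#' @return A tibble with one row per bead: `bead` (canonical label),
#'   `allele_1`, `allele_2` (`NA` for single-allele beads), `locus_1`,
#'   `locus_2`, and `hla_class`.
#' @examples
#' parse_bead(c("B*15:12", "DQB1*02:02\\DQA1*03:02"))
#' @export
parse_bead <- function(x) {
  if (length(x) == 0) {
    return(tibble::tibble(bead = character(), allele_1 = character(),
                          allele_2 = character(), locus_1 = character(),
                          locus_2 = character(), hla_class = character()))
  }
  parts <- strsplit(x, "\\", fixed = TRUE)
  n_part <- lengths(parts)
  if (any(n_part > 2)) {
    abort(paste0("bead label with more than two alleles: ",
                 paste(x[n_part > 2], collapse = ", ")))
  }
  one <- purrr::map2(parts, x, function(p, label) {
    a <- parse_allele(p)
    if (nrow(a) == 1) {
      if (a$locus %in% ALPHA_LOCI) {
        abort(paste0("lone alpha-chain allele cannot form a bead: ", label))
      }
      return(tibble::tibble(bead = a$allele, allele_1 = a$allele,
                            allele_2 = NA_character_, locus_1 = a$locus,
                            locus_2 = NA_character_, hla_class = a$hla_class))
    }
    beta <- a$locus %in% BETA_LOCI
    alpha <- a$locus %in% ALPHA_LOCI
    if (sum(beta) != 1 || sum(alpha) != 1) {
      abort(paste0("paired bead must combine one beta- and one alpha-chain ",
                   "allele: ", label))
    }
    gene <- substr(a$locus, 1, 2)
    if (gene[1] != gene[2]) {
      abort(paste0("paired bead mixes DQ and DP chains: ", label))
    }
    b <- a[beta, ]
    al <- a[alpha, ]
    tibble::tibble(bead = paste0(b$allele, "\\", al$allele),
                   allele_1 = b$allele, allele_2 = al$allele,
                   locus_1 = b$locus, locus_2 = al$locus,
                   hla_class = "II")
  })
  dplyr::bind_rows(one)
}
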