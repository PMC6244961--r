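#' Construct a bead panel
#'
#' A bead panel is one vendor's set of single-antigen beads plus its control
#' beads, held as a tibble with one row per bead. Panels are validated for
#' duplicate antigen entries and for the presence of exactly one
#' negative-control and at most one positive-control bead.
#'
#' @param beads A data frame with columns `bead_id`, `bead` (allele label or
#'   `"beta\\alpha"` pair label; may be `NA` for control beads) and `control`
#'   (`"none"`, `"negative_control"` or `"positive_control"`).
#' @param vendor `"LS"` or `"LC"`.
#' @param lot Free-text lot label.
#' @return A tibble of class `hla_panel` with parsed allele columns.
#' @export
hla_panel <- function(beads, vendor = c("LS", "LC"), lot = "") {
  vendor <- match.arg(vendor)
  stopifnot(is.data.frame(beads),
            all(c("bead_id", "bead", "control") %in% names(beads)))
  if (!all(beads$control %in% c("none", "negative_control", "positive_control"))) {
    abort("control must be one of none/negative_control/positive_control")
  }
  if (sum(beads$control == "negative_control") != 1) {
    abort("panel must contain exactly one negative-control bead")
  }
  if (sum(beads$control == "positive_control") > 1) {
    abort("panel may contain at most one positive-control bead")
  }
  antigen <- beads[beads$control == "none", ]
  parsed <- parse_bead(antigen$bead)
  if (anyDuplicated(parsed$bead)) {
    dup <- unique(parsed$bead[duplicated(parsed$bead)])
    abort(paste0("duplicate antigen entries in panel: ",
                 paste(dup, collapse = ", ")))
  }
  ctrl <- beads[beads$control != "none", ]
  out <- dplyr::bind_rows(
    tibble::tibble(bead_id = antigen$bead_id, control = "none", parsed),
    tibble::tibble(bead_id = ctrl$bead_id, control = ctrl$control,
                   bead = NA_character_, allele_1 = NA_character_,
                   allele_2 = NA_character_, locus_1 = NA_character_,
                   locus_2 = NA_character_, hla_class = NA_character_)
  )
  if (anyDuplicated(out$bead_id)) {
    abort("duplicate bead_id in panel")
  }
  structure(out, vendor = vendor, lot = lot,
            class = c("hla_panel", class(out)))
}

#' @export
print.hla_panel <- function(x, ...) {
  cat(sprintf("<hla_panel> vendor %s, lot \"%s\": %d antigen beads, %d controls\n",
              attr(x, "vendor"), attr(x, "lot"),
              sum(x$control == "none"), sum(x$control != "none")))
  NextMethod()
}

#' Read a panel definition file
#'
#' Expects a CSV with columns `vendor`, `lot`, `bead_id`, `allele_1`,
#' `allele_2` (blank if none) and `control_flag`.
#'
#' @param path Path to the CSV file.
#' @return An [hla_panel()] tibble.
#' @export
read_panel <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  need <- c("vendor", "lot", "bead_id", "allele_1", "allele_2", "control_flag")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("panel file missing column(s): ", paste(missing, collapse = ", ")))
  }
  bead <- ifelse(is.na(df$allele_2) | !nzchar(df$allele_2),
                 df$allele_1, paste0(df$allele_1, "\\", df$allele_2))
  hla_panel(tibble::tibble(bead_id = df$bead_id, bead = bead,
                           control = df$control_flag),
            vendor = df$vendor[1], lot = df$lot[1])
}

#' Bundled vendor class-I reference panels
#'
#' Class-I bead panels for the two vendors, reconstructed from the bundled
#' three-monoclonal-antibody panel characterisation table
#' ([table7_tfl006()]): an allele belongs to a vendor's panel exactly when
#' that vendor's column carries a reading (absent alleles are marked N/A in
#' the source table). Each panel also carries its negative- and
#' positive-control beads.
#'
#' @param vendor `"LS"` or `"LC"`.
#' @return An [hla_panel()].
#' @examples
#' nrow(reference_panel("LS"))
#' @export
reference_panel <- function(vendor = c("LS", "LC")) {
  vendor <- match.arg(vendor)
  t7 <- table7_tfl006()
  col <- if (vendor == "LS") t7$ls_mfi else t7$lc_mfi
  keep <- t7$control != "none" | !is.na(col)
  rows <- t7[keep, ]
  lot <- if (vendor == "LS") "Lot 10" else "Lot 3005613"
  hla_panel(tibble::tibble(
    bead_id = sprintf("%s-%03d", vendor, seq_len(nrow(rows))),
    bead = ifelse(rows$control == "none", rows$antigen, NA_character_),
    control = rows$control
  ), vendor = vendor, lot = lot)
}

#' Bundled beta2-microglobulin-free heavy-chain characterisation table
#'
#' Per-bead normalized MFI of the TFL-006 monoclonal antibody (which binds
#' beta2-microglobulin-free HLA class I heavy chains) on both vendors'
#' class-I panels, at 20 ug/mL. `NA` means the allele is absent from that
#' vendor's panel, not zero binding.
#'
#' @return A tibble with columns `antigen`, `control`, `ls_mfi`, `lc_mfi`.
#' @export
table7_tfl006 <- function() {
  readr::read_csv(sab_extdata("table7_tfl006.csv"),
                  col_types = readr::cols(antigen = "c", control = "c",
                                          ls_mfi = "d", lc_mfi = "d"))
}

#' Bundled vendor-unique antigen lists
#'
#' The published lists of antigens unique to each vendor's class I and
#' class II panels, stored verbatim as printed (including the printed
#' inconsistencies; see the methods vignette).
#'
#' @return A tibble with columns `hla_class`, `unique_to`, `bead`.
#' @export
table1_unique <- function() {
  readr::read_csv(sab_extdata("table1_unique.csv"),
                  col_types = readr::cols(.default = "c"))
}

panel_allele_set <- function(panel, locus = NULL) {
  x <- panel[panel$control == "none", ]
  if (!is.null(locus)) {
    x <- x[x$locus_1 %in% locus, ]
  }
  x
}

#' Antigens common to two panels
#'
#' Returns the beads whose antigen content is identical between the two
#' panels (control beads excluded); all cross-vendor comparisons in the
#' pipeline are restricted to this set.
#'
#' @param a,b [hla_panel()] objects.
#' @param locus Optional locus filter (e.g. `"A"`; uses the beta-chain locus
#'   for paired beads).
#' @return A tibble with columns `bead`, `locus`, `hla_class`, sorted by
#'   bead label; symmetric in `a` and `b`.
#' @examples
#' nrow(common_alleles(reference_panel("LS"), reference_panel("LC"), "A"))
#' @export
common_alleles <- function(a, b, locus = NULL) {
  xa <- panel_allele_set(a, locus)
  xb <- panel_allele_set(b, locus)
  keep <- intersect(xa$bead, xb$bead)
  idx <- match(sort(keep), xa$bead)
  tibble::tibble(bead = xa$bead[idx], locus = xa$locus_1[idx],
                 hla_class = xa$hla_class[idx])
}

#' Antigens unique to one panel
#'
#' @param a,b [hla_panel()] objects; returns antigens present in `a` and
#'   absent from `b`.
#' @param locus Optional locus filter.
#' @return A tibble with columns `bead`, `locus`, `hla_class`.
#' @export
unique_alleles <- function(a, b, locus = NULL) {
  xa <- panel_allele_set(a, locus)
  xb <- panel_allele_set(b, locus)
  keep <- setdiff(xa$bead, xb$bead)
  idx <- match(sort(keep), xa$bead)
  tibble::tibble(bead = xa$bead[idx], locus = xa$locus_1[idx],
                 hla_class = xa$hla_class[idx])
}

#' Allele to serologic base-antigen map
#'
#' Loads the bundled allele-to-base-antigen equivalence table (standard
#' serologic split equivalences, e.g. A*02:03 -> A2, B*14:01 -> B64). The
#' table is data, not code: supply `path` to use an edited copy.
#'
#' @param path Optional path to a CSV with columns `allele`, `base_antigen`.
#' @return A tibble with columns `allele`, `base_antigen`.
#' @export
antigen_map <- function(path = NULL) {
  path <- path %||% sab_extdata("antigen_map.csv")
  readr::read_csv(path, col_types = readr::cols(.default = "c"))
}

#' Serologic base antigen of an allele
#'
#' DRB3/DRB4/DRB5 alleles map to the locus-level serologic antigens
#' DR52/DR53/DR51. Alleles at loci excluded from unacceptable-antigen
#' listing (DQA1, DPA1, DPB1) and alleles absent from the map return `NA`;
#' callers decide whether an unmapped allele is an error.
#'
#' @param allele Character vector of allele labels.
#' @param map An [antigen_map()] tibble.
#' @return Character vector of base-antigen labels (`NA` when unmapped).
#' @examples
#' base_antigen(c("A*02:03", "DRB4*01:03"))
#' @export
base_antigen <- function(allele, map = antigen_map()) {
  parsed <- parse_allele(allele)
  out <- map$base_antigen[match(parsed$allele, map$allele)]
  drb345 <- parsed$locus %in% names(DRB345_MAP)
  out[drb345] <- DRB345_MAP[parsed$locus[drb345]]
  out
}
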