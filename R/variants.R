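#' Classify the conformational content of beads
#'
#' Derives per-bead conformational flags from the three-monoclonal-antibody
#' characterisation assay: W6/32 binds the intact trimer (heavy chain +
#' beta2-microglobulin + peptide), HC-10 binds peptide-free
#' beta2-microglobulin-associated heavy chain, and TFL-006 binds
#' beta2-microglobulin-free heavy chain. A flag is set when the
#' corresponding normalized MFI is at or above `cutoff` (default 1000).
#' A missing reading yields an `NA` flag ("unknown"), never `FALSE`.
#'
#' @param readings Data frame with a bead identifier column (`bead_id` or
#'   `antigen`) and numeric columns `w632_mfi`, `hc10_mfi`, `tfl006_mfi`
#'   (any may be `NA`; a row with all three missing is an error).
#' @param cutoff Positive-reaction cutoff in MFI units.
#' @return A tibble of class `variant_flags`: the identifier column plus
#'   `has_intact`, `has_peptide_free_hc`, `has_b2m_free_hc` and the stored
#'   MFIs, so flags are recomputable.
#' @examples
#' classify_beads(data.frame(bead_id = "b1", w632_mfi = 15000,
#'                           hc10_mfi = 300, tfl006_mfi = 7805))
#' @export
classify_beads <- function(readings, cutoff = 1000) {
  stopifnot(is.data.frame(readings))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    abort("cutoff must be a single positive number")
  }
  id_col <- intersect(c("bead_id", "antigen"), names(readings))[1]
  if (is.na(id_col)) {
    abort("readings need a bead_id or antigen column")
  }
  mabs <- c("w632_mfi", "hc10_mfi", "tfl006_mfi")
  for (m in setdiff(mabs, names(readings))) {
    readings[[m]] <- NA_real_
  }
  vals <- as.matrix(readings[mabs])
  if (any(vals < 0, na.rm = TRUE)) {
    abort("mAb MFI values must be non-negative (floor at zero for this assay)")
  }
  all_absent <- rowSums(!is.na(vals)) == 0
  if (any(all_absent)) {
    abort(paste0("bead(s) with no mAb reading at all: ",
                 paste(head(readings[[id_col]][all_absent], 5), collapse = ", ")))
  }
  out <- tibble::tibble(
    !!id_col := readings[[id_col]],
    w632_mfi = vals[, "w632_mfi"],
    hc10_mfi = vals[, "hc10_mfi"],
    tfl006_mfi = vals[, "tfl006_mfi"],
    has_intact = vals[, "w632_mfi"] >= cutoff,
    has_peptide_free_hc = vals[, "hc10_mfi"] >= cutoff,
    has_b2m_free_hc = vals[, "tfl006_mfi"] >= cutoff
  )
  structure(out, cutoff = cutoff, class = c("variant_flags", class(out)))
}

#' Summarize conformational variants across a panel
#'
#' Counts, per locus, the beads carrying each conformational variant at the
#' given cutoff, together with the fraction of that locus' beads.
#'
#' @param readings As for [classify_beads()]; bead identifiers must resolve
#'   against `panel` (by `bead_id` or antigen label).
#' @param panel An [hla_panel()] supplying the locus of each bead.
#' @param cutoff Positive-reaction cutoff in MFI units (default 1000).
#' @return A tibble with columns `locus`, `flag`, `n_positive`, `n_tested`
#'   (beads with a non-missing reading for that mAb) and `fraction`.
#' @export
summarize_panel_variants <- function(readings, panel, cutoff = 1000) {
  flags <- classify_beads(readings, cutoff = cutoff)
  id_col <- intersect(c("bead_id", "antigen"), names(flags))[1]
  key <- if (id_col == "bead_id") panel$bead_id else panel$bead
  idx <- match(flags[[id_col]], key)
  if (anyNA(idx)) {
    abort(paste0("reading(s) not resolvable against the panel: ",
                 paste(head(flags[[id_col]][is.na(idx)], 5), collapse = ", ")))
  }
  flags$locus <- panel$locus_1[idx]
  flags <- flags[panel$control[idx] == "none", ]
  long <- tidyr::pivot_longer(
    flags[c("locus", "has_intact", "has_peptide_free_hc", "has_b2m_free_hc")],
    cols = -"locus", names_to = "flag", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$locus, .data$flag),
    n_positive = sum(.data$value, na.rm = TRUE),
    n_tested = sum(!is.na(.data$value)),
    .groups = "drop")
  out$fraction <- ifelse(out$n_tested > 0, out$n_positive / out$n_tested, NA_real_)
  structure(out, cutoff = cutoff, class = c("variant_summary", class(out)))
}

#' TFL-006 readings for a bundled vendor panel
#'
#' Extracts one vendor's column of the bundled beta2-microglobulin-free
#' heavy-chain characterisation table ([table7_tfl006()]) as a reading table
#' consumable by [classify_beads()] and [summarize_panel_variants()].
#' W6/32 and HC-10 per-bead readings are not part of the bundled table, so
#' those columns are `NA` ("unknown").
#'
#' @param vendor `"LS"` or `"LC"`.
#' @return A tibble with columns `antigen` and `tfl006_mfi` for the beads
#'   present on that vendor's panel.
#' @export
tfl006_readings <- function(vendor = c("LS", "LC")) {
  vendor <- match.arg(vendor)
  t7 <- table7_tfl006()
  col <- if (vendor == "LS") t7$ls_mfi else t7$lc_mfi
  keep <- t7$control == "none" & !is.na(col)
  tibble::tibble(antigen = t7$antigen[keep], tfl006_mfi = col[keep])
}
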