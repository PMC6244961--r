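#' Normalize a trimmed-mean bead MFI
#'
#' Applies the background-correction formula used throughout the pipeline:
#' the buffer-only (PBS) reading is subtracted from the trimmed-mean MFI,
#' then the negative-control bead (NC) reading, then the mean of the
#' negative-control sera readings from the two vendors' kits (NGS):
#'
#' \deqn{((\mathrm{trim} - \mathrm{PBS}) - \mathrm{NC}) -
#'       (\mathrm{NGS}_{LS} + \mathrm{NGS}_{LC})/2}
#'
#' The result is not clamped; negative normalized values are retained and
#' handled by positivity calling.
#'
#' @param trim_mean,pbs,nc,ngs_ls,ngs_lc Numeric vectors (recycled to a
#'   common length), all finite and non-negative.
#' @return Numeric vector of normalized MFI values.
#' @examples
#' normalize_mfi(1000, 50, 100, 60, 40)  # 800
#' @export
normalize_mfi <- function(trim_mean, pbs, nc, ngs_ls, ngs_lc) {
  args <- vctrs::vec_recycle_common(trim_mean = trim_mean, pbs = pbs, nc = nc,
                                    ngs_ls = ngs_ls, ngs_lc = ngs_lc)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      abort(paste0("'", nm, "' must be finite and non-negative"))
    }
  }
  with(args, ((trim_mean - pbs) - nc) - (ngs_ls + ngs_lc) / 2)
}

#' Call positivity on a normalized MFI
#'
#' A bead is positive when its normalized MFI is at or above the cutoff
#' (default 500 MFI at a 1/10 serum dilution).
#'
#' @param normalized Numeric vector of normalized MFI values.
#' @param cutoff Positivity cutoff in MFI units; must be positive.
#' @return Logical vector.
#' @export
call_positive <- function(normalized, cutoff = 500) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    abort("cutoff must be a single positive number")
  }
  normalized >= cutoff
}

resolve_controls <- function(controls, bead_id) {
  need <- c("pbs", "nc", "ngs_ls", "ngs_lc")
  if (is.data.frame(controls)) {
    missing <- setdiff(c("bead_id", need), names(controls))
    if (length(missing) > 0) {
      abort(paste0("controls table missing column(s): ",
                   paste(missing, collapse = ", ")))
    }
    idx <- match(bead_id, controls$bead_id)
    if (anyNA(idx)) {
      abort(paste0("controls missing for bead(s): ",
                   paste(head(bead_id[is.na(idx)], 5), collapse = ", ")))
    }
    lapply(controls[need], `[`, idx)
  } else if (is.list(controls)) {
    missing <- setdiff(need, names(controls))
    if (length(missing) > 0) {
      abort(paste0("controls missing value(s): ",
                   paste(missing, collapse = ", ")))
    }
    controls[need]
  } else {
    abort("controls must be a data frame keyed by bead_id or a named list of scalars")
  }
}

#' Normalize a raw serum run into a serum profile
#'
#' Converts one serum's raw bead readings under one (vendor panel, secondary
#' antibody) condition into normalized MFIs with positivity flags. Control
#' beads are dropped from the output; background corrections are per-bead
#' when a per-bead controls table is supplied and scalar otherwise.
#'
#' @param raw Data frame of raw readings with columns `bead_id`,
#'   `trimmed_mean` and optionally `bead_count`.
#' @param controls Either a data frame with columns `bead_id`, `pbs`, `nc`,
#'   `ngs_ls`, `ngs_lc`, or a named list of scalar values.
#' @param panel The [hla_panel()] the run was acquired on; every raw bead id
#'   must resolve against it.
#' @param serum_id,secondary Identifiers stored with the profile.
#' @param cutoff Positivity cutoff (default 500).
#' @param dilution Serum dilution as a ratio (default 0.1, i.e. 1/10).
#' @return A tibble of class `serum_profile` with one row per non-control
#'   bead: `serum_id`, `vendor`, `secondary`, `bead_id`, `bead`, `locus`,
#'   `hla_class`, `normalized_mfi`, `positive`; cutoff and dilution are
#'   carried as attributes.
#' @export
normalize_profile <- function(raw, controls, panel, serum_id = "serum",
                              secondary = "IgHPolyFab", cutoff = 500,
                              dilution = 0.1) {
  stopifnot(is.data.frame(raw), inherits(panel, "hla_panel"))
  if (!all(c("bead_id", "trimmed_mean") %in% names(raw))) {
    abort("raw readings need columns bead_id and trimmed_mean")
  }
  unknown <- setdiff(raw$bead_id, panel$bead_id)
  if (length(unknown) > 0) {
    abort(paste0("raw readings contain bead id(s) not in the panel: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  ctl <- resolve_controls(controls, raw$bead_id)
  norm <- normalize_mfi(raw$trimmed_mean, ctl$pbs, ctl$nc,
                        ctl$ngs_ls, ctl$ngs_lc)
  idx <- match(raw$bead_id, panel$bead_id)
  out <- tibble::tibble(
    serum_id = serum_id,
    vendor = attr(panel, "vendor"),
    secondary = secondary,
    bead_id = raw$bead_id,
    bead = panel$bead[idx],
    locus = panel$locus_1[idx],
    hla_class = panel$hla_class[idx],
    normalized_mfi = norm,
    positive = call_positive(norm, cutoff)
  )
  out <- out[panel$control[idx] == "none", ]
  structure(out, cutoff = cutoff, dilution = dilution,
            class = c("serum_profile", class(out)))
}

#' Median MFI over positive beads
#'
#' @param profile A `serum_profile` (or any data frame with
#'   `normalized_mfi` and `positive` columns).
#' @return The median normalized MFI over positive beads, or `NA` when the
#'   profile has no positive bead (undefined, never 0).
#' @export
median_positive_mfi <- function(profile) {
  pos <- profile$normalized_mfi[profile$positive]
  if (length(pos) == 0) {
    return(NA_real_)
  }
  median(pos)
}
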