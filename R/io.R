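#' Read a raw bead-reading CSV
#'
#' Luminex-export-style file: one row per bead, comma-separated, UTF-8,
#' mandatory header, columns `bead_id`, `trimmed_mean` and optionally
#' `bead_count`. One file holds one (serum, vendor, secondary) run.
#'
#' @param path Path to the CSV file.
#' @return A tibble of typed readings.
#' @export
read_raw_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if ("trimmed_mean" %in% names(df)) df$trimmed_mean <- as.numeric(df$trimmed_mean)
  if ("bead_count" %in% names(df)) df$bead_count <- as.integer(df$bead_count)
  missing <- setdiff(c("bead_id", "trimmed_mean"), names(df))
  if (length(missing) > 0) {
    abort(paste0("raw reading file ", path, " missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$bead_id)) {
    dup <- unique(df$bead_id[duplicated(df$bead_id)])
    abort(paste0("duplicate bead_id in ", path, ": ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  df
}

#' Read a per-bead controls CSV
#'
#' @param path Path to a CSV keyed by `bead_id` with columns `pbs`, `nc`,
#'   `ngs_ls`, `ngs_lc`.
#' @return A tibble.
#' @export
read_controls_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    bead_id = "c", .default = "d"))
  missing <- setdiff(c("bead_id", "pbs", "nc", "ngs_ls", "ngs_lc"), names(df))
  if (length(missing) > 0) {
    abort(paste0("controls file ", path, " missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Write a report table
#'
#' Serializes a summary table as TSV or JSON at full numeric precision, so
#' that writing and re-reading round-trips.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  x <- tibble::as_tibble(x)
  if (format == "tsv") {
    readr::write_tsv(x, path)
  } else {
    jsonlite::write_json(x, path, dataframe = "columns", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a report table written by [write_report()]
#'
#' @param path Path to a `.tsv` or `.json` report.
#' @return A tibble.
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
}

#' Write a simulation to disk
#'
#' Emits the raw/control CSV dialect consumed by the pipeline, one raw file
#' per (serum, vendor, secondary) run, one controls file per vendor, plus
#' `truth.json` with the generator's ground truth.
#'
#' @param sim A [simulate_experiment()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  runs <- unique(sim$raw[c("serum_id", "vendor", "secondary")])
  purrr::pwalk(runs, function(serum_id, vendor, secondary) {
    rows <- sim$raw[sim$raw$serum_id == serum_id & sim$raw$vendor == vendor &
                      sim$raw$secondary == secondary, ]
    readr::write_csv(rows[c("bead_id", "trimmed_mean", "bead_count")],
                     file.path(outdir, paste0("raw_", serum_id, "_", vendor,
                                              "_", secondary, ".csv")))
  })
  for (v in names(sim$controls)) {
    readr::write_csv(sim$controls[[v]],
                     file.path(outdir, paste0("controls_", v, ".csv")))
  }
  truth <- sim$truth
  truth$sera <- lapply(truth$sera, function(cl) {
    cl$alleles <- lapply(cl$alleles, as.character)
    cl
  })
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Pipeline run configuration
#'
#' Collects the knobs of a full pipeline run. Cutoffs must be positive;
#' referenced files are checked at validation time.
#'
#' @param raw_dir Directory holding `raw_<serum>_<vendor>_<secondary>.csv`
#'   and `controls_<vendor>.csv` files (as written by [write_simulation()]).
#' @param out_dir Output directory for reports.
#' @param panels Named list of [hla_panel()] objects (`LS`, `LC`), or `NULL`
#'   for the bundled reference panels.
#' @param positivity_cutoff,variant_cutoff,high_cutoff MFI cutoffs
#'   (defaults 500, 1000, 1000).
#' @param dilution Serum dilution ratio (default 0.1).
#' @param freq_table Optional [frequency_table()] (or path) for the cPRA
#'   stage; with `NULL` the stage is skipped with a warning.
#' @param mab_files Optional named list of mAb reading CSVs (`w632`,
#'   `hc10`, `tfl006`) per vendor for the variant stage.
#' @param seed Seed recorded in the manifest.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(raw_dir, out_dir, panels = NULL,
                       positivity_cutoff = 500, variant_cutoff = 1000,
                       high_cutoff = 1000, dilution = 0.1,
                       freq_table = NULL, mab_files = NULL, seed = 1) {
  stopifnot(positivity_cutoff > 0, variant_cutoff > 0, high_cutoff > 0,
            dilution > 0)
  if (!dir.exists(raw_dir)) {
    abort(paste0("raw_dir does not exist: ", raw_dir))
  }
  panels <- panels %||% list(LS = reference_panel("LS"),
                             LC = reference_panel("LC"))
  structure(list(raw_dir = raw_dir, out_dir = out_dir, panels = panels,
                 positivity_cutoff = positivity_cutoff,
                 variant_cutoff = variant_cutoff, high_cutoff = high_cutoff,
                 dilution = dilution, freq_table = freq_table,
                 mab_files = mab_files, seed = seed),
            class = "run_config")
}

stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' normalize -> variants (when mAb files are configured) -> concordance ->
#' cPRA (when a frequency table is configured), writing TSV reports and a
#' JSON manifest (package version, seed, cutoffs) to the configured output
#' directory. Any stage error aborts with a stage-tagged message; a missing
#' frequency table only skips the cPRA stage with a warning.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `profiles`, `quartets`, `summary`,
#'   `variants`, `cpra` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  files <- list.files(config$raw_dir, pattern = "^raw_.*\\.csv$")
  if (length(files) == 0) {
    abort(paste0("no raw_*.csv files in ", config$raw_dir))
  }
  meta <- stringr::str_match(files, "^raw_(.+)_(LS|LC)_([A-Za-z]+)\\.csv$")
  if (anyNA(meta[, 1])) {
    abort(paste0("unparseable raw file name(s): ",
                 paste(files[is.na(meta[, 1])], collapse = ", ")))
  }
  controls <- stage("normalize", lapply(
    setNames(nm = unique(meta[, 3])), function(v) {
      read_controls_csv(file.path(config$raw_dir,
                                  paste0("controls_", v, ".csv")))
    }))
  profiles <- stage("normalize", purrr::pmap(
    list(files, meta[, 2], meta[, 3], meta[, 4]),
    function(f, serum, vendor, secondary) {
      normalize_profile(read_raw_csv(file.path(config$raw_dir, f)),
                        controls[[vendor]], config$panels[[vendor]],
                        serum_id = serum, secondary = secondary,
                        cutoff = config$positivity_cutoff,
                        dilution = config$dilution)
    }))
  names(profiles) <- paste(meta[, 2], meta[, 3], meta[, 4], sep = ".")

  variants <- NULL
  if (!is.null(config$mab_files)) {
    variants <- stage("variants", {
      lapply(setNames(nm = names(config$mab_files)), function(v) {
        mabs <- config$mab_files[[v]]
        readings <- read_raw_csv(mabs[[1]])[, "bead_id"]
        cols <- c(w632 = "w632_mfi", hc10 = "hc10_mfi", tfl006 = "tfl006_mfi")
        for (m in names(cols)) {
          if (!is.null(mabs[[m]])) {
            df <- read_raw_csv(mabs[[m]])
            readings[[cols[[m]]]] <- df$trimmed_mean[match(readings$bead_id,
                                                           df$bead_id)]
          }
        }
        summarize_panel_variants(readings, config$panels[[v]],
                                 cutoff = config$variant_cutoff)
      })
    })
    for (v in names(variants)) {
      write_report(variants[[v]],
                   file.path(config$out_dir, paste0("variants_", v, ".tsv")))
    }
  }

  summary <- stage("concordance", {
    sera <- unique(meta[, 2])
    quartets <- lapply(sera, function(s) {
      condition_quartet(profiles[meta[, 2] == s],
                        config$panels$LS, config$panels$LC)
    })
    names(quartets) <- sera
    list(quartets = quartets, summary = summarize_concordance(quartets))
  })
  write_report(summary$summary$counts,
               file.path(config$out_dir, "reactive_counts.tsv"))
  write_report(summary$summary$tallies,
               file.path(config$out_dir, "vendor_tallies.tsv"))
  write_report(summary$summary$groups,
               file.path(config$out_dir, "serum_groups.tsv"))
  write_report(summary$summary$tests,
               file.path(config$out_dir, "paired_tests.tsv"))

  cpra <- NULL
  if (is.null(config$freq_table)) {
    warn("no frequency table configured; cPRA stage skipped")
  } else {
    cpra <- stage("cpra", {
      ft <- frequency_table(config$freq_table)
      engine <- if (attr(ft, "mode") == "haplotype") cpra_haplotype
                else cpra_per_locus
      dplyr::bind_rows(lapply(names(profiles), function(nm) {
        ua <- expand_unacceptable(profiles[[nm]],
                                  cutoff = config$positivity_cutoff)
        res <- engine(ua, ft)
        tibble::tibble(run = nm, n_unacceptable = length(ua$antigens),
                       n_excluded = nrow(ua$excluded),
                       cpra = res$cpra, cpra_pct = 100 * res$cpra)
      }))
    })
    write_report(cpra, file.path(config$out_dir, "cpra.tsv"))
  }

  manifest <- list(
    package = "hlasab",
    version = as.character(utils::packageVersion("hlasab")),
    seed = config$seed,
    cutoffs = list(positivity = config$positivity_cutoff,
                   variant = config$variant_cutoff,
                   high = config$high_cutoff),
    dilution = config$dilution,
    n_runs = length(profiles),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(profiles = profiles, quartets = summary$quartets,
                 summary = summary$summary, variants = variants,
                 cpra = cpra, manifest = manifest))
}
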