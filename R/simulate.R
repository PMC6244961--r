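#' Vendor bead-composition profiles
#'
#' Distributions of the conformational composition of each bead's antigen
#' coat, per vendor. Each bead carries fractions of intact native trimer
#' (`native_frac`), peptide-free beta2-microglobulin-associated heavy chain
#' (`peptide_free_frac`) and beta2-microglobulin-free heavy chain
#' (`b2m_free_frac`) summing to at most 1. The LS profile draws a positive
#' beta2-microglobulin-free fraction for most class-I beads; the LC profile
#' has that fraction identically zero and a lower peptide-free share,
#' mirroring the characterised difference between the two vendors' panels.
#'
#' @param vendor `"LS"` or `"LC"`.
#' @return A list of distribution parameters consumed by
#'   [make_vendor_composition()]: `native_range`, `peptide_free_share`,
#'   `b2m_free_share` (shares of the non-native remainder) and
#'   `b2m_free_prob` (probability a bead carries any free heavy chain).
#' @export
vendor_profile <- function(vendor = c("LS", "LC")) {
  vendor <- match.arg(vendor)
  if (vendor == "LS") {
    list(native_range = c(0.40, 0.60), peptide_free_share = c(0.10, 0.35),
         b2m_free_share = c(0.30, 0.60), b2m_free_prob = 0.85)
  } else {
    list(native_range = c(0.70, 0.95), peptide_free_share = c(0.02, 0.15),
         b2m_free_share = c(0, 0), b2m_free_prob = 0)
  }
}

#' Draw a bead composition for a panel
#'
#' @param panel An [hla_panel()].
#' @param profile A [vendor_profile()] (defaults to the panel vendor's).
#' @param seed Optional integer seed; with `NULL` the current RNG stream is
#'   used.
#' @return A tibble with one row per antigen bead: `bead_id`, `bead`,
#'   `native_frac`, `peptide_free_frac`, `b2m_free_frac`.
#' @export
make_vendor_composition <- function(panel, profile = NULL, seed = NULL) {
  profile <- profile %||% vendor_profile(attr(panel, "vendor"))
  draw <- function() {
    beads <- panel[panel$control == "none", ]
    n <- nrow(beads)
    native <- runif(n, profile$native_range[1], profile$native_range[2])
    rest <- 1 - native
    pf <- rest * runif(n, profile$peptide_free_share[1],
                       profile$peptide_free_share[2])
    bf <- rest * runif(n, profile$b2m_free_share[1],
                       profile$b2m_free_share[2]) *
      rbinom(n, 1, profile$b2m_free_prob)
    tibble::tibble(bead_id = beads$bead_id, bead = beads$bead,
                   native_frac = native, peptide_free_frac = pf,
                   b2m_free_frac = bf)
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Serum clone repertoires
#'
#' A serum is modelled as a set of IgG clones. A `native` clone binds the
#' intact-trimer fraction of the beads carrying its target allele(s); a
#' `peptide_free` or `b2m_free` clone binds the corresponding variant
#' fraction across a breadth set of alleles (the shared or "public" epitopes
#' exposed on disrupted heavy chains).
#'
#' @param epitope_class `"native"`, `"peptide_free"` or `"b2m_free"`.
#' @param alleles Character vector of target (native) or breadth (shared)
#'   alleles; must be non-empty.
#' @param concentration Binding-unit concentration, `>= 0`.
#' @return A one-row tibble; rows bind into a clone table.
#' @export
serum_clone <- function(epitope_class = c("native", "peptide_free", "b2m_free"),
                        alleles, concentration) {
  epitope_class <- match.arg(epitope_class)
  if (length(alleles) == 0) {
    abort("a clone's allele set must be non-empty")
  }
  if (concentration < 0) {
    abort("clone concentration must be non-negative")
  }
  tibble::tibble(epitope_class = epitope_class, alleles = list(alleles),
                 concentration = concentration)
}

#' Bound IgG density on each bead
#'
#' Mass-action shorthand: the IgG surface density on a bead is the sum over
#' matching clones of clone concentration times the bead fraction presenting
#' the clone's epitope class (native clones bind `native_frac` of their
#' target alleles; shared-epitope clones bind the variant fraction across
#' their breadth set). Contributions are additive.
#'
#' @param clones A clone table ([serum_clone()] rows).
#' @param composition A [make_vendor_composition()] tibble.
#' @return A tibble `bead_id`, `bead`, `density`.
#' @export
bound_density <- function(clones, composition) {
  frac_col <- c(native = "native_frac", peptide_free = "peptide_free_frac",
                b2m_free = "b2m_free_frac")
  density <- rep(0, nrow(composition))
  for (i in seq_len(nrow(clones))) {
    match_bead <- composition$bead %in% clones$alleles[[i]]
    frac <- composition[[frac_col[[clones$epitope_class[i]]]]]
    density <- density + match_bead * frac * clones$concentration[i]
  }
  tibble::tibble(bead_id = composition$bead_id, bead = composition$bead,
                 density = density)
}

#' Secondary-antibody detection model
#'
#' Converts bound IgG density to fluorescence. The Fc-specific monoclonal
#' secondary (`FcMonoIgG`) binds the primary antibody one-to-one, so its
#' gain is density-independent. The polyclonal anti-heavy-chain F(ab')2
#' secondary (`IgHPolyFab`) can bind multiple epitopes per primary IgG when
#' the bead surface is sparsely occupied, but crowding and aggregation at
#' high density restrict access, modelled as the strictly decreasing gain
#' `g(D) = 1 + (A - 1) exp(-D / D0)` with `g(0) = A` and `g(Inf) = 1`.
#'
#' @param secondary `"FcMonoIgG"` or `"IgHPolyFab"`.
#' @param alpha Fluorescence per unit of detected IgG (MFI per density
#'   unit).
#' @param amp_max Maximum amplification `A >= 1` of the polyclonal
#'   secondary at vanishing density.
#' @param density_scale Density `D0 > 0` at which amplification has decayed
#'   by `1/e`.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise.
#' @param background_mfi Mean background fluorescence added to every bead.
#' @return A list of class `detection_model`.
#' @export
detection_model <- function(secondary = c("FcMonoIgG", "IgHPolyFab"),
                            alpha = 1, amp_max = 4, density_scale = 1000,
                            noise_cv = 0.15, background_mfi = 90) {
  secondary <- match.arg(secondary)
  stopifnot(alpha > 0, amp_max >= 1, density_scale > 0,
            noise_cv >= 0, background_mfi >= 0)
  structure(list(secondary = secondary, alpha = alpha, amp_max = amp_max,
                 density_scale = density_scale, noise_cv = noise_cv,
                 background_mfi = background_mfi),
            class = "detection_model")
}

#' Detection gain at a bound density
#'
#' @param density Non-negative numeric vector of bound IgG densities.
#' @param model A [detection_model()].
#' @return Numeric gain; identically 1 for the monoclonal secondary.
#' @export
amp_gain <- function(density, model) {
  if (model$secondary == "FcMonoIgG") {
    rep(1, length(density))
  } else {
    1 + (model$amp_max - 1) * exp(-density / model$density_scale)
  }
}

#' Simulate raw trimmed-mean MFI readings
#'
#' Mean signal is `background + alpha * g(D) * D`, multiplied by lognormal
#' noise with the model's coefficient of variation (unit mean), clipped at
#' zero. Uses the current RNG stream.
#'
#' @param density Non-negative numeric vector of bound densities.
#' @param model A [detection_model()].
#' @return Numeric vector of raw trimmed-mean MFI values.
#' @export
detect <- function(density, model) {
  stopifnot(all(density >= 0))
  mean_sig <- model$background_mfi + model$alpha * amp_gain(density, model) * density
  pmax(0, mean_sig * lognormal_noise(length(density), model$noise_cv))
}

# Unit-mean multiplicative lognormal noise at a given CV.
lognormal_noise <- function(n, cv) {
  if (cv <= 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# True mean background components; their sum equals the detection model's
# background so that the normalization formula (PBS, then NC, then mean NGS)
# centres blank beads at zero.
sim_background_parts <- function(background_mfi) {
  c(pbs = background_mfi * 20 / 90, nc = background_mfi * 25 / 90,
    ngs = background_mfi * 45 / 90)
}

sim_controls <- function(panel, model) {
  beads <- panel$bead_id
  parts <- sim_background_parts(model$background_mfi)
  n <- length(beads)
  tibble::tibble(
    bead_id = beads,
    pbs = parts["pbs"] * lognormal_noise(n, model$noise_cv),
    nc = parts["nc"] * lognormal_noise(n, model$noise_cv),
    ngs_ls = parts["ngs"] * lognormal_noise(n, model$noise_cv),
    ngs_lc = parts["ngs"] * lognormal_noise(n, model$noise_cv)
  )
}

#' Default simulated study configuration
#'
#' The study conditions the simulator emulates: both bundled class-I vendor
#' panels, both secondary antibodies, and a small cohort of serum
#' archetypes chosen to span the reactivity patterns the assay
#' distinguishes. The archetypes are:
#' \describe{
#'   \item{anti_denatured}{one low-titer clone against the shared epitopes
#'     of beta2-microglobulin-free heavy chain, broad across class-I beads
#'     (reactive on the vendor panel that carries free heavy chain, silent
#'     on the one that does not);}
#'   \item{dual_strong}{high-titer native clones against several antigens
#'     common to both panels;}
#'   \item{weak_native}{low-titer native clones against a few antigens;}
#'   \item{nonreactive}{no clones.}
#' }
#'
#' @param n_breadth Breadth of the anti-denatured clone's allele set.
#' @param seed Seed used to pick clone target alleles (compositions and
#'   readings are drawn later, under [simulate_experiment()]'s seed).
#' @return A config list with elements `panels`, `sera` (named list of
#'   clone tables), `models` (per secondary) and `cutoff`/`dilution`.
#' @export
default_sim_config <- function(n_breadth = 20, seed = 100) {
  ls <- reference_panel("LS")
  lc <- reference_panel("LC")
  common <- common_alleles(ls, lc)
  with_local_seed(seed, {
    breadth <- sample(common$bead, n_breadth)
    strong_targets <- sample(common$bead, 8)
    weak_targets <- sample(common$bead, 3)
    list(
      panels = list(LS = ls, LC = lc),
      sera = list(
        anti_denatured = serum_clone("b2m_free", breadth, 500),
        dual_strong = dplyr::bind_rows(
          lapply(strong_targets, function(a) serum_clone("native", a, 12000))),
        weak_native = dplyr::bind_rows(
          lapply(weak_targets, function(a) serum_clone("native", a, 1500))),
        nonreactive = serum_clone("native", "A*01:01", 0)[0, ]
      ),
      models = list(
        FcMonoIgG = detection_model("FcMonoIgG"),
        IgHPolyFab = detection_model("IgHPolyFab")
      ),
      cutoff = 500, dilution = 0.1
    )
  })
}

#' Simulate the full two-panel, two-secondary experiment
#'
#' Draws bead compositions for each vendor panel, computes per-bead bound
#' IgG densities for every serum, and generates raw trimmed-mean readings
#' under both detection models, plus control tables. Optionally writes the
#' raw/control CSV files consumed by [read_raw_csv()], [read_controls_csv()]
#' and [run_pipeline()], together with the ground truth.
#'
#' @param config A configuration list as returned by [default_sim_config()].
#' @param seed Integer seed; identical config and seed reproduce identical
#'   output.
#' @param outdir Optional directory to write `raw_<serum>_<vendor>_
#'   <secondary>.csv`, `controls_<vendor>.csv` and `truth.json` into.
#' @return A list of class `sab_simulation`: `raw` (tibble of readings for
#'   every serum x vendor x secondary, nested per condition), `controls`
#'   (per vendor), `truth` (compositions, densities, clone tables, seed) and
#'   the `config`.
#' @export
simulate_experiment <- function(config = default_sim_config(), seed = 1,
                                outdir = NULL) {
  out <- with_local_seed(seed, {
    compositions <- lapply(config$panels, make_vendor_composition)
    controls <- lapply(names(config$panels), function(v) {
      sim_controls(config$panels[[v]], config$models[[1]])
    })
    names(controls) <- names(config$panels)
    densities <- lapply(names(config$sera), function(s) {
      lapply(names(config$panels), function(v) {
        d <- bound_density(config$sera[[s]], compositions[[v]])
        tibble::tibble(serum_id = s, vendor = v, d)
      })
    })
    densities <- dplyr::bind_rows(unlist(densities, recursive = FALSE))
    raw <- dplyr::bind_rows(lapply(names(config$models), function(sec) {
      model <- config$models[[sec]]
      dplyr::mutate(densities, secondary = sec,
                    trimmed_mean = detect(.data$density, model),
                    bead_count = 95L + as.integer(round(10 * runif(dplyr::n()))))
    }))
    # control beads are read too: background-only signal per run
    ctrl_rows <- dplyr::bind_rows(lapply(names(config$panels), function(v) {
      panel <- config$panels[[v]]
      ctl <- panel[panel$control != "none", ]
      dplyr::bind_rows(lapply(names(config$sera), function(s) {
        dplyr::bind_rows(lapply(names(config$models), function(sec) {
          model <- config$models[[sec]]
          tibble::tibble(serum_id = s, vendor = v, bead_id = ctl$bead_id,
                         bead = NA_character_, density = 0, secondary = sec,
                         trimmed_mean = detect(rep(0, nrow(ctl)), model),
                         bead_count = 100L)
        }))
      }))
    }))
    list(raw = dplyr::bind_rows(raw, ctrl_rows), controls = controls,
         truth = list(compositions = compositions, densities = densities,
                      sera = config$sera, seed = seed))
  })
  out$config <- config
  class(out) <- "sab_simulation"
  if (!is.null(outdir)) {
    write_simulation(out, outdir)
  }
  out
}

#' @export
print.sab_simulation <- function(x, ...) {
  cat(sprintf("<sab_simulation> %d sera x %d panels x %d secondaries, seed %d\n",
              length(x$config$sera), length(x$config$panels),
              length(x$config$models), x$truth$seed))
  invisible(x)
}

#' Run the normalization stage over a whole simulation
#'
#' Normalizes every (serum, vendor, secondary) run of a simulation into a
#' `serum_profile`, and assembles per-serum [condition_quartet()]s.
#'
#' @param sim A [simulate_experiment()] result.
#' @return A list with `profiles` (list of `serum_profile`, named
#'   serum.vendor.secondary) and `quartets` (named by serum).
#' @export
normalize_simulation <- function(sim) {
  cfg <- sim$config
  runs <- unique(sim$raw[c("serum_id", "vendor", "secondary")])
  profiles <- purrr::pmap(runs, function(serum_id, vendor, secondary) {
    raw <- sim$raw[sim$raw$serum_id == serum_id & sim$raw$vendor == vendor &
                     sim$raw$secondary == secondary,
                   c("bead_id", "trimmed_mean", "bead_count")]
    normalize_profile(raw, sim$controls[[vendor]], cfg$panels[[vendor]],
                      serum_id = serum_id, secondary = secondary,
                      cutoff = cfg$cutoff, dilution = cfg$dilution)
  })
  names(profiles) <- paste(runs$serum_id, runs$vendor, runs$secondary, sep = ".")
  quartets <- lapply(unique(runs$serum_id), function(s) {
    condition_quartet(profiles[runs$serum_id == s],
                      cfg$panels$LS, cfg$panels$LC)
  })
  names(quartets) <- unique(runs$serum_id)
  list(profiles = profiles, quartets = quartets)
}
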