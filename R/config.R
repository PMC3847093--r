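#' Fluorophore photophysical parameters
#'
#' Bundles the per-dye constants used for photon accounting: molar extinction
#' coefficient, fluorescence quantum yield, detection-path efficiency and the
#' Forster radius of the donor/acceptor pair.
#'
#' Defaults mirror the HiLyteFluor 555 / HiLyteFluor 647 labels used for
#' Abeta40 and Abeta42 respectively: extinction coefficients of 150,000 and
#' 250,000 M^-1 cm^-1 and a pair Forster radius of 5.3 nm. Quantum yields and
#' detection efficiencies are setup-dependent and therefore configurable.
#'
#' @param name Dye label.
#' @param extinction Molar extinction coefficient (M^-1 cm^-1).
#' @param quantum_yield Fluorescence quantum yield, in (0, 1].
#' @param detection_efficiency Fraction of emitted photons detected, in (0, 1].
#' @param R0_nm Forster radius of the FRET pair this dye belongs to (nm).
#' @return A list of class `fluorophore`.
#' @export
#' @examples
#' fluorophore("HL555", 150000, 0.25, 0.35)
fluorophore <- function(name, extinction, quantum_yield, detection_efficiency,
                        R0_nm = 5.3) {
  stopifnot(extinction > 0, R0_nm > 0)
  if (quantum_yield <= 0 || quantum_yield > 1) {
    abort("`quantum_yield` must be in (0, 1].")
  }
  if (detection_efficiency <= 0 || detection_efficiency > 1) {
    abort("`detection_efficiency` must be in (0, 1].")
  }
  structure(
    list(
      name = name, extinction = extinction, quantum_yield = quantum_yield,
      detection_efficiency = detection_efficiency, R0_nm = R0_nm
    ),
    class = "fluorophore"
  )
}

#' Default donor (Abeta40-HL555) fluorophore parameters
#' @return A `fluorophore` object.
#' @export
hl555 <- function() fluorophore("HL555", 150000, 0.25, 0.35, 5.3)

#' Default acceptor (Abeta42-HL647) fluorophore parameters
#' @return A `fluorophore` object.
#' @export
hl647 <- function() fluorophore("HL647", 250000, 0.30, 0.35, 5.3)

#' Expand a heterogeneous size distribution into a (n40, n42) composition table
#'
#' A heterogeneous oligomer of total size `s` contains at least one monomer of
#' each peptide; the remaining `s - 2` monomers are assigned to Abeta40
#' independently with probability `p40`. This turns a marginal total-size
#' distribution into an explicit discrete distribution over compositions.
#'
#' @param size_probs Named numeric vector: names are total sizes (>= 2),
#'   values are probabilities summing to 1.
#' @param p40 Probability that a non-obligatory monomer is Abeta40.
#' @return A tibble with columns `n40`, `n42`, `prob`.
#' @export
#' @examples
#' hetero_composition(c(`2` = 0.5, `3` = 0.5), p40 = 0.5)
hetero_composition <- function(size_probs, p40 = 0.5) {
  sizes <- as.integer(names(size_probs))
  stopifnot(all(sizes >= 2), abs(sum(size_probs) - 1) < 1e-8,
            p40 >= 0, p40 <= 1)
  rows <- purrr::map2_dfr(sizes, as.numeric(size_probs), function(s, p) {
    k <- 0:(s - 2)          # extra Abeta40 monomers beyond the obligatory one
    tibble(
      n40 = 1L + k,
      n42 = s - 1L - k,
      prob = p * stats::dbinom(k, s - 2, p40)
    )
  })
  rows <- dplyr::filter(rows, .data$prob > 0)
  rows$prob <- rows$prob / sum(rows$prob)
  rows
}

# Size-distribution anchors for the two incubation timepoints. Homogeneous
# species are mainly dimeric with <10% of peptide above tetramer; mixed
# (heterogeneous) species peak at trimer/tetramer with ~5% dimers and ~20%
# heptamer-or-larger at 10 min, shifting modestly larger (and more
# Abeta42-rich) by 48 h.
#' Default per-class composition tables for a study timepoint
#'
#' @param timepoint `"10min"` or `"48h"`.
#' @return Named list of tibbles (`hom40`, `hom42`, `hetero`, `coloc_noFRET`),
#'   each with columns `n40`, `n42`, `prob`.
#' @export
default_composition_tables <- function(timepoint = c("10min", "48h")) {
  timepoint <- match.arg(timepoint)
  hom40 <- tibble(n40 = 1:4, n42 = 0L, prob = c(0.25, 0.45, 0.20, 0.10))
  coloc <- tibble(n40 = c(1L, 2L, 1L), n42 = c(1L, 1L, 2L),
                  prob = c(0.50, 0.25, 0.25))
  if (timepoint == "10min") {
    hom42 <- tibble(n40 = 0L, n42 = 1:4, prob = c(0.20, 0.45, 0.22, 0.13))
    hetero <- hetero_composition(
      c(`2` = 0.05, `3` = 0.25, `4` = 0.22, `5` = 0.15, `6` = 0.13,
        `7` = 0.08, `8` = 0.06, `9` = 0.04, `10` = 0.02),
      p40 = 0.55
    )
  } else {
    hom42 <- tibble(n40 = 0L, n42 = 1:5, prob = c(0.15, 0.44, 0.24, 0.14, 0.03))
    hetero <- hetero_composition(
      c(`2` = 0.04, `3` = 0.18, `4` = 0.20, `5` = 0.16, `6` = 0.14,
        `7` = 0.10, `8` = 0.08, `9` = 0.06, `10` = 0.04),
      p40 = 0.40
    )
  }
  list(hom40 = hom40, hom42 = hom42, hetero = hetero, coloc_noFRET = coloc)
}

#' Build a simulation configuration
#'
#' Collects every knob of the synthetic-field generator: image geometry, point
#' spread function, per-monomer photon budgets, membrane quenching,
#' intra-oligomer FRET, species densities and compositions, autofluorescent
#' impostors, background, fluorescence lifetimes and TCSPC binning.
#'
#' Defaults describe the study conditions: 125 nm pixels (a 12-px ROI spans
#' ~1.5 um), a 110 nm isotropic Gaussian PSF, quench factors equal to the
#' bound/free lifetime ratios (0.48/0.75 and 1.24/1.56), FRET efficiency 0.5
#' inside mixed oligomers, and lifetimes of 0.48 ns (bound Abeta40-HL555),
#' 1.24 ns (bound Abeta42-HL647) and 0.58 ns (autofluorescence).
#'
#' @param image_size_px Integer pair, image height/width in pixels.
#' @param pixel_nm Pixel pitch in nm.
#' @param psf_sigma_nm PSF standard deviation in nm.
#' @param photons_per_monomer Nested list: fluorophore -> channel -> expected
#'   detected photons per unquenched monomer.
#' @param quench_factor_40,quench_factor_42 Membrane quench factors in (0, 1];
#'   `NULL` derives them from `lifetimes_ns` as bound/free ratios.
#' @param fret_efficiency FRET efficiency applied inside heterogeneous
#'   oligomers, in \[0, 1\].
#' @param species_densities Named numeric, spots per 100 um of neurite for
#'   classes `hom40`, `hom42`, `hetero`, `coloc_noFRET`.
#' @param composition_tables Named list of composition tibbles, see
#'   [default_composition_tables()].
#' @param autofluorescence List with `density` (per 100 um neurite, placed
#'   uniformly over the field), `lifetime_ns` and `brightness` (expected DD
#'   photons).
#' @param background_rate Background photons per pixel per channel.
#' @param lifetimes_ns Named numeric with entries `ab40_free`, `ab40_bound`,
#'   `ab42_free`, `ab42_bound`, `autofluorescence` (ns).
#' @param decay_window_ns,decay_bin_ns TCSPC window and bin width (ns).
#' @param neurite List with `width_um`, `target_length_um`, `step_um`,
#'   `heading_sd` controlling the simulated neurite polyline.
#' @param crosstalk List with generator-side `alpha_bleed` (donor emission
#'   detected in DA) and `delta_direct` (direct acceptor excitation at 532 nm).
#' @param donor,acceptor [fluorophore()] parameter sets.
#' @param noise Logical; apply Poisson shot noise (disable for photon-
#'   conservation diagnostics).
#' @param seed Default integer seed.
#' @return A list of class `sim_config`, validated.
#' @export
sim_config <- function(image_size_px = c(512L, 512L),
                       pixel_nm = 125,
                       psf_sigma_nm = 110,
                       photons_per_monomer = list(ab40 = list(DD = 1000),
                                                  ab42 = list(AA = 1000)),
                       quench_factor_40 = NULL,
                       quench_factor_42 = NULL,
                       fret_efficiency = 0.5,
                       species_densities = c(hom40 = 29.5, hom42 = 49.5,
                                             hetero = 17.5,
                                             coloc_noFRET = 3) / 3.5,
                       composition_tables = default_composition_tables("10min"),
                       autofluorescence = list(density = 2.9,
                                               lifetime_ns = 0.58,
                                               brightness = 2000),
                       background_rate = 5,
                       lifetimes_ns = c(ab40_free = 0.75, ab40_bound = 0.48,
                                        ab42_free = 1.56, ab42_bound = 1.24,
                                        autofluorescence = 0.58),
                       decay_window_ns = 12.5,
                       decay_bin_ns = 0.05,
                       neurite = list(width_um = 1.5, target_length_um = 350,
                                      step_um = 2, heading_sd = 0.35),
                       crosstalk = list(alpha_bleed = 0, delta_direct = 0),
                       donor = hl555(),
                       acceptor = hl647(),
                       noise = TRUE,
                       seed = 1L) {
  quench_factor_40 <- quench_factor_40 %||%
    (lifetimes_ns[["ab40_bound"]] / lifetimes_ns[["ab40_free"]])
  quench_factor_42 <- quench_factor_42 %||%
    (lifetimes_ns[["ab42_bound"]] / lifetimes_ns[["ab42_free"]])
  cfg <- structure(
    list(
      image_size_px = as.integer(image_size_px),
      pixel_nm = pixel_nm,
      psf_sigma_nm = psf_sigma_nm,
      photons_per_monomer = photons_per_monomer,
      quench_factor_40 = quench_factor_40,
      quench_factor_42 = quench_factor_42,
      fret_efficiency = fret_efficiency,
      species_densities = species_densities,
      composition_tables = composition_tables,
      autofluorescence = autofluorescence,
      background_rate = background_rate,
      lifetimes_ns = lifetimes_ns,
      decay_window_ns = decay_window_ns,
      decay_bin_ns = decay_bin_ns,
      neurite = neurite,
      crosstalk = crosstalk,
      donor = donor,
      acceptor = acceptor,
      noise = noise,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants: non-negative densities, composition
#' probabilities summing to 1, quench factors in (0, 1], positive pixel pitch
#' and decay binning consistent with the window.
#'
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly unchanged, or an error.
#' @export
validate_sim_config <- function(cfg) {
  if (!inherits(cfg, "sim_config")) abort("`cfg` must be a `sim_config`.")
  if (length(cfg$image_size_px) != 2 || any(cfg$image_size_px < 32)) {
    abort("`image_size_px` must be two integers >= 32.")
  }
  if (cfg$pixel_nm <= 0) abort("`pixel_nm` must be > 0.")
  if (cfg$psf_sigma_nm <= 0) abort("`psf_sigma_nm` must be > 0.")
  if (any(cfg$species_densities < 0) || cfg$autofluorescence$density < 0) {
    abort("All species densities must be >= 0.")
  }
  for (q in c(cfg$quench_factor_40, cfg$quench_factor_42)) {
    if (q <= 0 || q > 1) abort("Quench factors must lie in (0, 1].")
  }
  if (cfg$fret_efficiency < 0 || cfg$fret_efficiency > 1) {
    abort("`fret_efficiency` must lie in [0, 1].")
  }
  for (cls in names(cfg$composition_tables)) {
    tab <- cfg$composition_tables[[cls]]
    if (abs(sum(tab$prob) - 1) > 1e-8) {
      abort(paste0("Composition probabilities for `", cls,
                   "` must sum to 1."))
    }
    if (any(tab$n40 < 0) || any(tab$n42 < 0)) {
      abort("Composition monomer counts must be >= 0.")
    }
  }
  if (cfg$decay_bin_ns <= 0 || cfg$decay_window_ns <= cfg$decay_bin_ns) {
    abort("Decay window must exceed the bin width, both > 0.")
  }
  if (any(cfg$lifetimes_ns <= 0)) abort("All lifetimes must be > 0.")
  invisible(cfg)
}

#' Canonical study-condition configurations
#'
#' Returns the generator configuration for one of the two incubation
#' timepoints of the mixed 1:1 Abeta40:Abeta42 experiment. Class weights are
#' chosen so that on a ~350 um neurite a field holds ~100 spots with the
#' reported species structure: at 10 min, 35% of Abeta40-containing spots and
#' 25% of Abeta42-containing spots are heterogeneous (FRET-positive) and <10%
#' of either peptide's spots are colocalized without FRET; by 48 h the
#' heterogeneous share of Abeta40 rises to 45% while the total number of
#' Abeta40 spots is unchanged and Abeta42 spots increase.
#'
#' @param timepoint `"10min"` or `"48h"`.
#' @param coloc_fraction Optional override: set the coloc-no-FRET class so
#'   that it makes up this fraction of the scarcer peptide's spots (i.e. the
#'   larger of the two per-peptide coloc shares equals `coloc_fraction`;
#'   chance overlaps at field density come on top of it).
#' @param ... Further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
study_config <- function(timepoint = c("10min", "48h"), coloc_fraction = NULL,
                         composition_tables = NULL, ...) {
  timepoint <- match.arg(timepoint)
  weights <- if (timepoint == "10min") {
    c(hom40 = 29.5, hom42 = 49.5, hetero = 17.5, coloc_noFRET = 3)
  } else {
    c(hom40 = 24.5, hom42 = 64.5, hetero = 22.5, coloc_noFRET = 3)
  }
  if (!is.null(coloc_fraction)) {
    # Abeta40 is the scarcer peptide in both compositions: solve
    # c / (hom40 + hetero + c) = coloc_fraction
    weights["coloc_noFRET"] <- coloc_fraction / (1 - coloc_fraction) *
      (weights[["hom40"]] + weights[["hetero"]])
  }
  sim_config(
    species_densities = weights / 3.5,
    composition_tables = composition_tables %||%
      default_composition_tables(timepoint),
    ...
  )
}

#' Address a configuration field by dotted key
#'
#' @param cfg A `sim_config` (or plain nested list).
#' @param key Dotted path, e.g. `"autofluorescence.lifetime_ns"`.
#' @return The addressed value; errors if the path does not resolve.
#' @export
#' @examples
#' config_get(sim_config(), "neurite.width_um")
config_get <- function(cfg, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  out <- cfg
  for (p in parts) {
    if (is.null(out[[p]])) abort(paste0("No config field `", key, "`."))
    out <- out[[p]]
  }
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  field:", paste(x$image_size_px, collapse = " x "), "px @",
      x$pixel_nm, "nm/px\n")
  cat("  densities (per 100 um):",
      paste(sprintf("%s=%.2f", names(x$species_densities),
                    x$species_densities), collapse = ", "), "\n")
  cat("  quench:", round(x$quench_factor_40, 4), "/",
      round(x$quench_factor_42, 4), " FRET E:", x$fret_efficiency, "\n")
  invisible(x)
}
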