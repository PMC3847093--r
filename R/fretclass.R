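#' Sensitized acceptor emission
#'
#' Isolates the FRET signal in the DA channel by removing donor bleed-through
#' (`alpha_bleed * I_dd`) and direct acceptor excitation at the donor
#' wavelength (`delta_direct * I_aa`), flooring the result at zero. The
#' crosstalk coefficients are calibrated on donor-only and acceptor-only
#' control fields, see [estimate_crosstalk()].
#'
#' @param I_da,I_dd,I_aa Background-subtracted integrated counts.
#' @param alpha_bleed Donor bleed-through coefficient.
#' @param delta_direct Direct-excitation coefficient.
#' @return Sensitized emission counts (>= 0), vectorized.
#' @export
#' @examples
#' sensitized_emission(100, 1000, 0, alpha_bleed = 0.1)  # pure bleed-through
sensitized_emission <- function(I_da, I_dd, I_aa, alpha_bleed = 0,
                                delta_direct = 0) {
  pmax(I_da - alpha_bleed * I_dd - delta_direct * I_aa, 0)
}

#' Total donor-excitation events corrected for FRET losses
#'
#' Inside a heterogeneous oligomer the donor's emission is partly lost to
#' energy transfer, so its DD intensity underestimates the Abeta40 content.
#' Collecting the photons emitted from both donor and acceptor under donor
#' excitation and correcting each path for quantum yield and detection
#' efficiency recovers the total number of donor excitation events:
#' `I_dd / (phi_D eta_D) + F_sens / (phi_A eta_A)`.
#'
#' @param I_dd Background-subtracted donor-channel counts.
#' @param F_sens Sensitized emission from [sensitized_emission()].
#' @param donor,acceptor [fluorophore()] parameter sets.
#' @return Donor-equivalent counts (excitation events).
#' @export
corrected_donor_counts <- function(I_dd, F_sens, donor = hl555(),
                                   acceptor = hl647()) {
  dphi <- donor$quantum_yield * donor$detection_efficiency
  aphi <- acceptor$quantum_yield * acceptor$detection_efficiency
  if (dphi <= 0 || aphi <= 0) {
    abort("Quantum yields and detection efficiencies must be > 0.")
  }
  I_dd / dphi + F_sens / aphi
}

#' Forster relation: FRET efficiency versus dye separation
#'
#' `E = 1 / (1 + (r / R0)^6)`; equals 0.5 at the Forster radius and decreases
#' steeply (sixth power) with distance, which is what makes single-molecule
#' FRET a nanometre-scale proximity reporter.
#'
#' @param r_nm Donor-acceptor distance (nm), >= 0.
#' @param R0_nm Forster radius (nm); 5.3 nm for the HL555/HL647 pair.
#' @return Efficiency in (0, 1].
#' @export
#' @examples
#' fret_efficiency_distance(5.3, 5.3)  # 0.5 at r = R0
fret_efficiency_distance <- function(r_nm, R0_nm = 5.3) {
  if (any(r_nm < 0) || any(R0_nm <= 0)) {
    abort("Need r_nm >= 0 and R0_nm > 0.")
  }
  1 / (1 + (r_nm / R0_nm)^6)
}

#' Estimate crosstalk coefficients from single-label control fields
#'
#' Donor bleed-through (`alpha_bleed`) is the zero-intercept regression slope
#' of DA on DD intensity over donor-only spots; direct acceptor excitation
#' (`delta_direct`) is the slope of DA on AA over acceptor-only spots.
#'
#' @param spots_donor_only,spots_acceptor_only Measured spot tibbles from
#'   control fields (columns `I_dd`, `I_da`, `I_aa`).
#' @return List with `alpha_bleed` and `delta_direct`.
#' @export
estimate_crosstalk <- function(spots_donor_only, spots_acceptor_only) {
  slope0 <- function(y, x) {
    if (length(x) == 0 || sum(x^2) == 0) return(0)
    max(sum(x * y) / sum(x^2), 0)
  }
  list(
    alpha_bleed = slope0(spots_donor_only$I_da, spots_donor_only$I_dd),
    delta_direct = slope0(spots_acceptor_only$I_da, spots_acceptor_only$I_aa)
  )
}

#' Classify spots into the four oligomer species
#'
#' Each spot that has passed the neurite and autofluorescence gates is called
#' by channel presence: DD-only -> homogeneous Abeta40 (`hom40`); AA-only ->
#' homogeneous Abeta42 (`hom42`); DD and AA with significant sensitized DA
#' emission -> heterogeneous FRET-positive (`hetero`); DD and AA without
#' significant sensitized emission -> colocalized without FRET
#' (`coloc_noFRET`). A channel is "present" when its background-subtracted
#' intensity exceeds `k_sigma` times the channel's background standard
#' deviation. DA-only spots (no DD, no AA) are anomalous and flagged `NA`.
#'
#' Colocalization is established upstream: detections from the DD and AA
#' images closer than the colocalization radius are merged into a single spot
#' record before measurement (see [analyze_field()]), so a single row here
#' carries both channels' intensities.
#'
#' @param spots Measured spot tibble (`I_dd`, `I_da`, `I_aa`, `bg_dd`,
#'   `bg_da`, `bg_aa`). When detection-provenance columns `det_dd`/`det_aa`
#'   are present (as produced by [analyze_field()]'s channel merge), channel
#'   presence additionally requires a detection in that channel within the
#'   colocalization radius — ROI-integrated intensity alone would declare
#'   "colocalization" at the 1.5-um ROI scale rather than the diffraction
#'   limit.
#' @param thresholds Optional list with absolute per-channel significance
#'   thresholds `sd_dd`, `sd_da`, `sd_aa` (counts). Default estimates each as
#'   `sqrt(2 * bg_total)`, the Poisson s.d. of a background-subtracted ROI
#'   total.
#' @param k_sigma Significance multiple.
#' @param alpha_bleed,delta_direct Crosstalk coefficients for
#'   [sensitized_emission()].
#' @return `spots` with columns `class`, `F_sens`, `sig_dd`, `sig_da`,
#'   `sig_aa` added.
#' @export
classify_species <- function(spots, thresholds = NULL, k_sigma = 3,
                             alpha_bleed = 0, delta_direct = 0) {
  if (nrow(spots) == 0) {
    return(dplyr::mutate(spots, class = character(0), F_sens = numeric(0),
                         sig_dd = logical(0), sig_da = logical(0),
                         sig_aa = logical(0)))
  }
  sd_dd <- thresholds$sd_dd %||% sqrt(2 * pmax(spots$bg_dd, 1))
  sd_da <- thresholds$sd_da %||% sqrt(2 * pmax(spots$bg_da, 1))
  sd_aa <- thresholds$sd_aa %||% sqrt(2 * pmax(spots$bg_aa, 1))
  f_sens <- sensitized_emission(spots$I_da, spots$I_dd, spots$I_aa,
                                alpha_bleed, delta_direct)
  sig_dd <- spots$I_dd > k_sigma * sd_dd
  sig_aa <- spots$I_aa > k_sigma * sd_aa
  sig_da <- f_sens > k_sigma * sd_da
  if (all(c("det_dd", "det_aa") %in% names(spots))) {
    sig_dd <- sig_dd & spots$det_dd
    sig_aa <- sig_aa & spots$det_aa
  }
  cls <- dplyr::case_when(
    sig_dd & sig_aa & sig_da ~ "hetero",
    sig_dd & sig_aa ~ "coloc_noFRET",
    sig_dd & !sig_aa ~ "hom40",
    !sig_dd & sig_aa ~ "hom42",
    TRUE ~ NA_character_  # DA-only or empty ROI: anomalous, excluded
  )
  dplyr::mutate(spots, class = cls, F_sens = f_sens,
                sig_dd = sig_dd, sig_da = sig_da, sig_aa = sig_aa)
}

#' Size classified oligomers in real monomer equivalents
#'
#' Abeta42 content is always sized from the AA channel (direct 635 nm
#' excitation, unaffected by FRET). Abeta40 content is sized from the DD
#' channel for homogeneous and non-FRET spots; for heterogeneous
#' (FRET-positive) spots the donor intensity is first corrected with
#' [corrected_donor_counts()], without which the donor size would be
#' underestimated by the FRET efficiency. Both are converted to monomer
#' equivalents with the calibration slopes and quench factors, then rounded
#' with [integer_size()].
#'
#' @param spots Classified spot tibble from [classify_species()].
#' @param calib A `calibration_result`.
#' @param donor,acceptor [fluorophore()] parameter sets.
#' @return `spots` with `n40_real`, `n42_real`, `n40`, `n42`, `total_size`
#'   added.
#' @export
size_oligomers <- function(spots, calib, donor = hl555(), acceptor = hl647()) {
  if (nrow(spots) == 0) {
    return(dplyr::mutate(spots, n40_real = numeric(0), n42_real = numeric(0),
                         n40 = integer(0), n42 = integer(0),
                         total_size = integer(0)))
  }
  ipm40 <- calib$intensity_per_molecule[["ab40_DD"]]
  ipm42 <- calib$intensity_per_molecule[["ab42_AA"]]
  q40 <- calib$quench_factor[["ab40"]]
  q42 <- calib$quench_factor[["ab42"]]
  dphi <- donor$quantum_yield * donor$detection_efficiency

  has40 <- spots$class %in% c("hom40", "hetero", "coloc_noFRET")
  has42 <- spots$class %in% c("hom42", "hetero", "coloc_noFRET")

  n40_real <- rep(0, nrow(spots))
  hetero <- !is.na(spots$class) & spots$class == "hetero"
  plain40 <- !is.na(spots$class) & has40 & !hetero
  if (any(plain40)) {
    n40_real[plain40] <- monomer_equivalents(spots$I_dd[plain40], ipm40, q40)
  }
  if (any(hetero)) {
    d_tot <- corrected_donor_counts(spots$I_dd[hetero], spots$F_sens[hetero],
                                    donor, acceptor)
    n40_real[hetero] <- monomer_equivalents(d_tot * dphi, ipm40, q40)
  }
  n42_real <- rep(0, nrow(spots))
  idx42 <- !is.na(spots$class) & has42
  if (any(idx42)) {
    n42_real[idx42] <- monomer_equivalents(spots$I_aa[idx42], ipm42, q42)
  }
  dplyr::mutate(
    spots,
    n40_real = n40_real, n42_real = n42_real,
    n40 = integer_size(n40_real), n42 = integer_size(n42_real),
    total_size = .data$n40 + .data$n42
  )
}
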