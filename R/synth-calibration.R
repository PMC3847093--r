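#' Number of molecules in the confocal volume at a given concentration
#'
#' @param concentration_nM Solution concentration (nM).
#' @param volume_fL Effective confocal detection volume (femtolitres).
#' @return Expected molecule count (real).
#' @export
#' @examples
#' molecules_in_volume(1, 1)  # ~0.6 molecules per fL at 1 nM
molecules_in_volume <- function(concentration_nM, volume_fL = 1) {
  if (volume_fL <= 0) abort("`volume_fL` must be > 0.")
  concentration_nM * 1e-9 * 6.02214076e23 * volume_fL * 1e-15
}

#' Simulate a solution calibration series
#'
#' Emulates the intensity-vs-concentration measurement used to calibrate
#' intensity per molecule: below saturation, total emission from the confocal
#' volume is linear in the number of molecules present. Integrated intensity
#' is `response_per_molecule * molecules + background`, with optional Gaussian
#' measurement noise; zero concentration yields pure background.
#'
#' @param concentrations Strictly increasing, non-negative concentrations (nM).
#' @param response_per_molecule Detected counts per molecule.
#' @param volume_fL Confocal volume (fL) converting concentration to molecule
#'   count, see [molecules_in_volume()].
#' @param noise_sd Gaussian noise s.d. on each intensity (counts).
#' @param background Constant background counts added to every reading.
#' @param n_replicates Replicate readings per concentration.
#' @param seed Integer seed.
#' @return A tibble with columns `concentration`, `molecules`,
#'   `integrated_intensity`.
#' @export
generate_calibration_series <- function(concentrations, response_per_molecule,
                                        volume_fL = 1, noise_sd = 0,
                                        background = 0, n_replicates = 1,
                                        seed = 1L) {
  if (any(concentrations < 0)) abort("Concentrations must be >= 0.")
  if (is.unsorted(concentrations, strictly = TRUE)) {
    abort("Concentrations must be strictly increasing.")
  }
  set.seed(as.integer(seed))
  grid <- tidyr::expand_grid(concentration = concentrations,
                             rep = seq_len(n_replicates))
  mol <- molecules_in_volume(grid$concentration, volume_fL)
  intensity <- response_per_molecule * mol + background +
    rnorm(nrow(grid), 0, noise_sd)
  tibble(concentration = grid$concentration, molecules = mol,
         integrated_intensity = intensity)
}
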