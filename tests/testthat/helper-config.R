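# Reduced-size study configuration for fast tests: 32 x 32 um field with a
# ~120 um neurite keeps the class structure of the full study conditions at
# roughly a third of the spots per field.
small_cfg <- function(timepoint = "10min",
                      image_size_px = c(256L, 256L),
                      neurite = list(width_um = 1.5, target_length_um = 120,
                                     step_um = 2, heading_sd = 0.35),
                      ...) {
  study_config(timepoint, image_size_px = image_size_px, neurite = neurite,
               ...)
}

# Single-species variants used for control-field tests
single_species_cfg <- function(class, density = 15, ...) {
  cfg <- small_cfg(...)
  d <- c(hom40 = 0, hom42 = 0, hetero = 0, coloc_noFRET = 0)
  d[class] <- density
  cfg$species_densities <- d
  cfg$autofluorescence$density <- 0
  cfg
}

# One rendered Gaussian spot on a blank image (noise-free), for detector and
# integration unit tests
render_single_spot <- function(dim = 64L, x = 31, y = 31, photons = 1280,
                               sigma_px = 0.88) {
  img <- matrix(0, dim, dim)
  smoligo:::add_gaussian_spot(img, x, y, photons, sigma_px)
}

expect_within_binomial_ci <- function(p_hat, p0, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(p_hat - p0), half + 1e-12)
}
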