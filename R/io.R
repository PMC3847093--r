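#' Write / read a field as single-channel 16-bit TIFFs
#'
#' One file per channel with suffixes `_DD.tif`, `_DA.tif`, `_AA.tif`, plus
#' the neurite mask as `_mask.tif` (0/255). Photon counts are stored as
#' 16-bit unsigned integers (values above 65535 are clipped).
#'
#' @param field A `field_bundle`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `write_field()` returns the written paths invisibly;
#'   `read_field()` returns a `field_bundle` (without polyline metadata).
#' @export
write_field <- function(field, dir, prefix = "field") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  to16 <- function(m) pmin(pmax(round(m), 0), 65535) / 65535
  paths <- file.path(dir, paste0(prefix, c("_DD.tif", "_DA.tif", "_AA.tif",
                                           "_mask.tif")))
  tiff::writeTIFF(to16(field$dd), paths[1], bits.per.sample = 16)
  tiff::writeTIFF(to16(field$da), paths[2], bits.per.sample = 16)
  tiff::writeTIFF(to16(field$aa), paths[3], bits.per.sample = 16)
  tiff::writeTIFF((field$mask > 0) * 255 / 65535, paths[4],
                  bits.per.sample = 16)
  invisible(paths)
}

#' @rdname write_field
#' @param pixel_nm Pixel pitch (nm), not stored in the TIFFs.
#' @export
read_field <- function(dir, prefix = "field", pixel_nm = 125) {
  from16 <- function(p) round(tiff::readTIFF(p) * 65535)
  mask <- from16(file.path(dir, paste0(prefix, "_mask.tif")))
  new_field_bundle(
    dd = from16(file.path(dir, paste0(prefix, "_DD.tif"))),
    da = from16(file.path(dir, paste0(prefix, "_DA.tif"))),
    aa = from16(file.path(dir, paste0(prefix, "_AA.tif"))),
    mask = matrix(as.integer(mask > 0), nrow(mask), ncol(mask)),
    pixel_nm = pixel_nm,
    neurite_length_um = NA_real_
  )
}

#' Write / read a ground-truth table as CSV
#'
#' Header: `id,x_px,y_px,class,n40,n42,lifetime_ns,on_neurite`.
#'
#' @param truth Ground-truth tibble from [generate_field()].
#' @param path File path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the tibble.
#' @export
write_ground_truth <- function(truth, path) {
  cols <- c("id", "x_px", "y_px", "class", "n40", "n42", "lifetime_ns",
            "on_neurite")
  utils::write.csv(truth[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Serialize / restore a simulation configuration as JSON
#'
#' Every configuration field is addressable by dotted key in the JSON
#' document (see [config_get()]).
#'
#' @param cfg A [sim_config()].
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  ser <- unclass(cfg)
  ser$donor <- unclass(ser$donor)
  ser$acceptor <- unclass(ser$acceptor)
  ser$species_densities <- as.list(ser$species_densities)
  ser$lifetimes_ns <- as.list(ser$lifetimes_ns)
  ser$composition_tables <- purrr::map(ser$composition_tables,
                                       ~ as.list(as.data.frame(.x)))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- purrr::map(raw$composition_tables, ~ as_tibble(as.data.frame(.x)))
  sim_config(
    image_size_px = raw$image_size_px,
    pixel_nm = raw$pixel_nm,
    psf_sigma_nm = raw$psf_sigma_nm,
    photons_per_monomer = raw$photons_per_monomer,
    quench_factor_40 = raw$quench_factor_40,
    quench_factor_42 = raw$quench_factor_42,
    fret_efficiency = raw$fret_efficiency,
    species_densities = unlist(raw$species_densities),
    composition_tables = comp,
    autofluorescence = raw$autofluorescence,
    background_rate = raw$background_rate,
    lifetimes_ns = unlist(raw$lifetimes_ns),
    decay_window_ns = raw$decay_window_ns,
    decay_bin_ns = raw$decay_bin_ns,
    neurite = raw$neurite,
    crosstalk = raw$crosstalk,
    donor = do.call(fluorophore, raw$donor),
    acceptor = do.call(fluorophore, raw$acceptor),
    noise = raw$noise,
    seed = raw$seed
  )
}
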