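#' Analyze one field end to end
#'
#' Runs the full quantification chain on a three-channel field: spot
#' detection on the DD and AA images (union, deduplicated at the
#' colocalization radius, so each physical particle yields one record),
#' 12x12-px ROI integration with adjacent-background subtraction in all
#' channels, the 500-nm neurite gate, per-spot TCSPC lifetime fitting with
#' the autofluorescence cutoff (donor-channel spots only), FRET species
#' classification, and quench-corrected monomer-equivalent sizing.
#'
#' Ground truth is used only to draw each spot's synthetic TCSPC decay (the
#' simulator stands in for the TCSPC hardware); it never informs detection,
#' classification or sizing.
#'
#' @param field A `field_bundle`.
#' @param truth Ground-truth tibble (for decay simulation).
#' @param calib A `calibration_result`.
#' @param cfg The [sim_config()] (pixel geometry, decay binning, fluorophore
#'   parameters).
#' @param seed Seed for the decay draws.
#' @param roi_px ROI width (px).
#' @param coloc_radius_nm Colocalization/deduplication radius (nm).
#' @param k_sigma Detection and channel-significance threshold.
#' @param max_dist_nm Neurite gate distance (nm).
#' @param cutoff_ns Autofluorescence lifetime gate (ns).
#' @param alpha_bleed,delta_direct Crosstalk coefficients.
#' @param verbose Emit per-stage counts as messages.
#' @return Tibble of retained spots with intensities, `dist_nm`, `tau_ns`,
#'   `autofluor`, `class`, `F_sens`, `n40_real`, `n42_real`, `n40`, `n42`,
#'   `total_size`. The attribute `"stage_counts"` records counts in/out per
#'   filter (detected, merged, neurite-kept, lifetime-kept, classified).
#' @export
analyze_field <- function(field, truth, calib, cfg, seed = 1L, roi_px = 12L,
                          coloc_radius_nm = 250, k_sigma = 3,
                          max_dist_nm = 500, cutoff_ns = 0.53,
                          alpha_bleed = 0, delta_direct = 0,
                          verbose = FALSE) {
  det_dd <- detect_spots(field$dd, k_sigma = k_sigma)
  det_aa <- detect_spots(field$aa, k_sigma = k_sigma)
  radius_px <- coloc_radius_nm / field$pixel_nm

  # one record per particle: DD detections seed the list; an AA detection
  # within the colocalization radius marks the record acceptor-positive,
  # otherwise it becomes an AA-only record
  merged <- det_dd
  merged$channel <- if (nrow(det_dd)) "DD" else character(0)
  merged$det_dd <- rep(TRUE, nrow(det_dd))
  merged$det_aa <- rep(FALSE, nrow(det_dd))
  if (nrow(det_aa) > 0) {
    for (i in seq_len(nrow(det_aa))) {
      if (nrow(merged) > 0) {
        d2 <- (merged$x_px - det_aa$x_px[i])^2 +
          (merged$y_px - det_aa$y_px[i])^2
        j <- which.min(d2)
      }
      if (nrow(merged) > 0 && d2[j] <= radius_px^2) {
        merged$det_aa[j] <- TRUE
      } else {
        merged <- dplyr::bind_rows(
          merged,
          dplyr::mutate(det_aa[i, ], channel = "AA", det_dd = FALSE,
                        det_aa = TRUE)
        )
      }
    }
  }
  n_detected <- nrow(det_dd) + nrow(det_aa)
  n_merged <- nrow(merged)

  meas <- measure_spots(field, merged, roi_px)
  meas$channel <- merged$channel
  meas$det_dd <- merged$det_dd
  meas$det_aa <- merged$det_aa
  meas <- dplyr::filter(meas, !.data$edge_flag)
  kept <- neurite_filter(meas, field$mask, max_dist_nm, field$pixel_nm)
  n_neurite <- nrow(kept)

  # FLIM gate on donor-channel spots: fit each spot's decay, drop spots whose
  # lifetime exceeds the cutoff (autofluorescence) or whose fit fails
  kept$tau_ns <- NA_real_
  kept$tau_stderr_ns <- NA_real_
  kept$converged <- TRUE   # spots without donor signal need no lifetime fit
  kept$autofluor <- FALSE
  # the lifetime gate mirrors the donor-channel (532 nm) autofluorescence
  # screen: only spots detected in DD are fitted; AA-only spots (bound
  # Abeta42, lifetime 1.24 ns > cutoff) are not subject to it
  dd_sig <- kept$det_dd & kept$I_dd > k_sigma * sqrt(2 * pmax(kept$bg_dd, 1))
  dd_idx <- which(dd_sig)
  if (length(dd_idx) > 0) {
    kept$converged[dd_idx] <- FALSE
    decays <- simulate_spot_decays(kept[dd_idx, ], truth, cfg, seed = seed)
    for (j in seq_along(dd_idx)) {
      d <- decays[[j]]
      if (is.null(d)) next
      f <- suppressWarnings(fit_lifetime(d))
      i <- dd_idx[j]
      kept$tau_ns[i] <- f$tau_ns
      kept$tau_stderr_ns[i] <- f$tau_stderr_ns
      kept$converged[i] <- f$converged
    }
    kept$autofluor <- kept$converged & !is.na(kept$tau_ns) &
      is_autofluorescence(kept$tau_ns, cutoff_ns)
    kept <- kept[!(dd_sig & (!kept$converged | kept$autofluor)), ]
  }
  n_lifetime <- nrow(kept)

  out <- classify_species(kept, k_sigma = k_sigma,
                          alpha_bleed = alpha_bleed,
                          delta_direct = delta_direct)
  out <- dplyr::filter(out, !is.na(.data$class))
  out <- size_oligomers(out, calib, cfg$donor, cfg$acceptor)
  n_classified <- nrow(out)

  counts <- c(detected = n_detected, merged = n_merged,
              neurite_kept = n_neurite, lifetime_kept = n_lifetime,
              classified = n_classified)
  if (verbose) {
    inform(paste0("stage counts: ",
                  paste(names(counts), counts, sep = "=", collapse = ", ")))
  }
  attr(out, "stage_counts") <- counts
  out
}

#' Simulate a calibration experiment matching a configuration
#'
#' Generates noisy solution calibration series for both dyes with responses
#' equal to the configured per-monomer photon budgets (solution species are
#' unquenched) and fits the calibration. Solution calibration runs at tens of
#' nM (tens of molecules in a 1-fL confocal volume); the sub-nM cell
#' incubation concentrations would average below one molecule per volume.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param concentrations Concentrations (nM).
#' @param noise_frac Gaussian noise s.d. as a fraction of the top intensity.
#' @return A `calibration_result`.
#' @export
simulate_calibration <- function(cfg, seed = 1L,
                                 concentrations = c(10, 25, 50, 75, 100),
                                 noise_frac = 0.02) {
  p40 <- cfg$photons_per_monomer$ab40$DD
  p42 <- cfg$photons_per_monomer$ab42$AA
  top <- molecules_in_volume(max(concentrations), 1)
  s40 <- generate_calibration_series(concentrations, p40, volume_fL = 1,
                                     noise_sd = noise_frac * top * p40,
                                     n_replicates = 3, seed = seed)
  s42 <- generate_calibration_series(concentrations, p42, volume_fL = 1,
                                     noise_sd = noise_frac * top * p42,
                                     n_replicates = 3, seed = seed + 1L)
  calibrate_from_series(s40, s42, cfg$lifetimes_ns)
}

#' Run a multi-field synthetic experiment
#'
#' Generates `n_fields` independent fields under one configuration,
#' calibrates (or accepts a calibration), and analyzes each field with
#' [analyze_field()]. All randomness derives from `seed`.
#'
#' @param cfg A [sim_config()].
#' @param n_fields Number of fields.
#' @param seed Root seed.
#' @param calib Optional `calibration_result`; default simulates and fits a
#'   calibration from the configuration.
#' @param on_crowded Crowding-check mode passed to [generate_field()]
#'   (default silent: the study densities intentionally exceed the
#'   conservative sparsity rule).
#' @param ... Passed to [analyze_field()].
#' @return Object of class `smol_experiment`: `spots` (classified spot
#'   tibble with `field` column), `truth` (pooled ground truth), `fields`
#'   (per-field seeds, neurite lengths, stage counts), `calib`, `cfg`.
#' @export
run_experiment <- function(cfg, n_fields = 10, seed = 1L, calib = NULL,
                           on_crowded = "silent", ...) {
  set.seed(as.integer(seed))
  field_seeds <- sample.int(.Machine$integer.max - 1, n_fields + 1)
  if (is.null(calib)) {
    calib <- simulate_calibration(cfg, seed = field_seeds[n_fields + 1])
  }
  res <- purrr::map(seq_len(n_fields), function(i) {
    sim <- generate_field(cfg, seed = field_seeds[i], on_crowded = on_crowded)
    spots <- analyze_field(sim$field, sim$truth, calib, cfg,
                           seed = field_seeds[i] %% 1000003L + 1L, ...)
    list(
      spots = dplyr::mutate(spots, field = i, .before = 1),
      truth = dplyr::mutate(sim$truth, field = i, .before = 1),
      info = tibble(field = i, seed = field_seeds[i],
                    neurite_length_um = sim$field$neurite_length_um,
                    !!!as.list(attr(spots, "stage_counts")))
    )
  })
  structure(
    list(
      spots = purrr::map_dfr(res, "spots"),
      truth = purrr::map_dfr(res, "truth"),
      fields = purrr::map_dfr(res, "info"),
      calib = calib,
      cfg = cfg
    ),
    class = "smol_experiment"
  )
}

#' @export
print.smol_experiment <- function(x, ...) {
  cat("<smol_experiment>", nrow(x$fields), "fields,",
      nrow(x$spots), "classified spots\n")
  print(dplyr::count(x$spots, .data$class))
  invisible(x)
}

#' Per-field and pooled species fractions of an experiment
#'
#' @param x A `smol_experiment`.
#' @return Tibble with per-field fractions plus, for each peptide/class, the
#'   across-field mean and s.d. in columns `mean_fraction`, `sd_fraction`.
#' @export
experiment_fractions <- function(x) {
  per_field <- x$spots |>
    dplyr::group_by(.data$field) |>
    dplyr::group_modify(~ species_fractions(.x)) |>
    dplyr::ungroup()
  per_field |>
    dplyr::group_by(.data$peptide, .data$class) |>
    dplyr::summarise(
      n_fields = dplyr::n(),
      mean_fraction = mean(.data$fraction),
      sd_fraction = sd(.data$fraction),
      n_spots = sum(.data$n),
      .groups = "drop"
    )
}

#' @export
glance.smol_experiment <- function(x, ...) {
  dens <- x$spots |>
    dplyr::left_join(dplyr::select(x$fields, "field", "neurite_length_um"),
                     by = "field") |>
    dplyr::group_by(.data$field) |>
    dplyr::summarise(
      n_spots = dplyr::n(),
      n_ab42 = sum(.data$class %in% c("hom42", "hetero", "coloc_noFRET")),
      length_um = dplyr::first(.data$neurite_length_um),
      .groups = "drop"
    )
  tibble(
    n_fields = nrow(x$fields),
    n_spots = nrow(x$spots),
    mean_density_ab42_per_100um =
      mean(density_per_100um(dens$n_ab42, dens$length_um)),
    mean_neurite_um = mean(x$fields$neurite_length_um)
  )
}

#' @export
tidy.smol_experiment <- function(x, ...) {
  experiment_fractions(x)
}
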