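#' Fit intensity per molecule from a solution calibration series
#'
#' Least-squares slope of integrated intensity against molecule count. The
#' molecule count per concentration comes from the `molecules` column when
#' present, otherwise from the configured confocal volume via
#' [molecules_in_volume()]. The intercept is reported but sizing uses the
#' slope only. When replicate readings are available the fit is weighted by
#' inverse Poisson variance (weight ~ 1/mean intensity); otherwise ordinary
#' least squares is used.
#'
#' @param series Data frame with columns `concentration`,
#'   `integrated_intensity` and optionally `molecules`.
#' @param volume_fL Confocal volume (fL) used when `molecules` is absent.
#' @return An object of class `ipm_fit` with elements `slope`, `stderr`,
#'   `intercept`, `n` and the underlying `lm` fit. [tidy()] and [glance()]
#'   methods are provided.
#' @export
#' @examples
#' s <- tibble::tibble(concentration = c(0, 1, 2),
#'                     molecules = c(0, 10, 20),
#'                     integrated_intensity = c(0, 1000, 2000))
#' fit_intensity_per_molecule(s)$slope
fit_intensity_per_molecule <- function(series, volume_fL = 1) {
  series <- as_tibble(series)
  if (!"molecules" %in% names(series)) {
    series$molecules <- molecules_in_volume(series$concentration, volume_fL)
  }
  if (dplyr::n_distinct(series$concentration) < 3) {
    abort("Need >= 3 distinct concentration points to fit a slope.")
  }
  means <- series |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(mi = mean(.data$integrated_intensity),
                     nrep = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$concentration)
  if (is.unsorted(means$mi, strictly = TRUE)) {
    abort(paste("Mean intensities are not monotone in concentration;",
                "saturation suspected. Drop saturated points and refit."))
  }
  if (any(means$nrep > 1)) {
    w <- 1 / pmax(means$mi[match(series$concentration, means$concentration)], 1)
    fit <- lm(integrated_intensity ~ molecules, data = series, weights = w)
  } else {
    fit <- lm(integrated_intensity ~ molecules, data = series)
  }
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
  structure(
    list(slope = unname(coef(fit)[["molecules"]]),
         stderr = unname(sm["molecules", "Std. Error"]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         n = nrow(series), fit = fit),
    class = "ipm_fit"
  )
}

#' @export
print.ipm_fit <- function(x, ...) {
  cat("<ipm_fit> intensity per molecule:", signif(x$slope, 6),
      "+/-", signif(x$stderr, 3), "counts/molecule (n =", x$n, ")\n")
  invisible(x)
}

#' @export
tidy.ipm_fit <- function(x, ...) {
  tibble(term = c("intercept", "intensity_per_molecule"),
         estimate = c(x$intercept, x$slope),
         std.error = c(suppressWarnings(summary(x$fit))$coefficients[1, 2], x$stderr))
}

#' @export
glance.ipm_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble(r.squared = s$r.squared, sigma = s$sigma, nobs = x$n)
}

#' Dynamic-quenching correction factor from lifetimes
#'
#' For dynamic quenching the intensity ratio of the quenched to the unquenched
#' fluorophore equals the ratio of its lifetimes, `I_q / I_0 = tau_q / tau_0`.
#' The membrane-bound/free lifetime ratio therefore converts the solution
#' calibration (intensity per molecule) to the membrane-bound setting.
#'
#' @param tau_q_ns Quenched (membrane-bound) lifetime (ns).
#' @param tau_0_ns Unquenched (free) lifetime (ns).
#' @return `tau_q_ns / tau_0_ns`.
#' @export
#' @examples
#' quench_factor(0.48, 0.75)  # Abeta40-HL555: 0.64
#' quench_factor(1.24, 1.56)  # Abeta42-HL647: ~0.795
quench_factor <- function(tau_q_ns, tau_0_ns) {
  if (any(tau_q_ns <= 0) || any(tau_0_ns <= 0)) {
    abort("Lifetimes must be > 0.")
  }
  tau_q_ns / tau_0_ns
}

#' Convert background-subtracted intensity to monomer equivalents
#'
#' Divides the integrated, background-subtracted spot intensity by the
#' quench-corrected intensity per molecule. The result is a real (possibly
#' fractional) monomer count; integer sizes are obtained downstream with
#' [integer_size()]. Negative intensities (background overshoot) are clamped
#' to zero and flagged in the `"clamped"` attribute.
#'
#' @param intensity_bg_subtracted Background-subtracted integrated counts.
#' @param intensity_per_molecule Calibration slope (counts/molecule), > 0.
#' @param quench Quench factor in (0, 1], see [quench_factor()].
#' @return Numeric vector of monomer equivalents, with attribute `clamped`.
#' @export
#' @examples
#' monomer_equivalents(1280, 1000, 0.64)  # 2 monomers
monomer_equivalents <- function(intensity_bg_subtracted,
                                intensity_per_molecule, quench = 1) {
  if (any(intensity_per_molecule <= 0)) {
    abort("`intensity_per_molecule` must be > 0.")
  }
  if (any(quench <= 0) || any(quench > 1)) {
    abort("`quench` must lie in (0, 1].")
  }
  clamped <- intensity_bg_subtracted < 0
  out <- pmax(intensity_bg_subtracted, 0) /
    (intensity_per_molecule * quench)
  attr(out, "clamped") <- clamped
  out
}

#' Assemble a calibration result from solution series and lifetimes
#'
#' Fits intensity per molecule for each peptide's detection channel (DD for
#' Abeta40-HL555, AA for Abeta42-HL647) and derives the membrane quench
#' factors from the bound/free lifetime ratios.
#'
#' @param series_ab40,series_ab42 Calibration tables as produced by
#'   [generate_calibration_series()] (or read from CSV).
#' @param lifetimes_ns Named numeric with `ab40_free`, `ab40_bound`,
#'   `ab42_free`, `ab42_bound` (ns).
#' @param volume_fL Confocal volume (fL) for concentration-to-molecules.
#' @return An object of class `calibration_result`: per-channel
#'   `intensity_per_molecule` and `slope_stderr`, lifetimes, and
#'   `quench_factor` per peptide.
#' @export
calibrate_from_series <- function(series_ab40, series_ab42,
                                  lifetimes_ns = c(ab40_free = 0.75,
                                                   ab40_bound = 0.48,
                                                   ab42_free = 1.56,
                                                   ab42_bound = 1.24),
                                  volume_fL = 1) {
  f40 <- fit_intensity_per_molecule(series_ab40, volume_fL)
  f42 <- fit_intensity_per_molecule(series_ab42, volume_fL)
  structure(
    list(
      intensity_per_molecule = c(ab40_DD = f40$slope, ab42_AA = f42$slope),
      slope_stderr = c(ab40_DD = f40$stderr, ab42_AA = f42$stderr),
      lifetimes_ns = lifetimes_ns,
      quench_factor = c(
        ab40 = quench_factor(lifetimes_ns[["ab40_bound"]],
                             lifetimes_ns[["ab40_free"]]),
        ab42 = quench_factor(lifetimes_ns[["ab42_bound"]],
                             lifetimes_ns[["ab42_free"]])
      )
    ),
    class = "calibration_result"
  )
}

#' Build a calibration result directly from known parameters
#'
#' Convenience constructor used when the intensity-per-molecule slopes are
#' known (e.g. from a previously saved calibration) rather than refit.
#'
#' @param ipm_ab40_DD,ipm_ab42_AA Intensity per molecule (counts/molecule).
#' @param lifetimes_ns As in [calibrate_from_series()].
#' @param slope_stderr Optional named stderr vector.
#' @return A `calibration_result`.
#' @export
calibration_result <- function(ipm_ab40_DD, ipm_ab42_AA,
                               lifetimes_ns = c(ab40_free = 0.75,
                                                ab40_bound = 0.48,
                                                ab42_free = 1.56,
                                                ab42_bound = 1.24),
                               slope_stderr = c(ab40_DD = NA_real_,
                                                ab42_AA = NA_real_)) {
  if (ipm_ab40_DD <= 0 || ipm_ab42_AA <= 0) {
    abort("Intensity per molecule must be > 0.")
  }
  structure(
    list(
      intensity_per_molecule = c(ab40_DD = ipm_ab40_DD, ab42_AA = ipm_ab42_AA),
      slope_stderr = slope_stderr,
      lifetimes_ns = lifetimes_ns,
      quench_factor = c(
        ab40 = quench_factor(lifetimes_ns[["ab40_bound"]],
                             lifetimes_ns[["ab40_free"]]),
        ab42 = quench_factor(lifetimes_ns[["ab42_bound"]],
                             lifetimes_ns[["ab42_free"]])
      )
    ),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat("  intensity/molecule: ab40_DD =",
      signif(x$intensity_per_molecule[["ab40_DD"]], 6), ", ab42_AA =",
      signif(x$intensity_per_molecule[["ab42_AA"]], 6), "\n")
  cat("  quench factors: ab40 =", round(x$quench_factor[["ab40"]], 4),
      ", ab42 =", round(x$quench_factor[["ab42"]], 4), "\n")
  invisible(x)
}

#' Serialize / restore a calibration result as JSON
#'
#' @param calib A `calibration_result`.
#' @param path File path (`calibration.json` by convention).
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns a `calibration_result`.
#' @export
write_calibration <- function(calib, path) {
  ser <- purrr::map(unclass(calib), as.list)  # keep element names in JSON
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_result(
    ipm_ab40_DD = raw$intensity_per_molecule[["ab40_DD"]],
    ipm_ab42_AA = raw$intensity_per_molecule[["ab42_AA"]],
    lifetimes_ns = unlist(raw$lifetimes_ns),
    slope_stderr = unlist(raw$slope_stderr)
  )
}
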