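#' @noRd
new_field_bundle <- function(dd, da, aa, mask, pixel_nm, neurite_length_um,
                             polyline_um = NULL) {
  structure(
    list(dd = dd, da = da, aa = aa, mask = mask, pixel_nm = pixel_nm,
         neurite_length_um = neurite_length_um, polyline_um = polyline_um),
    class = "field_bundle"
  )
}

#' @export
print.field_bundle <- function(x, ...) {
  cat("<field_bundle>", nrow(x$dd), "x", ncol(x$dd), "px,",
      round(x$pixel_nm), "nm/px, neurite",
      round(x$neurite_length_um %||% NA_real_, 1), "um\n")
  invisible(x)
}

# Smoothed random-walk polyline emulating a neurite, in um coordinates
# (x right, y down), kept inside a margin. Returns the vertex matrix and the
# exact arc length.
#' @noRd
simulate_neurite_polyline <- function(size_um, target_length_um, step_um,
                                      heading_sd, margin_um = 2.5) {
  lo <- c(margin_um, margin_um)
  hi <- size_um - margin_um
  pos <- runif(2, lo + 0.2 * (hi - lo), hi - 0.2 * (hi - lo))
  heading <- runif(1, 0, 2 * pi)
  pts <- list(pos)
  len <- 0
  while (len < target_length_um) {
    heading <- heading + rnorm(1, 0, heading_sd)
    cand <- pos + step_um * c(cos(heading), sin(heading))
    tries <- 0
    while (any(cand < lo) || any(cand > hi)) {
      # steer back toward the field centre when the walk hits the margin
      centre <- (lo + hi) / 2
      heading <- atan2(centre[2] - pos[2], centre[1] - pos[1]) +
        rnorm(1, 0, heading_sd)
      cand <- pos + step_um * c(cos(heading), sin(heading))
      tries <- tries + 1
      if (tries > 50) break
    }
    len <- len + sqrt(sum((cand - pos)^2))
    pos <- cand
    pts[[length(pts) + 1]] <- pos
  }
  xy <- do.call(rbind, pts)
  colnames(xy) <- c("x", "y")
  list(xy = xy, length_um = len)
}

# Rasterize a polyline (um coords) to a binary mask of the given pixel grid,
# dilated to the requested width with a disc structuring element.
#' @noRd
rasterize_neurite <- function(polyline_um, dim_px, pixel_nm, width_um) {
  px_per_um <- 1000 / pixel_nm
  seg <- polyline_um
  mask <- matrix(0L, dim_px[1], dim_px[2])
  if (nrow(seg) >= 2) {
    for (i in seq_len(nrow(seg) - 1)) {
      a <- seg[i, ]
      b <- seg[i + 1, ]
      n <- max(2L, ceiling(sqrt(sum((b - a)^2)) * px_per_um * 4))
      t <- seq(0, 1, length.out = n)
      xs <- round((a[1] + t * (b[1] - a[1])) * px_per_um)
      ys <- round((a[2] + t * (b[2] - a[2])) * px_per_um)
      ok <- xs >= 0 & xs < dim_px[2] & ys >= 0 & ys < dim_px[1]
      mask[cbind(ys[ok] + 1L, xs[ok] + 1L)] <- 1L
    }
  }
  radius_px <- max(1L, round(width_um * px_per_um / 2))
  brush <- EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
  mask <- EBImage::dilate(mask, brush)
  matrix(as.integer(mask > 0), dim_px[1], dim_px[2])
}

# Add the pixel-integrated mass of an isotropic Gaussian spot to an image.
# Pixel (row r, col c), 0-based centre-of-pixel convention: pixel c covers
# x in [c - 0.5, c + 0.5). The erf-difference weights make the rendered mass
# sum exactly to `photons` (up to a < 1e-12 tail beyond the patch).
#' @noRd
add_gaussian_spot <- function(img, x_px, y_px, photons, sigma_px) {
  if (photons <= 0) return(img)
  r_half <- ceiling(8 * sigma_px) + 1L
  rows <- max(0L, floor(y_px) - r_half):min(nrow(img) - 1L, ceiling(y_px) + r_half)
  cols <- max(0L, floor(x_px) - r_half):min(ncol(img) - 1L, ceiling(x_px) + r_half)
  wy <- pnorm((rows - y_px + 0.5) / sigma_px) - pnorm((rows - y_px - 0.5) / sigma_px)
  wx <- pnorm((cols - x_px + 0.5) / sigma_px) - pnorm((cols - x_px - 0.5) / sigma_px)
  img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] +
    photons * outer(wy, wx)
  img
}

# Expected per-channel photon budgets for one spot. Membrane quenching scales
# both the radiative and the FRET-sensitized pathway; inside a heterogeneous
# oligomer the donor loses the fraction E of its emission to the acceptor,
# which re-emits it with the acceptor's quantum yield / detection efficiency.
#' @noRd
spot_photon_budget <- function(truth, cfg) {
  p40 <- cfg$photons_per_monomer$ab40$DD
  p42 <- cfg$photons_per_monomer$ab42$AA
  eta_ratio <- (cfg$acceptor$quantum_yield * cfg$acceptor$detection_efficiency) /
    (cfg$donor$quantum_yield * cfg$donor$detection_efficiency)
  e <- ifelse(truth$class == "hetero", cfg$fret_efficiency, 0)
  base_dd <- truth$n40 * p40 * cfg$quench_factor_40
  mu_dd <- base_dd * (1 - e)
  f_sens <- base_dd * e * eta_ratio
  mu_aa <- truth$n42 * p42 * cfg$quench_factor_42
  mu_da <- f_sens + cfg$crosstalk$alpha_bleed * mu_dd +
    cfg$crosstalk$delta_direct * mu_aa
  af <- truth$class == "autofluor"
  mu_dd[af] <- cfg$autofluorescence$brightness
  mu_da[af] <- 0
  mu_aa[af] <- 0
  tibble(mu_dd = mu_dd, mu_da = mu_da, mu_aa = mu_aa)
}

#' Generate one synthetic field with full ground truth
#'
#' Simulates a three-channel confocal acquisition (DD: 532 nm excitation /
#' donor emission; DA: 532 nm excitation / acceptor emission, the FRET
#' channel; AA: 635 nm excitation / acceptor emission) of labelled Abeta
#' oligomers on a curvilinear neurite, plus autofluorescent impostor spots
#' scattered over the whole field.
#'
#' Photon accounting per spot: expected DD photons are
#' `n40 * photons_per_monomer * quench_40 * (1 - E)` with `E` the FRET
#' efficiency for heterogeneous oligomers (0 otherwise); the transferred
#' quanta reappear in DA as sensitized emission scaled by the acceptor/donor
#' quantum-yield and detection-efficiency ratio; AA photons scale with `n42`
#' times the Abeta42 budget and quench factor. Spots are rendered as
#' pixel-integrated Gaussians and Poisson shot noise is applied per pixel
#' after adding the uniform background (unless `cfg$noise` is `FALSE`, in
#' which case expected values are returned for conservation diagnostics).
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; all randomness in the field derives from it.
#' @param roi_px ROI width used for the crowding check and border margin.
#' @param on_crowded What to do when the realized mean nearest-neighbour
#'   distance falls below twice the ROI width: warn and proceed (default),
#'   error, or proceed silently.
#' @return A list with `field` (a `field_bundle`: `dd`, `da`, `aa` photon
#'   rasters, binary `neurite_mask`-equivalent `mask`, `pixel_nm`, true
#'   neurite length) and `truth` (tibble: `id`, `x_px`, `y_px`, `class`,
#'   `n40`, `n42`, `lifetime_ns`, `on_neurite`).
#' @export
generate_field <- function(cfg, seed = cfg$seed, roi_px = 12L,
                           on_crowded = c("warn", "error", "silent")) {
  validate_sim_config(cfg)
  on_crowded <- match.arg(on_crowded)
  set.seed(as.integer(seed))
  dim_px <- cfg$image_size_px
  size_um <- rev(dim_px) * cfg$pixel_nm / 1000  # (x extent, y extent)
  px_per_um <- 1000 / cfg$pixel_nm

  neur <- simulate_neurite_polyline(size_um, cfg$neurite$target_length_um,
                                    cfg$neurite$step_um, cfg$neurite$heading_sd)
  mask <- rasterize_neurite(neur$xy, dim_px, cfg$pixel_nm,
                            cfg$neurite$width_um)

  margin_px <- roi_px / 2 + 2
  classes <- names(cfg$species_densities)
  counts <- stats::rpois(length(classes),
                         cfg$species_densities * neur$length_um / 100)
  names(counts) <- classes
  n_af <- stats::rpois(1, cfg$autofluorescence$density * neur$length_um / 100)

  seg_len <- sqrt(rowSums(diff(neur$xy)^2))
  cum_len <- c(0, cumsum(seg_len))

  place_on_neurite <- function(n) {
    if (n == 0) return(matrix(numeric(0), 0, 2))
    out <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      repeat {
        u <- runif(1, 0, neur$length_um)
        k <- findInterval(u, cum_len, rightmost.closed = TRUE)
        k <- min(max(k, 1L), nrow(neur$xy) - 1L)
        t <- (u - cum_len[k]) / seg_len[k]
        p <- neur$xy[k, ] + t * (neur$xy[k + 1, ] - neur$xy[k, ])
        d <- neur$xy[k + 1, ] - neur$xy[k, ]
        nrm <- c(-d[2], d[1]) / sqrt(sum(d^2))
        p <- p + runif(1, -cfg$neurite$width_um / 2,
                       cfg$neurite$width_um / 2) * nrm
        xp <- p[1] * px_per_um
        yp <- p[2] * px_per_um
        if (xp >= margin_px && xp <= dim_px[2] - 1 - margin_px &&
            yp >= margin_px && yp <= dim_px[1] - 1 - margin_px) {
          out[i, ] <- c(xp, yp)
          break
        }
      }
    }
    out
  }

  rows <- list()
  for (cls in classes) {
    n <- counts[[cls]]
    if (n == 0) next
    pos <- place_on_neurite(n)
    tab <- cfg$composition_tables[[cls]]
    pick <- sample.int(nrow(tab), n, replace = TRUE, prob = tab$prob)
    lt <- switch(cls,
      hom40 = cfg$lifetimes_ns[["ab40_bound"]],
      coloc_noFRET = cfg$lifetimes_ns[["ab40_bound"]],
      hetero = cfg$lifetimes_ns[["ab40_bound"]] * (1 - cfg$fret_efficiency),
      hom42 = cfg$lifetimes_ns[["ab42_bound"]]
    )
    rows[[cls]] <- tibble(
      x_px = pos[, 1], y_px = pos[, 2], class = cls,
      n40 = as.integer(tab$n40[pick]), n42 = as.integer(tab$n42[pick]),
      lifetime_ns = lt, on_neurite = TRUE
    )
  }
  if (n_af > 0) {
    xp <- runif(n_af, margin_px, dim_px[2] - 1 - margin_px)
    yp <- runif(n_af, margin_px, dim_px[1] - 1 - margin_px)
    on <- mask[cbind(round(yp) + 1L, round(xp) + 1L)] > 0
    rows[["autofluor"]] <- tibble(
      x_px = xp, y_px = yp, class = "autofluor",
      n40 = 0L, n42 = 0L,
      lifetime_ns = cfg$autofluorescence$lifetime_ns, on_neurite = on
    )
  }
  truth <- dplyr::bind_rows(rows)
  if (nrow(truth) == 0) {
    truth <- tibble(id = integer(), x_px = numeric(), y_px = numeric(),
                    class = character(), n40 = integer(), n42 = integer(),
                    lifetime_ns = numeric(), on_neurite = logical())
  } else {
    truth <- dplyr::mutate(truth, id = dplyr::row_number(),
                           .before = "x_px")
    nn <- mean_nearest_neighbour_nm(truth$x_px, truth$y_px, cfg$pixel_nm)
    if (is.finite(nn) && nn < 2 * roi_px * cfg$pixel_nm) {
      msg <- sprintf(
        "Spot density is high: mean nearest-neighbour distance %.0f nm < 2 x ROI width (%.0f nm); ROI background boxes will often overlap neighbouring spots.",
        nn, 2 * roi_px * cfg$pixel_nm)
      if (on_crowded == "error") abort(msg, class = "smoligo_crowded")
      if (on_crowded == "warn") warn(msg, class = "smoligo_crowded")
    }
  }

  budget <- spot_photon_budget(truth, cfg)
  sigma_px <- cfg$psf_sigma_nm / cfg$pixel_nm
  render <- function(mu) {
    img <- matrix(0, dim_px[1], dim_px[2])
    for (i in seq_len(nrow(truth))) {
      img <- add_gaussian_spot(img, truth$x_px[i], truth$y_px[i], mu[i],
                               sigma_px)
    }
    img <- img + cfg$background_rate
    if (cfg$noise) {
      img <- matrix(rpois(length(img), img), dim_px[1], dim_px[2])
    }
    img
  }
  field <- new_field_bundle(
    dd = render(budget$mu_dd), da = render(budget$mu_da),
    aa = render(budget$mu_aa), mask = mask, pixel_nm = cfg$pixel_nm,
    neurite_length_um = neur$length_um, polyline_um = neur$xy
  )
  list(field = field, truth = truth)
}

#' @noRd
mean_nearest_neighbour_nm <- function(x_px, y_px, pixel_nm) {
  n <- length(x_px)
  if (n < 2) return(Inf)
  d <- as.matrix(stats::dist(cbind(x_px, y_px)))
  diag(d) <- Inf
  mean(apply(d, 1, min)) * pixel_nm
}
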