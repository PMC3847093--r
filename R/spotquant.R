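#' @noRd
shift_mat <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr
  cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Detect diffraction-limited spots in one channel
#'
#' Local maxima of the Gaussian-smoothed image that exceed the background
#' level by `k_sigma` background standard deviations (background estimated
#' robustly by the median and MAD of the smoothed image, valid for sparse
#' fields). Maxima closer than `min_separation_px` are merged, keeping the
#' brighter one.
#'
#' @param image Photon-count matrix.
#' @param min_separation_px Merge radius in pixels.
#' @param k_sigma Detection threshold in background s.d. units.
#' @param smooth_sigma_px Gaussian smoothing sigma (px); default matches a
#'   diffraction-limited PSF at ~125 nm pixels.
#' @return Tibble with `x_px`, `y_px` (0-based pixel indices, centre-of-pixel
#'   convention) and `peak` (smoothed peak height), ordered by brightness.
#' @export
detect_spots <- function(image, min_separation_px = 4, k_sigma = 3,
                         smooth_sigma_px = 1) {
  if (length(image) == 0) abort("`image` must be non-empty.")
  sm <- as.matrix(EBImage::gblur(image, sigma = smooth_sigma_px))
  # background level and s.d. estimated robustly from the raw image (median
  # and MAD over a sparse field are background statistics); smoothing only
  # sharpens the maxima, the threshold stays on the raw photon scale
  thr <- median(image) + k_sigma * max(mad(image), 1e-12)
  is_max <- sm > thr
  for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
    is_max <- is_max & sm >= shift_mat(sm, d[1], d[2], fill = -Inf)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(x_px = numeric(), y_px = numeric(), peak = numeric()))
  }
  cand <- tibble(x_px = idx[, "col"] - 1, y_px = idx[, "row"] - 1,
                 peak = sm[idx])
  cand <- dplyr::arrange(cand, dplyr::desc(.data$peak))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    prev <- which(keep)
    if (length(prev) == 0) {
      keep[i] <- TRUE
    } else {
      d2 <- (cand$x_px[prev] - cand$x_px[i])^2 +
        (cand$y_px[prev] - cand$y_px[i])^2
      keep[i] <- all(d2 >= min_separation_px^2)
    }
  }
  cand[keep, ]
}

# Choose the adjacent equal-sized background box: first of right/left/up/down
# that lies fully inside the image and contains no other detected spot.
# Falls back to the first in-image candidate if every neighbour is occupied.
#' @noRd
select_background_box <- function(cx, cy, roi_px, dim_px, others = NULL) {
  half_lo <- roi_px %/% 2 - 1L
  half_hi <- roi_px %/% 2
  box <- function(cx, cy) {
    list(cols = (cx - half_lo):(cx + half_hi),
         rows = (cy - half_lo):(cy + half_hi))
  }
  offsets <- list(c(roi_px, 0L), c(-roi_px, 0L), c(0L, -roi_px),
                  c(0L, roi_px))  # right, left, up, down
  inside <- function(b) {
    min(b$cols) >= 0 && max(b$cols) <= dim_px[2] - 1 &&
      min(b$rows) >= 0 && max(b$rows) <= dim_px[1] - 1
  }
  occupied <- function(b) {
    if (is.null(others) || nrow(others) == 0) return(FALSE)
    any(round(others$x_px) >= min(b$cols) & round(others$x_px) <= max(b$cols) &
        round(others$y_px) >= min(b$rows) & round(others$y_px) <= max(b$rows))
  }
  fallback <- NULL
  for (off in offsets) {
    b <- box(cx + off[1], cy + off[2])
    if (!inside(b)) next
    if (is.null(fallback)) fallback <- b
    if (!occupied(b)) return(b)
  }
  fallback
}

#' Integrate a spot in a square ROI with adjacent-background subtraction
#'
#' Sums photon counts in a `roi_px` x `roi_px` box centred on the spot and
#' subtracts the total of an equal-sized adjacent background box (first
#' unoccupied neighbour right/left/up/down; a neighbour containing another
#' detected spot is skipped).
#'
#' @param image Photon-count matrix.
#' @param x_px,y_px Spot centre, 0-based pixel coordinates.
#' @param roi_px ROI width in pixels (12 px ~ 1.5 um at 125 nm/px).
#' @param others Optional tibble of all detected spots (columns `x_px`,
#'   `y_px`) used to avoid background boxes containing neighbours.
#' @return List with `intensity` (background-subtracted integrated counts),
#'   `bg_total`, and `edge_flag` (`TRUE` when the ROI or every candidate
#'   background box leaves the image; such spots are excluded from
#'   statistics).
#' @export
integrate_spot <- function(image, x_px, y_px, roi_px = 12L, others = NULL) {
  dim_px <- dim(image)
  cx <- round(x_px)
  cy <- round(y_px)
  half_lo <- roi_px %/% 2 - 1L
  half_hi <- roi_px %/% 2
  cols <- (cx - half_lo):(cx + half_hi)
  rows <- (cy - half_lo):(cy + half_hi)
  if (min(cols) < 0 || max(cols) > dim_px[2] - 1 ||
      min(rows) < 0 || max(rows) > dim_px[1] - 1) {
    return(list(intensity = NA_real_, bg_total = NA_real_, edge_flag = TRUE))
  }
  roi_sum <- sum(image[rows + 1L, cols + 1L])
  if (!is.null(others)) {
    others <- others[!(round(others$x_px) == cx & round(others$y_px) == cy), ,
                     drop = FALSE]
  }
  bg <- select_background_box(cx, cy, as.integer(roi_px), dim_px, others)
  if (is.null(bg)) {
    return(list(intensity = NA_real_, bg_total = NA_real_, edge_flag = TRUE))
  }
  bg_total <- sum(image[bg$rows + 1L, bg$cols + 1L])
  list(intensity = roi_sum - bg_total, bg_total = bg_total, edge_flag = FALSE)
}

#' Measure detected spots in all three channels
#'
#' Applies [integrate_spot()] to the DD, DA and AA images of a field at the
#' given positions (the same background box, chosen on geometry alone, is
#' used for all channels of a spot).
#'
#' @param field A `field_bundle` (see [generate_field()]) or a named list
#'   with matrices `dd`, `da`, `aa`.
#' @param positions Tibble with `x_px`, `y_px`.
#' @param roi_px ROI width in pixels.
#' @return Tibble: `id`, `x_px`, `y_px`, `I_dd`, `I_da`, `I_aa`, `bg_dd`,
#'   `bg_da`, `bg_aa`, `edge_flag`, `crowded_flag`. `crowded_flag` marks
#'   spots with another detection close enough that the ROIs share photons;
#'   such spots classify normally but their integrated sizes are inflated by
#'   the neighbour and are excluded from size statistics.
#' @export
measure_spots <- function(field, positions, roi_px = 12L) {
  if (nrow(positions) == 0) {
    return(tibble(id = integer(), x_px = numeric(), y_px = numeric(),
                  I_dd = numeric(), I_da = numeric(), I_aa = numeric(),
                  bg_dd = numeric(), bg_da = numeric(), bg_aa = numeric(),
                  edge_flag = logical(), crowded_flag = logical()))
  }
  res <- purrr::map_dfr(seq_len(nrow(positions)), function(i) {
    x <- positions$x_px[i]
    y <- positions$y_px[i]
    dd <- integrate_spot(field$dd, x, y, roi_px, others = positions)
    da <- integrate_spot(field$da, x, y, roi_px, others = positions)
    aa <- integrate_spot(field$aa, x, y, roi_px, others = positions)
    dx <- abs(positions$x_px - x)
    dy <- abs(positions$y_px - y)
    crowded <- sum(pmax(dx, dy) <= roi_px / 2 + 2) > 1  # self plus neighbour
    tibble(id = i, x_px = x, y_px = y,
           I_dd = dd$intensity, I_da = da$intensity, I_aa = aa$intensity,
           bg_dd = dd$bg_total, bg_da = da$bg_total, bg_aa = aa$bg_total,
           edge_flag = dd$edge_flag | da$edge_flag | aa$edge_flag,
           crowded_flag = crowded)
  })
  res
}

#' Keep spots on or near the neurite
#'
#' Computes each spot's distance to the nearest neurite-mask pixel with a
#' Euclidean distance transform and keeps those within `max_dist_nm`
#' (membrane-bound oligomers are defined as spots whose maxima fall on or
#' within 500 nm of a neurite).
#'
#' @param spots Tibble with `x_px`, `y_px` (0-based).
#' @param mask Binary neurite mask matrix (same geometry as the images).
#' @param max_dist_nm Maximum centre-to-mask distance (nm).
#' @param pixel_nm Pixel pitch (nm).
#' @return `spots` filtered, with a `dist_nm` column added. An empty mask
#'   rejects all spots with a warning.
#' @export
neurite_filter <- function(spots, mask, max_dist_nm = 500, pixel_nm = 125) {
  if (sum(mask) == 0) {
    warn("Neurite mask is empty; all spots rejected.")
    return(dplyr::mutate(spots[0, ], dist_nm = numeric(0)))
  }
  dist_px <- as.matrix(EBImage::distmap(1 - (mask > 0)))
  spots$dist_nm <- dist_px[cbind(round(spots$y_px) + 1L,
                                 round(spots$x_px) + 1L)] * pixel_nm
  dplyr::filter(spots, .data$dist_nm <= max_dist_nm)
}

# One pass of Zhang-Suen thinning (subiteration 1 or 2), vectorized over the
# whole binary matrix.
#' @noRd
thin_pass <- function(m, sub) {
  p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
  p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
  p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
  p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  a <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:8) a <- a + (seqs[[i]] == 0 & seqs[[i + 1]] == 1)
  if (sub == 1) {
    cond <- (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
  } else {
    cond <- (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
  }
  del <- m == 1 & b >= 2 & b <= 6 & a == 1 & cond
  m[del] <- 0L
  list(m = m, changed = any(del))
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' @param mask Binary matrix.
#' @return Binary matrix of the one-pixel-wide skeleton.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  repeat {
    s1 <- thin_pass(m, 1)
    s2 <- thin_pass(s1$m, 2)
    m <- s2$m
    if (!s1$changed && !s2$changed) break
  }
  m
}

#' @noRd
skeleton_neighbour_counts <- function(sk) {
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  Reduce(`+`, lapply(offs, function(d) shift_mat(sk, d[1], d[2])))
}

# Ordered walk along a single open skeleton path, greedily following
# unvisited neighbours (orthogonal preferred so corner clusters are not cut).
#' @noRd
walk_skeleton_path <- function(sk, start) {
  path <- matrix(NA_real_, sum(sk), 2)
  cur <- start
  n <- 0L
  repeat {
    n <- n + 1L
    path[n, ] <- cur
    sk[cur[1], cur[2]] <- 0L
    rows <- cur[1] + c(-1, 0, 1, 0, -1, -1, 1, 1)
    cols <- cur[2] + c(0, -1, 0, 1, -1, 1, -1, 1)
    ok <- rows >= 1 & rows <= nrow(sk) & cols >= 1 & cols <= ncol(sk)
    ok[ok] <- sk[cbind(rows[ok], cols[ok])] == 1
    if (!any(ok)) break
    k <- which(ok)[1]   # orthogonal candidates listed first
    cur <- c(rows[k], cols[k])
  }
  path[seq_len(n), , drop = FALSE]
}

# Running mean with symmetric windows that shrink near the ends, so the end
# points are preserved exactly
#' @noRd
smooth_coords <- function(v, half = 3L) {
  n <- length(v)
  cs <- c(0, cumsum(v))
  h <- pmin(half, seq_len(n) - 1L, n - seq_len(n))
  lo <- seq_len(n) - h
  hi <- seq_len(n) + h
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Total neurite length from the mask
#'
#' Skeletonizes the mask ([skeletonize()]) and measures the skeleton's arc
#' length. For the common case of a single open path (two endpoints) the
#' skeleton is traversed end to end and the length of the smoothed pixel
#' path is returned, which removes the staircase inflation of raw pixel
#' steps. Branched or closed skeletons fall back to counting unique
#' adjacencies (orthogonal steps one pixel, diagonal steps `sqrt(2)`,
#' diagonal shortcuts of orthogonal corners not double-counted).
#'
#' @param mask Binary neurite mask.
#' @param pixel_nm Pixel pitch (nm).
#' @return Length in micrometres.
#' @export
neurite_length <- function(mask, pixel_nm = 125) {
  if (sum(mask) == 0) return(0)
  sk <- skeletonize(mask)
  nb <- skeleton_neighbour_counts(sk)
  ends <- which(sk == 1 & nb == 1, arr.ind = TRUE)
  if (nrow(ends) == 2) {
    path <- walk_skeleton_path(sk, ends[1, ])
    if (nrow(path) >= 0.9 * sum(sk)) {
      x <- smooth_coords(path[, 2])
      y <- smooth_coords(path[, 1])
      len_px <- sum(sqrt(diff(x)^2 + diff(y)^2))
      return(len_px * pixel_nm / 1000)
    }
  }
  # fallback: unique-adjacency count over the whole skeleton
  e <- shift_mat(sk, 0, 1)
  s <- shift_mat(sk, 1, 0)
  w <- shift_mat(sk, 0, -1)
  n_orth <- sum(sk * e) + sum(sk * s)
  se <- sk * shift_mat(sk, 1, 1) * (1 - pmax(e, s))
  sw <- sk * shift_mat(sk, 1, -1) * (1 - pmax(w, s))
  (n_orth + sqrt(2) * (sum(se) + sum(sw))) * pixel_nm / 1000
}

#' Match detected spots to ground-truth spots
#'
#' Optimal one-to-one assignment (Hungarian algorithm) between detections and
#' ground-truth positions, admitting only pairs within `radius_nm`.
#'
#' @param detected,truth Tibbles with `x_px`, `y_px`.
#' @param radius_nm Maximum matching distance (nm).
#' @param pixel_nm Pixel pitch (nm).
#' @return Tibble with `det`, `truth` (row indices) and `dist_nm`.
#' @export
match_spots <- function(detected, truth, radius_nm = 250, pixel_nm = 125) {
  empty <- tibble(det = integer(), truth = integer(), dist_nm = numeric())
  nd <- nrow(detected)
  nt <- nrow(truth)
  if (nd == 0 || nt == 0) return(empty)
  dx <- outer(detected$x_px, truth$x_px, "-")
  dy <- outer(detected$y_px, truth$y_px, "-")
  cost <- sqrt(dx^2 + dy^2) * pixel_nm
  big <- 10 * max(cost) + radius_nm + 1
  cost_cap <- ifelse(cost <= radius_nm, cost, big)
  n <- max(nd, nt)
  padded <- matrix(big, n, n)
  padded[seq_len(nd), seq_len(nt)] <- cost_cap
  sol <- clue::solve_LSAP(padded)
  det_idx <- seq_len(nd)
  truth_idx <- as.integer(sol)[seq_len(nd)]
  ok <- truth_idx <= nt & cost_cap[cbind(det_idx, pmin(truth_idx, nt))] <= radius_nm
  tibble(det = det_idx[ok], truth = truth_idx[ok],
         dist_nm = cost[cbind(det_idx[ok], truth_idx[ok])])
}

#' Write a per-spot measurement table as CSV
#'
#' Columns follow the pipeline's spot schema:
#' `id,channel,x_px,y_px,I_dd,I_da,I_aa,bg_dd,bg_da,bg_aa,dist_nm,edge_flag`.
#'
#' @param spots Spot tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  cols <- c("id", "channel", "x_px", "y_px", "I_dd", "I_da", "I_aa",
            "bg_dd", "bg_da", "bg_aa", "dist_nm", "edge_flag")
  for (cl in setdiff(cols, names(spots))) spots[[cl]] <- NA
  utils::write.csv(spots[, cols], path, row.names = FALSE)
  invisible(path)
}
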