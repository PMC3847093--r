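test_that("blank and near-blank images yield no detections", {
  expect_equal(nrow(detect_spots(matrix(0, 64, 64))), 0)
  set.seed(1)
  noise <- matrix(rpois(64 * 64, 5), 64, 64)
  expect_equal(nrow(detect_spots(noise)), 0)
})

test_that("maxima closer than the separation radius merge to the brighter one", {
  img <- render_single_spot(64, 30, 30, 2000)
  img <- smoligo:::add_gaussian_spot(img, 31, 30, 1500, 0.88)
  det <- detect_spots(img)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_px - 30), 1.5)
})

test_that("detection achieves high recall and precision on a synthetic field", {
  cfg <- single_species_cfg("hom40", density = 12)
  hits <- 0; n_det <- 0; n_truth <- 0
  for (s in 1:3) {
    sim <- generate_field(cfg, seed = 200 + s)
    det <- detect_spots(sim$field$dd)
    m <- match_spots(det, sim$truth, radius_nm = 250, pixel_nm = cfg$pixel_nm)
    hits <- hits + nrow(m)
    n_det <- n_det + nrow(det)
    n_truth <- n_truth + nrow(sim$truth)
  }
  expect_gt(n_truth, 30)
  expect_gte(hits / n_truth, 0.95)  # recall
  expect_gte(hits / n_det, 0.95)    # precision
})

test_that("uniform images integrate to zero after background subtraction", {
  img <- matrix(7, 64, 64)
  res <- integrate_spot(img, 30, 30)
  expect_equal(res$intensity, 0)
  expect_false(res$edge_flag)
})

test_that("a rendered spot integrates to its photon budget within PSF truncation", {
  img <- render_single_spot(64, 31, 31, 1280)
  res <- integrate_spot(img, 31, 31)
  expect_lt(abs(res$intensity - 1280), 0.01 * 1280)
  expect_equal(res$bg_total, 0, tolerance = 1e-6)
})

test_that("ROIs that leave the image are edge-flagged", {
  img <- matrix(0, 64, 64)
  expect_true(integrate_spot(img, 2, 32)$edge_flag)
  expect_false(integrate_spot(img, 32, 32)$edge_flag)
  # a centred ROI whose four neighbour boxes all leave the image is also
  # flagged: no background estimate is available
  expect_true(integrate_spot(matrix(0, 32, 32), 16, 16)$edge_flag)
})

test_that("an occupied background box is skipped for the next free neighbour", {
  img <- render_single_spot(96, 40, 40, 1280)
  img <- smoligo:::add_gaussian_spot(img, 52, 40, 5000, 0.88)  # in right box
  others <- tibble::tibble(x_px = c(40, 52), y_px = c(40, 40))
  res <- integrate_spot(img, 40, 40, others = others)
  expect_lt(abs(res$intensity - 1280), 0.01 * 1280)
  # without the occupancy information the right-hand box is contaminated
  naive <- integrate_spot(img, 40, 40)
  expect_lt(naive$intensity, 0)
})

test_that("integration is additive over disjoint spots", {
  one <- render_single_spot(128, 30, 30, 1000)
  other <- render_single_spot(128, 90, 90, 2500)
  both <- one + other
  others <- tibble::tibble(x_px = c(30, 90), y_px = c(30, 90))
  i1 <- integrate_spot(one, 30, 30)$intensity
  i2 <- integrate_spot(other, 90, 90)$intensity
  j1 <- integrate_spot(both, 30, 30, others = others)$intensity
  j2 <- integrate_spot(both, 90, 90, others = others)$intensity
  expect_equal(j1 + j2, i1 + i2, tolerance = 1e-9)
})

test_that("the neurite gate keeps spots within 500 nm and is monotone", {
  mask <- matrix(0L, 64, 64)
  mask[, 21:31] <- 1L  # vertical band, columns 20..30 (0-based)
  # 0-based x: on mask 25; 3.2 px (400 nm) and 4.8 px (600 nm) off the edge
  spots <- tibble::tibble(x_px = c(25, 30 + 3.2, 30 + 4.8), y_px = 32,
                          id = 1:3)
  kept <- neurite_filter(spots, mask, max_dist_nm = 500, pixel_nm = 125)
  expect_setequal(kept$id, c(1, 2))
  expect_equal(kept$dist_nm[kept$id == 1], 0)
  kept400 <- neurite_filter(spots, mask, max_dist_nm = 400, pixel_nm = 125)
  expect_true(all(kept400$id %in% kept$id))
})

test_that("an empty mask rejects every spot with a warning", {
  spots <- tibble::tibble(x_px = 10, y_px = 10)
  expect_warning(out <- neurite_filter(spots, matrix(0L, 32, 32)), "empty")
  expect_equal(nrow(out), 0)
})

test_that("neurite length matches a bar and the generator's arc length", {
  mask <- matrix(0L, 32, 128)
  mask[16, 21:100] <- 1L  # 80-px horizontal bar
  expect_lt(abs(neurite_length(mask, 125) - 10), 0.125 + 1e-9)
  expect_equal(neurite_length(matrix(0L, 16, 16), 125), 0)

  # a smooth, non-self-crossing curve rasterized to the study's band width:
  # skeleton length must agree with the polyline's analytic arc length
  # (self-crossing masks merge pixels and legitimately shorten the skeleton)
  t <- seq(0, 1, length.out = 400)
  poly <- cbind(x = 5 + 38 * t, y = 24 + 6 * sin(6 * t))
  arc <- sum(sqrt(rowSums(diff(poly)^2)))
  mask <- smoligo:::rasterize_neurite(poly, c(384L, 384L), 125, 1.5)
  est <- neurite_length(mask, 125)
  expect_lt(abs(est - arc) / arc, 0.05)
})

test_that("crowded ROIs are flagged during measurement", {
  field <- list(dd = render_single_spot(96, 30, 30, 1000) +
                  render_single_spot(96, 34, 30, 1000),
                da = matrix(0, 96, 96), aa = matrix(0, 96, 96))
  pos <- tibble::tibble(x_px = c(30, 34, 70), y_px = c(30, 30, 70))
  meas <- measure_spots(field, pos)
  expect_true(all(meas$crowded_flag[1:2]))
  expect_false(meas$crowded_flag[3])
})
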