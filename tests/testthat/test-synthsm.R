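test_that("noise-free rendering conserves the analytic photon budget", {
  cfg <- small_cfg(
    background_rate = 0, noise = FALSE,
    composition_tables = list(
      hom40 = tibble::tibble(n40 = 2L, n42 = 0L, prob = 1),
      hom42 = tibble::tibble(n40 = 0L, n42 = 1L, prob = 1),
      hetero = tibble::tibble(n40 = 1L, n42 = 1L, prob = 1),
      coloc_noFRET = tibble::tibble(n40 = 1L, n42 = 1L, prob = 1)
    )
  )
  cfg$species_densities <- c(hom40 = 5, hom42 = 0, hetero = 0,
                             coloc_noFRET = 0)
  cfg$autofluorescence$density <- 0
  sim <- suppressWarnings(generate_field(cfg, seed = 11))
  n <- nrow(sim$truth)
  expect_gt(n, 0)
  # each hom40 spot carries n40 = 2 monomers at 1000 photons and quench 0.64
  expect_equal(sum(sim$field$dd), n * 2 * 1000 * 0.64, tolerance = 1e-9)
  expect_equal(sum(sim$field$da), 0)
  expect_equal(sum(sim$field$aa), 0)

  # heterogeneous budget: donor loses E = 0.5 to FRET, sensitized emission
  # reappears in DA scaled by the acceptor/donor phi*eta ratio, AA unaffected
  cfg$species_densities <- c(hom40 = 0, hom42 = 0, hetero = 5,
                             coloc_noFRET = 0)
  sim <- suppressWarnings(generate_field(cfg, seed = 12))
  n <- nrow(sim$truth)
  eta_ratio <- (0.30 * 0.35) / (0.25 * 0.35)
  expect_equal(sum(sim$field$dd), n * 1000 * 0.64 * 0.5, tolerance = 1e-9)
  expect_equal(sum(sim$field$da), n * 1000 * 0.64 * 0.5 * eta_ratio,
               tolerance = 1e-9)
  expect_equal(sum(sim$field$aa), n * 1000 * (1.24 / 1.56), tolerance = 1e-9)
})

test_that("ground-truth class proportions follow the configured densities", {
  cfg <- small_cfg()
  classes <- c("hom40", "hom42", "hetero", "coloc_noFRET")
  pooled <- integer(length(classes))
  names(pooled) <- classes
  for (s in 1:6) {
    sim <- suppressWarnings(generate_field(cfg, seed = 100 + s))
    tab <- table(factor(sim$truth$class, levels = classes))
    pooled <- pooled + as.integer(tab)
  }
  p0 <- cfg$species_densities / sum(cfg$species_densities)
  n <- sum(pooled)
  for (cls in classes) {
    expect_within_binomial_ci(pooled[[cls]] / n, p0[[cls]], n, conf = 0.999)
  }
})

test_that("class counts scale with neurite length (law of large numbers)", {
  cfg <- study_config(
    "10min",
    image_size_px = c(1024L, 1024L),
    neurite = list(width_um = 1.5, target_length_um = 1200, step_um = 2,
                   heading_sd = 0.35)
  )
  sim <- suppressWarnings(generate_field(cfg, seed = 5))
  expected <- sum(cfg$species_densities) * sim$field$neurite_length_um / 100
  n_lab <- sum(sim$truth$class != "autofluor")
  expect_lt(abs(n_lab - expected), 4 * sqrt(expected))
})

test_that("zero densities give an empty truth table and background-only images", {
  cfg <- small_cfg()
  cfg$species_densities[] <- 0
  cfg$autofluorescence$density <- 0
  sim <- generate_field(cfg, seed = 2)
  expect_equal(nrow(sim$truth), 0)
  expect_lt(abs(mean(sim$field$dd) - cfg$background_rate), 0.1)
  expect_true(all(sim$field$dd >= 0))
  expect_true(all(sim$field$dd == round(sim$field$dd)))
})

test_that("overcrowded configurations are rejected in strict mode", {
  cfg <- small_cfg()
  cfg$species_densities <- cfg$species_densities * 4
  expect_error(generate_field(cfg, seed = 3, on_crowded = "error"),
               class = "smoligo_crowded")
  expect_warning(generate_field(cfg, seed = 3, on_crowded = "warn"),
                 class = "smoligo_crowded")
  expect_silent(invisible(generate_field(cfg, seed = 3,
                                         on_crowded = "silent")))
})

test_that("decay sampler matches the truncated-exponential mean", {
  tau <- 1
  window <- 50
  d <- generate_decay(tau, 1e6, bin_ns = 0.01, window_ns = window, seed = 4)
  mid <- (head(d$bin_edges_ns, -1) + tail(d$bin_edges_ns, -1)) / 2
  emp_mean <- sum(mid * d$counts) / sum(d$counts)
  # closed-form mean of Exp(tau) truncated to [0, window]
  m <- tau - window * exp(-window / tau) / (1 - exp(-window / tau))
  expect_lt(abs(emp_mean - m), 3 * tau / sqrt(1e6) + 0.01 / 2)
})

test_that("decay sampler rejects invalid photon counts", {
  expect_error(generate_decay(1, 0, seed = 1))
  expect_error(generate_decay(-1, 100, seed = 1))
})

test_that("decay histograms are consistent with the generating exponential", {
  tau <- 1
  window <- 12.5
  bin <- 0.05
  edges <- seq(0, window, by = bin)
  probs <- (exp(-head(edges, -1) / tau) - exp(-tail(edges, -1) / tau)) /
    (1 - exp(-window / tau))
  n <- 800
  pass <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    d <- generate_decay(tau, n, bin_ns = bin, window_ns = window, seed = s)
    # pool bins so every expected count is >= 5, then chi-square GOF
    grp <- pmin(cumsum(n * probs) %/% 5, 60)
    obs <- tapply(d$counts, grp, sum)
    exp_p <- tapply(probs, grp, sum)
    p <- suppressWarnings(
      stats::chisq.test(as.vector(obs), p = as.vector(exp_p),
                        rescale.p = TRUE)$p.value)
    if (p > 0.01) pass <- pass + 1
  }
  expect_gte(pass / n_seeds, 0.95)
})

test_that("calibration series is linear with configurable noise", {
  s <- generate_calibration_series(c(0.1, 0.2, 0.3), 100, volume_fL = 1,
                                   noise_sd = 0, seed = 1)
  expect_equal(s$integrated_intensity, 100 * s$molecules)
  expect_equal(s$integrated_intensity[1] / s$integrated_intensity[2],
               0.5, tolerance = 1e-12)

  noisy <- generate_calibration_series(seq(20, 200, by = 20), 100,
                                       noise_sd = 500, n_replicates = 3,
                                       seed = 7)
  # independent closed-form least-squares oracle
  x <- noisy$molecules
  y <- noisy$integrated_intensity
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  resid <- y - mean(y) - slope * (x - mean(x))
  se <- sqrt(sum(resid^2) / (length(x) - 2) / sum((x - mean(x))^2))
  expect_lt(abs(slope - 100), 2 * se)
})

test_that("calibration series validates its inputs", {
  expect_error(generate_calibration_series(c(2, 1), 100))
  expect_error(generate_calibration_series(c(-1, 1), 100))
})
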