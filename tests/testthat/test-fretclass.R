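test_that("sensitized emission removes bleed-through and direct excitation", {
  expect_equal(sensitized_emission(100, 0, 0, 0.1, 0.05), 100)
  expect_equal(sensitized_emission(100, 1000, 0, 0.1, 0.05), 0)
  expect_equal(sensitized_emission(150, 1000, 400, 0.1, 0.05), 30)
  expect_equal(sensitized_emission(10, 1000, 0, 0.1, 0), 0)  # floored
})

test_that("corrected donor counts implement photon accounting", {
  d <- fluorophore("D", 1e5, 0.25, 0.4)
  a <- fluorophore("A", 1e5, 0.5, 0.4)
  expect_equal(corrected_donor_counts(500, 0, d, a), 500 / 0.1)
  unit <- fluorophore("U", 1e5, 1, 1)
  expect_equal(corrected_donor_counts(500, 300, unit, unit), 800)
  bad <- d
  bad$quantum_yield <- 0
  expect_error(corrected_donor_counts(1, 1, bad, a))
})

test_that("the Forster relation has its defining values", {
  expect_identical(fret_efficiency_distance(5.3, 5.3), 0.5)
  expect_identical(fret_efficiency_distance(0, 5.3), 1)
  expect_equal(fret_efficiency_distance(2 * 5.3, 5.3), 1 / 65)
  r <- seq(0.5, 15, by = 0.5)
  expect_true(all(diff(fret_efficiency_distance(r, 5.3)) < 0))
  expect_error(fret_efficiency_distance(-1, 5.3))
})

test_that("donor-only fields produce no FRET calls and near-zero sensitized emission", {
  cfg <- single_species_cfg("hom40", density = 12)
  ex <- run_experiment(cfg, n_fields = 2, seed = 41)
  expect_gt(nrow(ex$spots), 20)
  expect_lte(mean(ex$spots$class == "hetero"), 0.02)
  expect_true(all(ex$spots$class %in% c("hom40", "hom42", "coloc_noFRET")))
  # sensitized emission should scatter around zero: well below one monomer's
  # worth of acceptor photons on average
  expect_lt(mean(ex$spots$F_sens), 100)
  expect_lte(mean(ex$spots$class != "hom40"), 0.05)
})

test_that("acceptor-only fields yield hom42 calls only", {
  cfg <- single_species_cfg("hom42", density = 12)
  ex <- run_experiment(cfg, n_fields = 2, seed = 43)
  expect_gt(nrow(ex$spots), 20)
  expect_lte(mean(ex$spots$class == "hetero"), 0.02)
  expect_gte(mean(ex$spots$class == "hom42"), 0.95)
})

test_that("species classification reaches 90 percent accuracy on mixed fields", {
  cfg <- small_cfg()
  calib <- simulate_calibration(cfg, seed = 5)
  n_ok <- 0
  n_tot <- 0
  for (s in 1:3) {
    sim <- suppressWarnings(generate_field(cfg, seed = 300 + s))
    spots <- analyze_field(sim$field, sim$truth, calib, cfg, seed = 400 + s)
    m <- match_spots(spots, sim$truth, 250, cfg$pixel_nm)
    lab <- sim$truth$class[m$truth]
    keep <- lab != "autofluor"
    n_ok <- n_ok + sum(spots$class[m$det][keep] == lab[keep])
    n_tot <- n_tot + sum(keep)
  }
  expect_gt(n_tot, 60)
  expect_gte(n_ok / n_tot, 0.90)
})

test_that("classification is invariant to joint intensity rescaling", {
  spots <- tibble::tibble(
    I_dd = c(5000, 10, 4000, 3000, 20),
    I_da = c(30, 15, 2500, 40, 2000),
    I_aa = c(25, 6000, 3500, 4500, 10),
    bg_dd = 700, bg_da = 700, bg_aa = 700
  )
  thr <- list(sd_dd = 40, sd_da = 40, sd_aa = 40)
  base <- classify_species(spots, thresholds = thr)
  for (c_scale in c(0.5, 20)) {
    scaled_spots <- dplyr::mutate(spots, dplyr::across(
      dplyr::everything(), ~ .x * c_scale))
    scaled_thr <- purrr::map(thr, ~ .x * c_scale)
    scaled <- classify_species(scaled_spots, thresholds = scaled_thr)
    expect_identical(scaled$class, base$class)
  }
  # and the expected calls themselves
  expect_identical(base$class,
                   c("hom40", "hom42", "hetero", "coloc_noFRET", NA))
})

test_that("crosstalk coefficients are recovered from control fields", {
  set.seed(13)
  donor_only <- tibble::tibble(I_dd = runif(40, 500, 5000))
  donor_only$I_da <- 0.12 * donor_only$I_dd + rnorm(40, 0, 20)
  donor_only$I_aa <- 0
  acc_only <- tibble::tibble(I_aa = runif(40, 500, 5000))
  acc_only$I_da <- 0.06 * acc_only$I_aa + rnorm(40, 0, 20)
  acc_only$I_dd <- 0
  ct <- estimate_crosstalk(donor_only, acc_only)
  expect_equal(ct$alpha_bleed, 0.12, tolerance = 0.02)
  expect_equal(ct$delta_direct, 0.06, tolerance = 0.02)
})

test_that("FRET-corrected donor sizing is unbiased and the naive size is halved", {
  cfg <- single_species_cfg("hetero", density = 8)
  cfg$composition_tables$hetero <- tibble::tibble(n40 = 2L, n42 = 2L, prob = 1)
  ex <- run_experiment(cfg, n_fields = 4, seed = 55)
  het <- dplyr::filter(ex$spots, class == "hetero", !crowded_flag)
  expect_gt(nrow(het), 25)
  se <- sd(het$n40_real) / sqrt(nrow(het))
  expect_lt(abs(mean(het$n40_real) - 2), 3 * se + 0.05)
  # naive DD-only sizing ignores the FRET loss and lands near (1 - E) * n40
  ipm <- ex$calib$intensity_per_molecule[["ab40_DD"]]
  q <- ex$calib$quench_factor[["ab40"]]
  naive <- as.numeric(monomer_equivalents(het$I_dd, ipm, q))
  expect_lt(abs(mean(naive) - 1) , 0.15)
})

test_that("corrected sizing reduces to plain DD sizing without FRET", {
  spots <- tibble::tibble(
    I_dd = c(1280, 640), I_da = 0, I_aa = c(795, 795),
    bg_dd = 0, bg_da = 0, bg_aa = 0,
    class = c("coloc_noFRET", "hetero"), F_sens = 0
  )
  calib <- calibration_result(1000, 1000)
  out <- size_oligomers(spots, calib)
  expect_equal(out$n40_real[1],
               as.numeric(monomer_equivalents(1280, 1000, 0.64)))
  expect_equal(out$n40_real[2],
               as.numeric(monomer_equivalents(640, 1000, 0.64)))
  expect_equal(out$n42[1], 1L)
})
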