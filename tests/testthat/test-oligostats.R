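test_that("integer sizing rounds halves away from zero", {
  expect_identical(integer_size(c(2.6, 1.2, 2.5, 0.4, 3.5)),
                   c(3L, 1L, 3L, 0L, 4L))
  expect_error(integer_size(-0.1))
})

test_that("heterogeneous sizes sum the rounded components", {
  expect_identical(hetero_size(1.2, 2.6), 4L)
  expect_identical(hetero_size(1.0, 1.0), 2L)  # minimal heterogeneous dimer
  expect_true(is.na(hetero_size(0.2, 0.3)))
})

test_that("size distributions normalize with an open top bin", {
  d <- size_distribution(c(2, 2, 3, 7, 9))
  expect_equal(sum(d$fraction), 1, tolerance = 1e-12)
  expect_equal(d$fraction[d$bin == "2"], 0.4)
  expect_equal(d$fraction[d$bin == "3"], 0.2)
  expect_equal(d$fraction[d$bin == "7+"], 0.4)
  dimers <- size_distribution(rep(2, 10))
  expect_equal(dimers$fraction[dimers$bin == "2"], 1)
  expect_error(size_distribution(numeric(0)))
  records <- tibble::tibble(total_size = c(2, 8, 3), class = c("a", "a", "b"))
  da <- size_distribution(records, class_filter = "a")
  expect_equal(da$fraction[da$bin == "7+"], 0.5)
})

test_that("species fractions use per-peptide denominators", {
  rec <- tibble::tibble(class = rep(c("hom40", "hetero", "coloc_noFRET"),
                                    c(55, 35, 10)))
  fr <- species_fractions(rec)
  ab40 <- dplyr::filter(fr, peptide == "ab40")
  expect_equal(ab40$fraction[ab40$class == "hetero"], 0.35)
  expect_equal(sum(ab40$fraction), 1, tolerance = 1e-12)
  # Abeta42's denominator here is hetero + coloc only (no hom42 records)
  ab42 <- dplyr::filter(fr, peptide == "ab42")
  expect_equal(sum(ab42$fraction), 1, tolerance = 1e-12)
  expect_warning(species_fractions(tibble::tibble(class = "hom40")),
                 "no spots")
})

test_that("fraction vectors sum to one for arbitrary class mixes", {
  set.seed(31)
  for (i in 1:10) {
    rec <- tibble::tibble(class = sample(
      c("hom40", "hom42", "hetero", "coloc_noFRET"), 50, replace = TRUE))
    fr <- species_fractions(rec)
    sums <- tapply(fr$fraction, fr$peptide, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("densities are per 100 um of neurite", {
  expect_equal(density_per_100um(3, 150), 2)
  expect_equal(density_per_100um(0, 100), 0)
  expect_error(density_per_100um(1, 0))
})

test_that("stoichiometric ratios are defined for heterogeneous records with donor content", {
  rec <- tibble::tibble(class = c("hetero", "hetero", "hetero", "hom40"),
                        n40 = c(1L, 1L, 2L, 2L), n42 = c(3L, 1L, 1L, 0L))
  out <- ratio_42_40(rec)
  expect_equal(out$ratio_42_40, c(3, 1, 0.5))
  none <- ratio_42_40(tibble::tibble(class = "hetero", n40 = 0L, n42 = 2L))
  expect_equal(nrow(none), 0)
})

test_that("exact Mann-Whitney enumeration matches known values and wilcox.test", {
  r <- compare_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  w <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(r$p_value, w$p.value)
  expect_equal(r$statistic, unname(w$statistic))

  tied <- compare_distributions(c(1, 1, 1), c(1, 1, 1))
  expect_equal(tied$statistic, 9 / 2)  # n1 n2 / 2 under full ties
  expect_equal(tied$p_value, 1)

  ident <- compare_distributions(c(2, 5, 9), c(2, 5, 9))
  expect_equal(ident$p_value, 1)
})

test_that("large-sample Mann-Whitney matches the tie-corrected normal approximation", {
  set.seed(8)
  a <- sample(1:8, 30, replace = TRUE)
  b <- sample(2:9, 35, replace = TRUE)
  r <- compare_distributions(a, b)
  w <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  expect_equal(r$statistic, unname(w$statistic))
  expect_equal(r$p_value, w$p.value, tolerance = 1e-10)
  expect_match(r$method, "normal")
})

test_that("Mann-Whitney rejects empty samples and tidies", {
  expect_error(compare_distributions(numeric(0), 1))
  td <- tidy(compare_distributions(1:3, 2:4))
  expect_named(td, c("statistic", "p.value", "method", "n_a", "n_b"))
})

test_that("peptide mass share weights oligomers by monomer content", {
  rec <- tibble::tibble(total_size = c(2, 2, 6), class = "hetero")
  expect_equal(peptide_mass_share(rec, 5), 0.6)
  expect_equal(peptide_mass_share(rec, 1), 1)
  expect_error(peptide_mass_share(rec[0, ], 5))
})
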