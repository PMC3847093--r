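#' Round a real monomer count to an integer size
#'
#' Nearest-integer rounding with halves away from zero (so a 2.5-monomer
#' estimate becomes a trimer). Negative inputs are an error; values that
#' round to zero are legitimate output and are flagged/dropped by callers.
#'
#' @param n_real Non-negative real monomer counts.
#' @return Integer vector.
#' @export
#' @examples
#' integer_size(c(1.2, 2.5, 2.6))
integer_size <- function(n_real) {
  if (any(is.na(n_real))) abort("`n_real` contains NA.")
  if (any(n_real < 0)) abort("`n_real` must be >= 0.")
  as.integer(floor(n_real + 0.5))
}

#' Total size of a heterogeneous oligomer
#'
#' Rounds the Abeta40 and Abeta42 monomer estimates to the nearest integer
#' separately and sums them. The minimal heterogeneous oligomer is dimeric;
#' records where both peptides round to zero have no defensible size and are
#' returned as `NA` (dropped with a flag downstream).
#'
#' @param n40_real,n42_real Real monomer estimates, >= 0.
#' @return Integer total sizes (`NA` where both components round to 0).
#' @export
#' @examples
#' hetero_size(1.2, 2.6)  # 4
hetero_size <- function(n40_real, n42_real) {
  s <- integer_size(n40_real) + integer_size(n42_real)
  s[s == 0] <- NA_integer_
  s
}

#' Normalized oligomer size distribution with an open top bin
#'
#' Histograms integer sizes into bins 1 .. `max_bin - 1` plus an open
#' "`max_bin` or larger" bin, normalized to the total number of oligomers.
#'
#' @param records Tibble with a `total_size` column (and optionally `class`),
#'   or a bare integer vector of sizes.
#' @param class_filter Optional class name(s) to keep before binning.
#' @param max_bin First size of the open top bin (default 7: "7+").
#' @return Tibble with `bin` (ordered factor `"1"`..`"7+"`), `n`, `fraction`;
#'   fractions sum to 1.
#' @export
#' @examples
#' size_distribution(c(2, 2, 3, 7, 9))
size_distribution <- function(records, class_filter = NULL, max_bin = 7L) {
  sizes <- if (is.data.frame(records)) {
    r <- records
    if (!is.null(class_filter)) r <- r[r$class %in% class_filter, ]
    r$total_size
  } else {
    records
  }
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) == 0) abort("No retained records to bin.")
  labs <- c(as.character(seq_len(max_bin - 1)), paste0(max_bin, "+"))
  binned <- pmin(as.integer(sizes), max_bin)
  counts <- tabulate(binned, nbins = max_bin)
  tibble(
    bin = factor(labs, levels = labs),
    n = counts,
    fraction = counts / sum(counts)
  )
}

#' Species fractions per base peptide
#'
#' Mirrors the per-peptide normalization of the species-population analysis:
#' for Abeta40 the denominator is every Abeta40-containing spot (`hom40` +
#' `hetero` + `coloc_noFRET`) and likewise for Abeta42. A colocalized-no-FRET
#' spot contains both peptides and is counted in both denominators.
#'
#' @param records Tibble with a `class` column.
#' @return Tibble with `peptide`, `class`, `n`, `fraction`; within each
#'   peptide the fractions sum to 1. Peptides with no spots are dropped with
#'   a warning.
#' @export
#' @examples
#' species_fractions(tibble::tibble(
#'   class = rep(c("hom40", "hetero", "coloc_noFRET"), c(55, 35, 10))))
species_fractions <- function(records) {
  records <- records[!is.na(records$class), ]
  member <- list(
    ab40 = c("hom40", "hetero", "coloc_noFRET"),
    ab42 = c("hom42", "hetero", "coloc_noFRET")
  )
  out <- purrr::imap_dfr(member, function(classes, pep) {
    sub <- records[records$class %in% classes, ]
    if (nrow(sub) == 0) return(NULL)
    tab <- table(factor(sub$class, levels = classes))
    tibble(peptide = pep, class = names(tab), n = as.integer(tab),
           fraction = as.numeric(tab) / nrow(sub))
  })
  if (!"ab40" %in% out$peptide || !"ab42" %in% out$peptide) {
    warn("A peptide has no spots; its fractions are undefined and omitted.")
  }
  out
}

#' Oligomer density per 100 um of neurite
#'
#' @param n_spots Number of oligomers.
#' @param neurite_length_um Total neurite length in the field (um), > 0.
#' @return Oligomers per 100 um.
#' @export
#' @examples
#' density_per_100um(3, 150)
density_per_100um <- function(n_spots, neurite_length_um) {
  if (any(neurite_length_um <= 0)) abort("Neurite length must be > 0.")
  n_spots * 100 / neurite_length_um
}

#' Abeta42/Abeta40 stoichiometric ratio of heterogeneous oligomers
#'
#' `n42 / n40` per heterogeneous record; a ratio of 1 marks equal amounts of
#' the two peptides. Records that are not heterogeneous or have `n40 = 0`
#' are excluded (the ratio is undefined there).
#'
#' @param records Tibble with `class`, `n40`, `n42`.
#' @return Tibble of the retained heterogeneous records with `ratio_42_40`
#'   added.
#' @export
ratio_42_40 <- function(records) {
  kept <- records[!is.na(records$class) & records$class == "hetero" &
                    records$n40 >= 1, , drop = FALSE]
  dplyr::mutate(kept, ratio_42_40 = .data$n42 / .data$n40)
}

#' Mann-Whitney U comparison of two size distributions
#'
#' For small samples (both groups at most `exact_max` observations) the exact
#' two-sided p-value is computed by full enumeration of all label
#' rearrangements of the pooled sample, which handles ties exactly; larger
#' samples use the normal approximation with the tie-corrected variance.
#' The statistic is `U` for the first sample (ties counting one half).
#'
#' @param sizes_a,sizes_b Numeric vectors, non-empty.
#' @param exact_max Largest per-group size for exact enumeration.
#' @return Object of class `mw_test`: `statistic` (U), `p_value`, `method`,
#'   `n_a`, `n_b`. A [tidy()] method is provided.
#' @export
#' @examples
#' compare_distributions(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
compare_distributions <- function(sizes_a, sizes_b, exact_max = 8L) {
  if (length(sizes_a) == 0 || length(sizes_b) == 0) {
    abort("Both samples must be non-empty.")
  }
  n1 <- length(sizes_a)
  n2 <- length(sizes_b)
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(sizes_a, sizes_b)
  if (n1 <= exact_max && n2 <= exact_max) {
    pooled <- c(sizes_a, sizes_b)
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
    p <- min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(c(sizes_a, sizes_b))
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  structure(
    list(statistic = u_obs, p_value = p, method = method, n_a = n1, n_b = n2),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat("Mann-Whitney U =", x$statistic, ", two-sided p =",
      signif(x$p_value, 3), "(", x$method, ")\n")
  invisible(x)
}

#' @export
tidy.mw_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method,
         n_a = x$n_a, n_b = x$n_b)
}

#' Monomer-weighted share of peptide in large oligomers
#'
#' Fraction of all monomers (both peptides) that reside in oligomers of at
#' least `min_size` monomers, optionally restricted to given classes.
#'
#' @param records Tibble with `total_size` (and `class` if filtering).
#' @param min_size Size threshold (default 5: larger than tetramers).
#' @param classes Optional class filter.
#' @return Fraction in \[0, 1\].
#' @export
peptide_mass_share <- function(records, min_size = 5L, classes = NULL) {
  if (!is.null(classes)) records <- records[records$class %in% classes, ]
  sizes <- records$total_size[!is.na(records$total_size)]
  if (length(sizes) == 0) abort("No retained records.")
  sum(sizes[sizes >= min_size]) / sum(sizes)
}
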