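#' @noRd
new_decay_histogram <- function(bin_edges_ns, counts) {
  stopifnot(length(counts) == length(bin_edges_ns) - 1,
            all(diff(bin_edges_ns) > 0), all(counts >= 0))
  structure(list(bin_edges_ns = bin_edges_ns, counts = as.integer(counts)),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat("<decay_histogram>", sum(x$counts), "photons in",
      length(x$counts), "bins over",
      round(max(x$bin_edges_ns), 2), "ns\n")
  invisible(x)
}

#' Simulate a TCSPC decay histogram
#'
#' Draws photon arrival times from a mono-exponential decay with lifetime
#' `tau_ns`, truncated to the acquisition window (sampling is by the exact
#' truncated inverse CDF, so no photons are discarded), and bins them into a
#' time-correlated single-photon-counting histogram.
#'
#' @param tau_ns Fluorescence lifetime (ns), > 0.
#' @param n_photons Number of photons, >= 1. A window of at least ~5 lifetimes
#'   is recommended so truncation stays mild.
#' @param bin_ns Histogram bin width (ns).
#' @param window_ns Acquisition window (ns).
#' @param seed Integer seed.
#' @return A `decay_histogram` with fields `bin_edges_ns` and `counts`.
#' @export
#' @examples
#' d <- generate_decay(0.48, 2000, seed = 1)
#' sum(d$counts)
generate_decay <- function(tau_ns, n_photons, bin_ns = 0.05,
                           window_ns = 12.5, seed = 1L) {
  if (tau_ns <= 0) abort("`tau_ns` must be > 0.")
  if (n_photons < 1) abort("`n_photons` must be >= 1.")
  if (bin_ns <= 0 || window_ns <= bin_ns) {
    abort("Need 0 < bin_ns < window_ns.")
  }
  set.seed(as.integer(seed))
  # inverse CDF of Exp(tau) truncated to [0, window]
  u <- runif(n_photons)
  t <- -tau_ns * log(1 - u * (1 - exp(-window_ns / tau_ns)))
  edges <- seq(0, window_ns, by = bin_ns)
  if (max(edges) < window_ns) edges <- c(edges, window_ns)
  counts <- tabulate(findInterval(t, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  new_decay_histogram(edges, counts)
}

#' Read/write decay histograms as CSV
#'
#' The on-disk format is `bin_start_ns,bin_end_ns,counts`, one row per bin.
#'
#' @param decay A `decay_histogram`.
#' @param path File path.
#' @return `write_decay_csv()` returns `path` invisibly; `read_decay_csv()`
#'   returns a `decay_histogram`.
#' @export
write_decay_csv <- function(decay, path) {
  df <- data.frame(
    bin_start_ns = head(decay$bin_edges_ns, -1),
    bin_end_ns = tail(decay$bin_edges_ns, -1),
    counts = decay$counts
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  df <- utils::read.csv(path)
  new_decay_histogram(c(df$bin_start_ns, tail(df$bin_end_ns, 1)), df$counts)
}
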