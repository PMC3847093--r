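#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_col geom_point
#'   geom_line geom_path scale_fill_viridis_c scale_y_log10 facet_wrap labs
#'   theme_minimal coord_equal
NULL

#' @export
ggplot2::autoplot

#' Plot a synthetic field channel with the neurite outline
#'
#' @param object A `field_bundle`.
#' @param channel `"dd"`, `"da"` or `"aa"`.
#' @param truth Optional ground-truth tibble; spots are overlaid coloured by
#'   class.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.field_bundle <- function(object, channel = c("dd", "da", "aa"),
                                  truth = NULL, ...) {
  channel <- match.arg(channel)
  img <- object[[channel]]
  df <- tidyr::expand_grid(y_px = seq_len(nrow(img)) - 1L,
                           x_px = seq_len(ncol(img)) - 1L)
  df$photons <- as.vector(t(img))
  p <- ggplot(df, aes(.data$x_px, .data$y_px, fill = .data$photons)) +
    geom_raster() +
    scale_fill_viridis_c(trans = "sqrt") +
    coord_equal(expand = FALSE) +
    labs(x = "x (px)", y = "y (px)", fill = "photons",
         title = paste(toupper(channel), "channel")) +
    theme_minimal()
  if (!is.null(truth) && nrow(truth) > 0) {
    p <- p + geom_point(
      data = truth, aes(.data$x_px, .data$y_px, colour = .data$class),
      inherit.aes = FALSE, shape = 1, size = 3
    )
  }
  p
}

#' Bar plot of a normalized oligomer size distribution
#'
#' @param dist Output of [size_distribution()], optionally row-bound over
#'   groups with a `group` column for facetting.
#' @return A ggplot.
#' @export
plot_size_distribution <- function(dist) {
  p <- ggplot(dist, aes(.data$bin, .data$fraction)) +
    geom_col(fill = "grey35") +
    labs(x = "oligomer size (monomers)", y = "fraction of oligomers") +
    theme_minimal()
  if ("group" %in% names(dist)) p <- p + facet_wrap(~group)
  p
}

#' Stacked bar plot of species fractions per peptide
#'
#' @param fractions Output of [species_fractions()] (or
#'   [experiment_fractions()]; the `mean_fraction` column is used if present).
#' @return A ggplot.
#' @export
plot_species_fractions <- function(fractions) {
  if ("mean_fraction" %in% names(fractions)) {
    fractions <- dplyr::rename(fractions, fraction = "mean_fraction")
  }
  ggplot(fractions, aes(.data$peptide, .data$fraction, fill = .data$class)) +
    geom_col() +
    labs(x = NULL, y = "fraction of peptide's oligomers", fill = "species") +
    theme_minimal()
}

#' Plot a TCSPC decay histogram with an optional fitted curve
#'
#' @param object A `decay_histogram`.
#' @param fit Optional `lifetime_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot (log-count axis).
#' @export
autoplot.decay_histogram <- function(object, fit = NULL, ...) {
  mid <- (head(object$bin_edges_ns, -1) + tail(object$bin_edges_ns, -1)) / 2
  df <- tibble(t_ns = mid, counts = object$counts)
  p <- ggplot(dplyr::filter(df, .data$counts > 0),
              aes(.data$t_ns, .data$counts)) +
    geom_point(size = 0.6, alpha = 0.6) +
    scale_y_log10() +
    labs(x = "arrival time (ns)", y = "photons / bin") +
    theme_minimal()
  if (!is.null(fit) && isTRUE(fit$converged)) {
    n <- sum(object$counts)
    w <- max(object$bin_edges_ns)
    bin <- diff(object$bin_edges_ns)[1]
    expected <- n * bin * exp(-mid / fit$tau_ns) /
      (fit$tau_ns * (1 - exp(-w / fit$tau_ns)))
    p <- p + geom_line(data = tibble(t_ns = mid, counts = expected),
                       colour = "firebrick")
  }
  p
}
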