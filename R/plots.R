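# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_line geom_point
#'   geom_tile geom_vline labs scale_fill_viridis_c theme_minimal after_stat
NULL

#' @export
ggplot2::autoplot

#' Plot a tMRCA posterior
#'
#' Weighted histogram of accepted tMRCA draws with the median marked.
#'
#' @param object A `tmrca_posterior`.
#' @param binwidth Histogram bin width in generations.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tmrca_posterior <- function(object, binwidth = 5, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$t, weight = .data$weight,
                 y = after_stat(.data$density))) +
    geom_histogram(binwidth = binwidth, boundary = 0,
                   fill = "steelblue", colour = "white") +
    geom_vline(xintercept = object$summaries$median, linetype = 2) +
    labs(x = "tMRCA (generations)", y = "posterior density",
         title = sprintf("tMRCA posterior: %g (%g-%g) generations",
                         object$summaries$median, object$summaries$q2.5,
                         object$summaries$q97.5)) +
    theme_minimal()
}

#' Plot a carrier-count distribution
#'
#' @param object A `carrier_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.carrier_distribution <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$carriers, y = after_stat(.data$density))) +
    geom_histogram(bins = 50, boundary = 0, fill = "grey25", colour = "white") +
    geom_vline(xintercept = object$summaries$median, colour = "red") +
    labs(x = "carriers per generation", y = "density",
         title = sprintf("Present-day carriers per generation: %g (%g-%g)",
                         object$summaries$median, object$summaries$q2.5,
                         object$summaries$q97.5)) +
    theme_minimal()
}

#' Plot a one-phase decay fit
#'
#' Observed levels with the fitted decay curve overlaid.
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_fit <- function(object, ...) {
  grid <- tibble::tibble(time_h = seq(0, max(object$data$time_h), length.out = 200))
  grid$level_pct <- object$fitted(grid$time_h)
  ggplot(object$data, aes(x = .data$time_h, y = .data$level_pct)) +
    geom_point(alpha = 0.7) +
    geom_line(data = grid, colour = "steelblue") +
    labs(x = "time (h)", y = "protein level (% of t = 0)",
         title = sprintf("One-phase decay: K = %.3g /h, plateau = %.3g%%",
                         object$K, object$plateau)) +
    theme_minimal()
}

#' Plot a haplotype panel
#'
#' Tile plot of allele repeat numbers, carriers on top, emulating the usual
#' haplotype-sharing figure: the conserved founder block appears as a band
#' of constant colour across carrier rows around the disease locus.
#'
#' @param object A `haplotype_panel`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.haplotype_panel <- function(object, ...) {
  loci <- object$map$marker
  df <- object$chromosomes |>
    tidyr::pivot_longer(dplyr::all_of(loci), names_to = "marker",
                        values_to = "allele") |>
    dplyr::mutate(marker = factor(.data$marker, levels = loci),
                  sample_id = factor(.data$sample_id,
                                     levels = rev(unique(object$chromosomes$sample_id))))
  ggplot(df, aes(x = .data$marker, y = .data$sample_id, fill = .data$allele)) +
    geom_tile(colour = "white") +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = "repeat no.") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
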