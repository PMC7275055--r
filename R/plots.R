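#' Plot a FRET population histogram
#'
#' @param object A [fret_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fret_histogram
#' @export
autoplot.fret_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$density)) +
    ggplot2::geom_col(width = object$bin_right[1] - object$bin_left[1],
                      fill = "steelblue", colour = NA, alpha = 0.8) +
    ggplot2::labs(x = "apparent FRET efficiency", y = "probability density") +
    ggplot2::theme_minimal()
}

#' Plot a mixture fit over its sample histogram
#'
#' Draws the area-normalised sample histogram with each fitted Gaussian
#' component and their sum overlaid — the standard presentation of a
#' multi-Gaussian population decomposition.
#'
#' @param object A `fret_mixture`.
#' @param bins Histogram bins for the backdrop.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fret_mixture
#' @export
autoplot.fret_mixture <- function(object, bins = 60, ...) {
  h <- fret_histogram(object$samples, bins = bins)
  grid <- seq(min(h$bin_left), max(h$bin_right), length.out = 400)
  comp <- purrr::map_dfr(seq_len(object$k), function(j) {
    tibble(component = factor(j), E = grid,
           density = object$weights[j] * dnorm(grid, object$means[j],
                                               object$sds[j]))
  })
  total <- comp %>%
    group_by(.data$E) %>%
    summarise(density = sum(.data$density), .groups = "drop")
  ggplot2::ggplot() +
    ggplot2::geom_col(data = h,
                      ggplot2::aes(x = .data$bin_mid, y = .data$density),
                      width = h$bin_right[1] - h$bin_left[1],
                      fill = "grey80") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$E, y = .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_line(data = total,
                       ggplot2::aes(x = .data$E, y = .data$density),
                       colour = "black") +
    ggplot2::labs(x = "apparent FRET efficiency", y = "probability density") +
    ggplot2::theme_minimal()
}

#' Plot a time-windowed FRET population contour
#'
#' @param object A [windowed_histograms()] result.
#' @param ... Unused.
#' @return A ggplot (tile map of density over time and FRET).
#' @method autoplot fret_contour
#' @export
autoplot.fret_contour <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$n_frames > 0),
                  ggplot2::aes(x = .data$bin_mid,
                               y = (.data$t_start + .data$t_end) / 2,
                               fill = .data$density)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "apparent FRET efficiency", y = "time (s)",
                  fill = "density") +
    ggplot2::theme_minimal()
}

#' Plot a dwell-time histogram with its exponential fit
#'
#' @param object A [fit_dwell_times()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dwell_fit
#' @export
autoplot.dwell_fit <- function(object, ...) {
  if (is.null(object$histogram)) abort("degenerate fit has no histogram")
  grid <- seq(0, max(object$histogram$t), length.out = 200)
  pred <- rowSums(vapply(seq_along(object$rates), function(j) {
    object$amplitudes[j] * exp(-object$rates[j] * grid)
  }, numeric(length(grid))))
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$t, y = .data$count)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_line(data = tibble(t = grid, count = pred),
                       colour = "firebrick") +
    ggplot2::labs(x = "dwell time (s)", y = "events") +
    ggplot2::theme_minimal()
}

#' Plot a single molecule's donor/acceptor/FRET trajectory
#'
#' @param traces Trace tibble.
#' @param molecule Molecule id to plot.
#' @param alpha Leakage factor for the FRET panel.
#' @return A ggplot with intensity and FRET panels.
#' @export
plot_trace <- function(traces, molecule, alpha = 0.88) {
  tr <- filter(traces, .data$molecule_id == molecule)
  if (nrow(tr) == 0) abort("molecule not found")
  fr <- compute_fret(tr, alpha = alpha)
  long <- tidyr::pivot_longer(
    select(fr, "time_s", donor = "I_D", acceptor = "I_A", FRET = "E_fret"),
    -"time_s", names_to = "channel", values_to = "value")
  long$panel <- ifelse(long$channel == "FRET", "FRET", "intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(donor = "forestgreen",
                                            acceptor = "firebrick",
                                            FRET = "black")) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
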