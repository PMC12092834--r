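#' Raster plot of MEA spikes
#'
#' @param raster A `mea_raster` or `mea_sim`.
#' @return A ggplot object: one row per electrode, one tick per spike.
#' @export
plot_raster <- function(raster) {
  if (inherits(raster, "mea_sim")) raster <- raster$raster
  ggplot2::ggplot(tibble::as_tibble(raster),
                  ggplot2::aes(x = .data$time_s, y = .data$electrode)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::scale_y_continuous(
      breaks = seq(0, raster_n_electrodes(raster) - 1)) +
    ggplot2::labs(x = "time (s)", y = "electrode") +
    ggplot2::theme_minimal()
}

#' Network firing rate with detected bursts
#'
#' @param raster A `mea_raster`.
#' @param bin_ms Bin width (ms).
#' @return A ggplot object: binned network rate with burst windows
#'   shaded and the start/stop thresholds drawn.
#' @export
plot_network_rate <- function(raster, bin_ms = 25) {
  rate <- network_rate(raster, bin_ms)
  bursts <- detect_bursts(raster, bin_ms)
  df <- tibble::tibble(
    time_s = (seq_along(rate$counts) - 0.5) * bin_ms / 1000,
    counts = rate$counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                        y = .data$counts)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = rate$max_rate / 4,
                        linetype = "dashed", colour = "darkred") +
    ggplot2::geom_hline(yintercept = rate$max_rate / 50,
                        linetype = "dotted", colour = "darkred") +
    ggplot2::labs(x = "time (s)", y = "spikes per bin") +
    ggplot2::theme_minimal()
  if (nrow(bursts)) {
    p <- p + ggplot2::geom_rect(
      data = bursts, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$stop,
                   ymin = -Inf, ymax = Inf),
      fill = "steelblue", alpha = 0.2)
  }
  p
}

#' Marginal posterior distributions
#'
#' @param object A `mea_posterior`.
#' @param n_samples,seed Sampling settings.
#' @param true_params Optional named ground-truth values drawn as
#'   vertical lines.
#' @param ... Unused.
#' @return A ggplot object: one density panel per parameter over its
#'   prior range.
#' @export
autoplot.mea_posterior <- function(object, n_samples = 1000, seed = 1,
                                   true_params = NULL, ...) {
  s <- posterior_sample(object, n_samples, seed = seed)
  long <- tidyr::pivot_longer(s, dplyr::everything(),
                              names_to = "parameter")
  long$parameter <- factor(long$parameter,
                           levels = object$model$ranges$parameter)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "goldenrod", alpha = 0.5) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density") +
    ggplot2::theme_minimal()
  if (!is.null(true_params)) {
    tp <- tibble::tibble(parameter = factor(names(true_params),
                                            levels = levels(long$parameter)),
                         value = as.numeric(true_params))
    p <- p + ggplot2::geom_vline(data = tp,
                                 ggplot2::aes(xintercept = .data$value),
                                 colour = "brown")
  }
  p
}

#' Heatmap of mean conditional correlations between parameters
#'
#' @param object A `mea_cond_corr` from [conditional_corr_matrix()].
#' @param ... Unused.
#' @return A ggplot tile plot of the mean pairwise conditional Pearson
#'   correlations.
#' @export
autoplot.mea_cond_corr <- function(object, ...) {
  m <- object$mean_r
  df <- tibble::as_tibble(as.table(m), .name_repair = ~c("a", "b", "r"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
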