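# ggplot2 views of the main result types.

#' Plot burst statistics
#'
#' @param object A [burst_statistics()] result.
#' @param which One of `"size"`, `"duration"`, `"suppression"`,
#'   `"participation"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.burst_statistics <- function(object,
                                      which = c("size", "duration",
                                                "suppression",
                                                "participation"), ...) {
  which <- match.arg(which)
  if (which %in% c("size", "duration")) {
    tab <- if (which == "size") object$size_hist else object$duration_hist
    tab <- tab[is.finite(tab$log10_rate), ]
    ggplot(tab, aes(x = .data$log10_mid, y = .data$log10_rate)) +
      geom_point() + geom_line() +
      labs(x = if (which == "size") "log10 burst size (neurons)"
           else "log10 burst duration (s)",
           y = "log10 rate (bursts/min)") +
      theme_minimal()
  } else {
    tab <- object[[which]]
    if (is.null(tab)) abort("profile not available (zero bursts)")
    ggplot(tab, aes(x = .data$lag_s, y = .data$value)) +
      geom_line() +
      geom_hline(yintercept = 1, linetype = "dashed") +
      labs(x = "lag from burst (s)",
           y = if (which == "suppression") "normalised activity"
           else "normalised participation") +
      theme_minimal()
  }
}

#' Plot a raster as a spike-time image
#'
#' @param raster A [spike_raster()].
#' @param neurons Optional neuron table; if given, rows are ordered by
#'   anterior-posterior position.
#' @param max_neurons Downsample to at most this many rows (default 500).
#' @return A ggplot.
#' @export
plot_raster <- function(raster, neurons = NULL, max_neurons = 500L) {
  cm <- methods::as(raster$counts, "TsparseMatrix")
  df <- tibble(neuron = cm@i + 1L, frame = cm@j + 1L, count = cm@x)
  if (!is.null(neurons)) {
    ord <- order(neurons$ap)
    pos <- integer(nrow(neurons)); pos[ord] <- seq_along(ord)
    df$neuron <- pos[df$neuron]
  }
  if (!is.null(max_neurons) && max(df$neuron) > max_neurons) {
    keep <- sort(sample.int(max(df$neuron), max_neurons))
    df <- df[df$neuron %in% keep, ]
    df$neuron <- match(df$neuron, keep)
  }
  ggplot(df, aes(x = .data$frame * raster$frame_dt + raster$t0,
                 y = .data$neuron)) +
    geom_point(shape = ".", alpha = 0.6) +
    labs(x = "time (s)", y = "neuron") +
    theme_minimal()
}

#' Plot a receptive-field fit
#' @param object An `rf_fit`.
#' @param azimuth,response The data the fit was made on.
#' @param ... Unused.
#' @export
autoplot.rf_fit <- function(object, azimuth, response, ...) {
  grid <- seq(min(azimuth), max(azimuth), length.out = 200)
  pred <- object$A * exp(-(grid - object$mu)^2 / (2 * object$sigma^2))
  ggplot() +
    geom_point(aes(x = azimuth, y = response)) +
    geom_line(aes(x = grid, y = pred), colour = "steelblue") +
    labs(x = "azimuth (deg)", y = "mean spike count") +
    theme_minimal()
}

#' Plot adaptation timecourse from a response-modulation analysis
#' @param object A [response_modulation()] result.
#' @param ... Unused.
#' @export
autoplot.response_modulation <- function(object, ...) {
  ggplot(object$timecourse,
         aes(x = .data$onset, y = .data$norm_response,
             colour = .data$elevation, shape = .data$role)) +
    geom_point() + geom_line(alpha = 0.4) +
    labs(x = "time (s)", y = "response (normalised to first)") +
    theme_minimal()
}
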