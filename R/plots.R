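#' Plot a lateralized ERP wave
#'
#' Contralateral, ipsilateral and difference time courses; the difference
#' wave carries the N2pc.
#'
#' @param object a `lateralized_wave` tibble from [contra_ipsi()].
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot lateralized_wave
#' @export
autoplot.lateralized_wave <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("contra", "ipsi", "diff"),
                              names_to = "wave", values_to = "uV")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$uV,
                                     colour = .data$wave)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after cue (ms)", y = "amplitude (µV)",
                  colour = NULL)
}

#' Plot saccade-rate time courses
#'
#' @param rates tibble from [saccade_rate()].
#' @return a ggplot object showing toward and away rates plus their bias.
#' @export
plot_saccade_rate <- function(rates) {
  long <- tidyr::pivot_longer(rates, c("rate_toward", "rate_away", "bias"),
                              names_to = "series", values_to = "hz")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$hz,
                                     colour = .data$series)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after cue (ms)", y = "rate (Hz)", colour = NULL)
}

#' Plot a time-frequency lateralization map
#'
#' @param lat a `tfr_lat` tibble from [lateralization_index()].
#' @return a ggplot raster of the lateralization index (percent).
#' @export
plot_lateralization <- function(lat) {
  ggplot2::ggplot(lat, ggplot2::aes(.data$time_ms, .data$freq,
                                    fill = .data$lat)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-100, 100)) +
    ggplot2::labs(x = "time after cue (ms)", y = "frequency (Hz)",
                  fill = "L (%)")
}

#' Plot an ERP image
#'
#' Sorted single-trial voltages with the sorted reference-onset curve
#' overlaid.
#'
#' @param object an `erp_image`.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot erp_image
#' @export
autoplot.erp_image <- function(object, ...) {
  m <- object$matrix
  df <- tibble(
    trial = rep(seq_len(nrow(m)), times = ncol(m)),
    time_ms = rep(object$time_ms, each = nrow(m)),
    uV = as.vector(m)
  )
  ons <- tibble(trial = seq_len(nrow(m)), onset = object$onsets)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$trial,
                                   fill = .data$uV)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::geom_path(data = ons,
                       ggplot2::aes(x = .data$onset, y = .data$trial),
                       inherit.aes = FALSE, colour = "black") +
    ggplot2::labs(x = "time after cue (ms)", y = "sorted trial",
                  fill = "µV", title = object$label)
}

#' Plot a cluster permutation test
#'
#' Pointwise t statistic with significant clusters shaded.
#'
#' @param object a `cluster_test` (1D series only).
#' @param time optional time axis for the x coordinate (defaults to the
#'   sample index).
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot cluster_test
#' @export
autoplot.cluster_test <- function(object, time = NULL, ...) {
  if (!is.null(object$dims))
    stop("plotting is implemented for 1D (time-series) tests", call. = FALSE)
  tv <- object$tvals
  tm <- time %||% seq_along(tv)
  df <- tibble(time = tm, t = tv)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$t)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$crit,
                        linetype = "dashed", linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "t")
  cl <- object$clusters
  if (nrow(cl)) {
    shade <- tibble(xmin = tm[cl$start], xmax = tm[cl$end],
                    sig = cl$p < object$alpha)
    gg <- gg + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf,
                   ymax = Inf, alpha = .data$sig),
      inherit.aes = FALSE, fill = "firebrick") +
      ggplot2::scale_alpha_manual(values = c(`TRUE` = 0.3, `FALSE` = 0.1),
                                  guide = "none")
  }
  gg
}
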