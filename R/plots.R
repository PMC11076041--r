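#' Plot a mean dF/F0 trace
#'
#' Mean trace with an SEM ribbon, the stimulation window shaded, and NH4Cl
#' frames marked.
#'
#' @param mean_trace Tibble from [average_traces()].
#' @param protocol The [stim_protocol()].
#' @return A ggplot object.
#' @export
plot_mean_trace <- function(mean_trace, protocol) {
  pre <- mean_trace[!mean_trace$nh4cl, ]
  p <- ggplot2::ggplot(pre, ggplot2::aes(x = .data$time, y = .data$mean_dff)) +
    ggplot2::annotate("rect",
                      xmin = protocol$stim_start,
                      xmax = protocol$stim_start + protocol$stim_duration,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_dff - .data$sem_dff,
                                      ymax = .data$mean_dff + .data$sem_dff),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from stimulation onset (s)",
                  y = expression(Delta * F / F[0]),
                  title = "Mean sypHy response") +
    ggplot2::theme_minimal()
  if (any(mean_trace$nh4cl)) {
    p <- p + ggplot2::geom_point(data = mean_trace[mean_trace$nh4cl, ],
                                 shape = 17, colour = "darkorange")
  }
  p
}

#' Plot a fitted endocytosis decay
#'
#' @param object A `decay_fit` from [fit_endocytosis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  w <- object$window
  curve <- tibble::tibble(
    time = seq(min(w$time), max(w$time), length.out = 200))
  curve$dff <- object$y0 + object$amplitude * exp(-curve$time / object$tau)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$time, y = .data$dff)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(
      x = "time from stimulation onset (s)", y = expression(Delta * F / F[0]),
      title = sprintf("Endocytosis decay: tau = %.1f s%s", object$tau,
                      if (object$valid) "" else " (discarded)")) +
    ggplot2::theme_minimal()
}

#' Plot a fitted Gaussian line profile
#'
#' @param object A converged `profile_fit` from [fit_profile()].
#' @param ... Unused.
#' @param profile Optional tibble of the underlying data (`x`, `intensity`).
#' @return A ggplot object.
#' @method autoplot profile_fit
#' @export
autoplot.profile_fit <- function(object, ..., profile = NULL) {
  if (!object$converged) stop("cannot plot a non-converged fit", call. = FALSE)
  if (is.null(profile)) {
    xr <- object$x_c + c(-4, 4) * object$w
    profile <- tibble::tibble(x = seq(xr[1], xr[2], length.out = 200))
    profile$intensity <- object$f_axon +
      object$f_syn * exp(-(profile$x - object$x_c)^2 / (2 * object$w^2))
    geom_data <- ggplot2::geom_blank()
  } else {
    geom_data <- ggplot2::geom_point(alpha = 0.6)
  }
  curve <- tibble::tibble(
    x = seq(min(profile$x), max(profile$x), length.out = 300))
  curve$intensity <- object$f_axon +
    object$f_syn * exp(-(curve$x - object$x_c)^2 / (2 * object$w^2))
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$x, y = .data$intensity)) +
    geom_data +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "position (px)", y = "intensity",
                  title = sprintf("Gaussian profile: FWHM = %.2f", object$fwhm)) +
    ggplot2::theme_minimal()
}

#' Overlay detected puncta on an image
#'
#' @param image Numeric matrix.
#' @param puncta Tibble from [detect_puncta()].
#' @return A ggplot object (raster of the image with punctum centroids).
#' @export
plot_puncta <- function(image, puncta) {
  df <- tibble::tibble(
    x = rep(seq_len(ncol(image)), each = nrow(image)),
    y = rep(seq_len(nrow(image)), ncol(image)),
    value = as.vector(image)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(data = puncta, colour = "red", shape = 1, size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%d puncta", nrow(puncta))) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
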